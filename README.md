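# MotifContrast

Comparative visualization of sequence motifs: **difference logos** for
pairs of motifs and a clustered, color-coded N×N comparison grid for
motif collections, over DNA, RNA, protein or user-defined alphabets.

## Why

Sequence logos are the standard picture of a motif, but differences
between *similar* motifs — the same transcription factor assayed in
different cell lines, different factors binding near-identical E-boxes,
one protein domain across kingdoms — are nearly invisible when you put
two logos side by side. Scalar motif-similarity scores go to the other
extreme: one number, no indication of *which* positions and symbols
differ.

A difference logo shows both. For motifs *P* and *Q* with per-position
distributions *p<sub>ℓ</sub>* and *q<sub>ℓ</sub>*:

* stack height at position ℓ = the **Jensen–Shannon divergence**
  (bits): H<sub>ℓ</sub> = ½ KL(p<sub>ℓ</sub>‖m<sub>ℓ</sub>) +
  ½ KL(q<sub>ℓ</sub>‖m<sub>ℓ</sub>), with
  m<sub>ℓ</sub> = (p<sub>ℓ</sub>+q<sub>ℓ</sub>)/2 — symmetric, bounded
  by 1 bit, zero iff the distributions agree;
* symbol height = H<sub>ℓ</sub> × the **normalized probability
  difference** r<sub>ℓ,a</sub> = (p<sub>ℓ,a</sub> − q<sub>ℓ,a</sub>) /
  Σ<sub>a′</sub>|p<sub>ℓ,a′</sub> − q<sub>ℓ,a′</sub>|. Symbols losing
  abundance in the second motif point up, symbols gaining point down;
  gains and losses balance exactly at every position.

Summing stack heights gives a scalar dissimilarity
D = Σ<sub>ℓ</sub> H<sub>ℓ</sub> used to cluster motif collections
(hierarchical clustering with optimal leaf ordering) and to color the
grid cells from green (most similar pair) to red (most dissimilar).
Both measures are pluggable (`measurePair()`, `listMeasures()`).

## Worked example

A single position where C trades abundance with T between two otherwise
identical binding-site models:

```r
library(MotifContrast)
p <- probabilityMotif(rbind(c(0.97, 0.01, 0.01, 0.01),
                            c(0.10, 0.35, 0.10, 0.45),
                            c(0.25, 0.25, 0.25, 0.25)), "dna", label = "siteA")
q <- probabilityMotif(rbind(c(0.97, 0.01, 0.01, 0.01),
                            c(0.10, 0.58, 0.10, 0.22),
                            c(0.25, 0.25, 0.25, 0.25)), "dna", label = "siteB")
dc <- differenceColumn(probs(p)[2, ], probs(q)[2, ])
round(dc$stackHeight, 4)
#> [1] 0.0498
round(dc$symbolHeights, 4)
#>       A       C       G       T
#>  0.0000 -0.0249  0.0000  0.0249
motifDissimilarity(p, q)
#> [1] 0.04981486
```

Position 2 carries all of the difference (0.0498 bits): T points up
(less abundant in `siteB`), C points down (more abundant in `siteB`),
each with half the stack height. Positions 1 and 3 agree and contribute
nothing. `renderLogo(buildDifferenceLogo(p, q), "diff.svg")` draws it.

Comparing a collection:

```r
ms <- lapply(1:4, function(i)
    randomMotif("dna", 8, concentration = 0.5, seed = i,
                label = paste0("motif", i)))
g <- buildComparisonGrid(ms)
g
#> ComparisonGrid: 4 motifs, leaf order: motif1 motif4 motif2 motif3
#> shared ordinate bound: 0.298382 bits
round(dissimilarityValues(g), 3)
#>        motif1 motif2 motif3 motif4
#> motif1  0.000  2.149  3.235  1.884
#> motif2  2.149  0.000  2.605  2.123
#> motif3  3.235  2.605  0.000  2.635
#> motif4  1.884  2.123  2.635  0.000
renderGrid(g, "grid.svg")          # figure with logos, tree, colors
writeDistanceMatrix(g@dissimilarity, "D.tsv")
writeNewick(g@tree, "tree.nwk")
```

The leaf order puts the most similar motifs (1 and 4, D = 1.884) next
to each other; the most dissimilar pair (1 and 3, D = 3.235) gets the
red background.

## Command line

```sh
inst/scripts/motifcontrast seqlogo motif.pfm --out logo.svg
inst/scripts/motifcontrast pair a.pfm b.pfm --out diff.svg
inst/scripts/motifcontrast grid *.pfm --out grid.svg \
    --export-dist D.tsv --export-tree tree.nwk
inst/scripts/motifcontrast fixtures --out-dir examples --seed 1
```

Inputs: JASPAR-style PFM text, plain TSV matrices (counts or
probabilities, either orientation), aligned FASTA. Every figure gets a
numeric TSV sidecar so pipelines never parse images.

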