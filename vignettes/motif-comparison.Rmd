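---
title: "Comparing sequence motifs with difference logos"
author: "MotifContrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sequence motifs with difference logos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifContrast)
```

## The problem

A sequence motif summarizes a set of aligned, equal-length biopolymer
subsequences — transcription-factor binding sites, splice sites, protein
domain columns — as an $L \times |\mathcal{A}|$ matrix of per-position
symbol probabilities $p_{\ell,a}$. The classic sequence logo draws each
position as a stack of letters whose total height is the information
content

$$\mathrm{IC}(p_\ell) = \log_2|\mathcal{A}| + \sum_a p_{\ell,a}\log_2 p_{\ell,a},$$

with each letter's height proportional to its probability. Sequence logos
are excellent for single motifs but poor for *comparing* motifs: two
motifs of the same factor from different cell lines, or two basic
helix-loop-helix factors binding near-identical E-boxes, produce logos
that look the same even when positions differ in ways that matter for
binding-site prediction.

MotifContrast visualizes the *difference* between two motifs directly.

## The difference logo

Positions are compared independently (dependencies between positions are
deliberately neglected to keep the model simple). At position $\ell$,
with distributions $p_\ell$ and $q_\ell$ from the first and second motif:

* the **stack height** is the Jensen–Shannon divergence, in bits,
  $$H_\ell = \tfrac12\,\mathrm{KL}(p_\ell\,\|\,m_\ell) +
            \tfrac12\,\mathrm{KL}(q_\ell\,\|\,m_\ell),\qquad
    m_\ell = \tfrac{p_\ell+q_\ell}{2},$$
  which is symmetric, zero iff $p_\ell=q_\ell$, bounded by 1 bit, and —
  unlike several alternatives — behaves comparably for distributions near
  uniform;
* each **symbol height** is $H_{\ell,a} = r_{\ell,a}\,H_\ell$ with the
  normalized probability difference
  $$r_{\ell,a} = \frac{p_{\ell,a}-q_{\ell,a}}
                      {\sum_{a'}|p_{\ell,a'}-q_{\ell,a'}|}$$
  (zero vector when $p_\ell=q_\ell$).

Symbols losing abundance in the second motif point upward, symbols
gaining abundance point downward; because every gain is some other
symbol's loss, the upward and downward totals are equal at every position
($H_\ell/2$ each when the distributions differ). Summing the stack
heights gives the scalar motif dissimilarity

$$D = \sum_{\ell=1}^{L} H_\ell,$$

which is non-negative, symmetric, zero only for identical motifs, and
additive over concatenated blocks. It is *not* a metric: the
Jensen–Shannon divergence without a square root violates the triangle
inequality, so $D$ is used only as a dissimilarity for clustering and
coloring, never as a distance in a metric embedding.

```{r basics}
a <- probabilityMotif(rbind(c(1, 0, 0, 0)), "dna", label = "allA")
b <- probabilityMotif(rbind(c(0, 1, 0, 0)), "dna", label = "allC")
jsDivergence(c(1, 0, 0, 0), c(0, 1, 0, 0))   # 1 bit, the maximum
motifDissimilarity(a, b)
differenceColumn(c(1, 0, 0, 0), c(0, 1, 0, 0))$symbolHeights
```

Both measures are pluggable. `measurePair()` accepts any stack-height
function $H(p,q)$ and symbol-weight function $r(p,q)$; the registry
(`listMeasures()`) ships `sumAbsProbDiff` ($\sum_a|p_a-q_a|$) and
`infoContentDiff` ($|\mathrm{IC}(p)-\mathrm{IC}(q)|$) as alternative
stack heights and `rawProbDiff` ($p-q$) as an alternative symbol weight.
The registry is a pragmatic selection of the measure families one would
plausibly combine here (probability differences, information divergences,
entropy differences), not an exhaustive catalogue. Note `rawProbDiff`
weights can have absolute sum up to 2, so the "absolute heights sum to
$H_\ell$" identity is specific to the default normalized weights.

## Comparing many motifs

For $N \ge 3$ motifs, `buildComparisonGrid()` computes all pairwise $D$
values, clusters the motifs (`stats::hclust`; complete linkage by
default, average and single selectable — the linkage is a display choice
and never changes $D$), and arranges the $N\times(N-1)$ difference logos
in an $N \times N$ grid with an empty diagonal. Cells opposite each
other across the diagonal are the same comparison with the ordinate
inverted. All cells share one ordinate bound (`commonOrdinate()`), so
stack heights are comparable across cells. Cell backgrounds interpolate
linearly in RGB from green `#00B000` (the most similar off-diagonal
pair) to red `#D00000` (the most dissimilar); when all pairs are equally
dissimilar the interpolation degenerates and every cell is green.

Rows and columns follow the **optimal leaf order** of the cluster tree:
among the $2^{N-1}$ leaf orders reachable by flipping subtrees, the one
minimizing the summed dissimilarity of adjacent leaves. This is the
standard dynamic program over (leftmost, rightmost) leaf pairs per
subtree, re-implemented here and verified in the test suite against
exhaustive enumeration of all flip-consistent orders for $N \le 8$.
Ties are broken deterministically (candidates scanned in label-sorted
order; of the two reversals of an optimum the lexicographically smaller
is returned), so figures are reproducible and independent of the input
order of the motifs.

```{r grid}
ms <- lapply(1:4, function(i)
    randomMotif("dna", 8, concentration = 0.5, seed = i,
                label = paste0("motif", i)))
g <- buildComparisonGrid(ms)
g
round(dissimilarityValues(g), 3)
```

## Numerical conventions

* All logarithms are base 2; every height and $D$ is in **bits**.
* $0\log_2 0 = 0$, and $p\log_2(p/m) = 0$ when $p = 0$; $m > 0$ wherever
  either distribution is positive, so no division by zero arises. This
  continuity convention is what makes the fully-conserved-vs-different
  single-column comparison equal exactly 1 bit.
* The $p_\ell \ne q_\ell$ test in the symbol weights uses tolerance
  1e-12 on the maximum componentwise difference, because inputs come
  from floating-point normalization.
* Probability rows are validated to sum to 1 within a tolerance
  (1e-6 by default, 1e-4 for file input) and then renormalized exactly;
  rows outside tolerance are an error, never silently rescaled.
* Pseudocounts: the library's `countsToProbabilities()` defaults to 0 so
  nothing is smoothed behind the user's back; the command-line interface
  defaults to Laplace smoothing (pseudocount 1) for raw count and
  alignment input, where zero cells are usually sampling artifacts, and
  never smooths input that is already probabilities.
* Unequal motif lengths are an error by default. The optional pad mode
  extends the shorter motif symmetrically with uniform columns (extra
  column on the right when the padding is odd) — the least-assumptive
  padding, since a uniform column against another uniform column
  contributes exactly zero to $D$.
* Gaps and ambiguity codes (`-`, `.`, `N`, `X`, ...) are skipped when
  tallying alignments (the default), so column sums equal the number of
  informative sequences; a position with no informative sequence is a
  hard error. RNA `U` is remapped to `T` only on explicit request.
* Distance matrices are serialized with 9 significant digits so the
  written TSV re-reads within 1e-6 of the in-memory values even for
  long motifs with $D$ well above 1.

## Geometry and rendering choices

Stacks are built backend-independently (`LogoColumns`): within each side
of the axis, segments are placed in ascending absolute height from the
baseline outward, so the most frequent (sequence logo) or most changed
(difference logo) symbol is outermost and most salient; ties are broken
by alphabet order. Zero-height segments are dropped rather than drawn at
zero extent. Sequence logos use a fixed ordinate of $\log_2|\mathcal{A}|$
for comparability; difference logos use a data-driven symmetric ordinate
(1 bit shown when the motifs are identical and there is nothing to
scale).

Letters are built-in polygon outlines, not font glyphs: SVG output is
therefore identical byte-for-byte across systems and repeat runs (no
timestamps, no font metrics), which is what makes figures testable by
parsing rather than pixel comparison. PDF and PNG use the same scene
model through base graphics. Every figure written by the command-line
interface is accompanied by a numeric TSV sidecar (per-position stack
and symbol heights, or the $D$ matrix for grids) so downstream checks
never read pixels.

## The synthetic-motif generator

`randomMotif()` draws each position independently from a symmetric
Dirichlet. Concentration 0.5–1 mimics the mix of conserved and
degenerate columns typical of transcription-factor binding motifs;
concentration well above 10 produces near-uniform, uninformative
columns. The fixture generator (`writeFixtureMotifs()`) emits the four
canonical single-column pairs (divergences 1, 1, 0.5 and 0.25 bits; the
0.25-bit pair's mixing weight is solved numerically at generation time
since only its divergence, not its distributions, is canonical),
Dirichlet motif sets at concentrations 0.5, 1 and 5, and a sampled
40-sequence alignment. What the generator does *not* emulate:
position-position dependencies, alignment errors, sequencing depth
effects, or the biased base composition of real genomes — so passing
tests demonstrate correctness of the computations, not robustness of
biological conclusions drawn from noisy motif estimates.

Test and check problem sizes were chosen to exercise the mathematics at
desk scale: motifs of length 1–12, alphabets of size 4 and 20, 100–10
000 random column pairs per invariant, and exhaustive leaf-order
verification up to $N = 8$ (128 flip-consistent orders).

## Known limitations

* No motif alignment, shifting, or reverse-complement matching before
  comparison: motifs are compared position by position as given.
* No statistical significance for $D$ (no permutation p-values).
* $D$ values depend on motif length; comparing $D$ across motif sets of
  different lengths is not meaningful.
* Log-odds position weight matrices are not accepted as input — there is
  no single convention for their background and base, so only counts and
  probabilities are read.
* MEME, TRANSFAC and HOMER motif formats are not parsed (future work).
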