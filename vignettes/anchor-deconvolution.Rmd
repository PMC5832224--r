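---
title: "Anchor-gene discovery and marker-driven deconvolution of bulk mixtures"
author: "anchorDeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene discovery and marker-driven deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorDeconv)
```

## The problem

Bulk expression profiles of heterogeneous tissue are mixtures.  If $A$ is
the $g \times b$ matrix of pure expression signatures of $b$ biological
processes (or cell types) and $P$ the $b \times s$ matrix of mixing
fractions (each sample column on the probability simplex), the observed
linear-scale data are approximately

$$X \;\approx\; A\,P, \qquad X \in \mathbb{R}_{\ge 0}^{g \times s}.$$

Complete deconvolution — estimating both $A$ and $P$ from $X$ alone — is
ill-posed in general: a non-negative factorisation of a mixture is not
unique.  It becomes well-posed under *separability*: every process owns at
least one gene expressed (effectively) in that process alone.  Such genes
are called **distinguishers** (anchor or marker genes; in topic modelling,
anchor words).  anchorDeconv first finds candidate distinguishers directly
from $X$, then uses them to anchor an alternating estimation of $A$
and $P$.

## The conditional-expression geometry

The search operates on the gene–gene conditional-expression matrix.  With
$Q = XX^{\mathsf T}$, let $\bar{Q}$ be $Q$ with every row rescaled to sum
to one.  Entry $\bar{Q}_{ij}$ is the probability that a second random
sequence fragment falls in gene $j$ given that a first fragment from the
same randomly chosen sample falls in gene $i$.  Each gene is thus a point
in a $g$-dimensional space; rows of genes exclusive to one process are the
*extreme points* of this cloud, and every other row is (approximately) a
convex combination of them.  Anchor search is therefore a farthest-point
problem.

**Factored representation.**  $\bar{Q}$ is $g \times g$ (easily
$20{,}000^2$) and is never materialised.  Row $i$ equals $y_i X^{\mathsf T}$
with $y_i = x_i / d_i$, $d_i = x_i \cdot t$ and $t$ the per-sample totals,
so inner products between rows reduce to $y_i S y_j^{\mathsf T}$ with the
$s \times s$ Gram matrix $S = X^{\mathsf T} X$.  All distances and
projections are computed in this $s$-dimensional coefficient space: the
one-time construction costs $O(g s^2)$ and each subsequent anchor costs
one $O(g s)$ pass.  An explicit small-instance oracle
(`explicitConditionalMatrix()`, capped at 2000 genes) backs the test suite.

## Two-pass anchor selection

1. **First pass** (`firstPass()`): the first tentative distinguisher is the
   gene with the largest $\bar{Q}$ row norm; each next one is the gene whose
   row is farthest from the affine hull of those already chosen (recentring
   on the first anchor, then orthogonal projection of the other anchor
   directions, Gram–Schmidt under the $S$-induced inner product).  Argmax
   ties break to the lowest gene index.
2. **Second pass** (`secondPass()`): a single sweep in selection order
   replaces each anchor by the gene farthest from the affine hull of the
   *other* anchors, so every final distinguisher is farthest from both its
   predecessors and its successors.  The sweep is not iterated to
   convergence; when a replacement occurs, later positions see the updated
   set.  Leave-one-out projections are shared through a divide-and-conquer
   split, costing $O(b \log_2 b)$ sub-basis constructions per sweep instead
   of the naive $b(b-1)$; after a replacement the reuse restarts from the
   next position, since cached states would contain the stale anchor.

The affine-hull formulation (rather than a literal sequential subtraction)
is basis-order independent, which is what makes leave-one-out well defined
when the first anchor itself is left out; the two formulations agree
exactly and the equivalence is asserted against the dense oracle in the
tests.

**Runners-up and bestLengths** (`runnersUp()`): for each process, genes are
ranked by their *signed* scalar projection onto the direction of the
anchor's residual from the other anchors' hull; only genes on the anchor's
side (positive projection) are reported, and the anchor itself need not
rank first.  The first row of the `bestLengths` matrix holds each best
distinguisher's hyperplane distance; scanning it across candidate process
counts (`bestLengthsScan()`) shows a sharp drop once $b$ exceeds the number
of resolvable processes.  No automatic cutoff is applied — like choosing
the number of clusters, this is left to inspection.

## The expression spike

Low-expression genes are relatively noisy, and a gene observed only in one
sample can masquerade as a perfect distinguisher.  Before geometry
construction a constant **spike** is added to every value — by default the
0.75 quantile of the strictly positive entries, with linear interpolation
between order statistics ($h = 1 + (n-1)q$, the common statistical default;
the convention is stated because it makes results bit-reproducible).  For
strongly expressed genes the spike is negligible; for weakly expressed ones
it flattens the conditional profile and demotes them without removing them.
The spike applies to anchor discovery only; deconvolution uses the raw
matrix.  Genes with all-zero rows are dropped first, and the spike is
computed after dropping.

## Marker-driven deconvolution

`deconvolveByDistinguishers()` estimates $P$ and $A$ given marker sets
(typically `markersFromDistinguishers()` output).  Three design choices
matter, all of which exist because the plain alternating scheme is either
unidentifiable or non-monotone:

* **Initialisation** (`initProportionsFromMarkers()`): the mixed profile of
  a gene exclusive to process $k$ is proportional to $P_{k\cdot}$.  Marker
  profiles are rescaled by their maxima and averaged within each set; the
  unknown per-process scales are then calibrated by one small non-negative
  least-squares fit of the score rows against the per-sample sum-to-one
  constraint, and columns are normalised to the simplex.  On noiseless
  mixtures with truly exclusive markers this start is already exact.  The
  max-rescaling assumes each process approaches its maximal proportion in
  some sample; violations degrade only the start, which the refinement
  corrects.
* **Marker exclusivity as a constraint**: in every signature refit, marker
  genes load only on their own process (single-coefficient non-negative
  fit; all other entries fixed at zero).  Without this, the alternation can
  reach a *perfect* reconstruction with the wrong compositions — the
  factorisation is only identifiable through the separability information,
  so the markers must constrain every iteration, not just the start.
* **Exact simplex proportion step**: the per-sample proportion update
  minimises $\lVert x_j - A p \rVert$ over the probability simplex exactly
  (active-face enumeration with a bordered KKT solve), rather than NNLS
  followed by renormalisation.  Renormalisation is a per-sample column
  scaling that the signature step cannot absorb, and it can increase the
  constrained objective; the exact step makes the alternation a true
  coordinate descent, so the residual trace is provably non-increasing.
  The standalone `fitProportions()` keeps the NNLS-plus-renormalise
  contract (scale-invariant partial deconvolution); the exact simplex step
  is used inside the alternation.

All non-negative least-squares subproblems share one design matrix across
thousands of right-hand sides, so they are solved exactly by enumerating
candidate supports ($2^b - 1$ small solves, vectorised over right-hand
sides; exact for $b \le 12$).  The tests cross-check this solver against an
independent single-right-hand-side NNLS implementation.

Convergence is declared when the relative decrease of the Frobenius
residual falls below `tol` (default `1e-8`) or after `maxIter` (default
100) iterations.  If round-off stalls the descent, the previous (better)
iterate is kept; a genuine residual increase aborts with a diagnostic.

## The mixture simulator

`simulateDataset()` generates ground-truthed mixtures with the structure
used throughout the tests:

* **Pure signatures** (`generatePureSignatures()`): each process owns
  `anchorsPerProcess` exclusive genes drawn log-uniformly from
  `anchorRange` (default 200–1000, i.e. strongly expressed, as real marker
  genes tend to be); all remaining genes carry positive log-uniform
  loadings in every process (`backgroundRange`, default 1–100).
  Separability holds by construction and the planted anchors are recorded
  as ground truth.
* **Mixing designs**: independent Dirichlet draws per sample
  (`dirichletProportions()`, default flat $\alpha = 1$) or a fixed table
  (`fixedDesign()`).  The packaged `exampleMixingDesign()` is a synthetic
  10-sample × 5-tissue table in the style of published multi-tissue mixture
  experiments; with one dominant tissue at fraction $d$ and the rest equal,
  the per-sample uniform-baseline RMSE is $0.5(d - 0.2)$, so five samples
  at $d = 0.60$ and five at $d = 0.36$ give a mean baseline of exactly
  0.14 — the conventional "worse than guessing" threshold for this kind of
  design.
* **Noise** (`addLognormalNoise()`): a value $x > 0$ is replaced by a draw
  from the unique log-normal with arithmetic mean $x$ and standard
  deviation $\sigma x$ ($\sigma^2_{\ln} = \ln(1+\sigma^2)$,
  $\mu = \ln x - \sigma^2_{\ln}/2$ — the moment-matched parameterisation).
  Zeros stay zero (a log-normal with mean zero is degenerate).  Replicates
  are independent draws appended as column blocks with `_r<k>` suffixes.

What the simulator does **not** emulate: library-size differences between
samples, count discreteness and overdispersion structure of real RNA-seq,
correlated gene modules, or partial (non-exclusive) markers.  Passing tests
on these mixtures therefore demonstrate correctness of the algorithms under
the separable generative model, not robustness to every artefact of real
data.

## Evaluation

Complete deconvolution recovers components only up to a label permutation.
`alignComponents()` matches estimated to true processes by maximising the
summed Pearson correlation of proportion rows (exhaustive over $b!$,
$b \le 8$); proportions are used for matching because they are the primary
quantity of interest.  Metrics then include the mean per-sample proportions
RMSE (per-sample RMSE over the $b$ components, averaged over samples; a
pooled variant is available via `pooled = TRUE`), per-process Pearson
correlations of signatures, the cosine similarity of the concatenated
aligned signatures on the linear scale, and the uniform-baseline RMSE — the
error of always guessing $1/b$, read as the worse-than-random threshold.

## Problem sizes and reproducibility

The test-suite and `scripts/acceptance.R` study conditions, chosen once as
representative desk-scale versions of the designs above: oracle equivalence
on 100 random instances ($g \le 50$, $s \le 8$); exact-recovery checks on
100 zero-noise datasets ($g = 60$, $b \in 2..5$, $s \in b..20$, two
exclusive anchors per process, spike 0); a noise sweep at $g = 2000$,
$b = 5$, $s = 10$, three replicates, $\sigma \in \{0, 0.1, 0.2, 0.4\}$ over
20 seeds, passing the top-2 ranked distinguishers per process as markers
(two, matching the number of exclusive genes the generator plants); noise
moments on a 3 × 3 $(x, \sigma)$ grid with $10^5$ draws; and a bestLengths
scan over 20 seeds with three true processes at $\sigma = 0.1$.  All
randomness flows through explicit seeds; rerunning any entry point with the
same seed reproduces outputs byte for byte.

## Numerical choices and degenerate inputs

* Residual directions with norm below $10^{-9}$ times the largest row norm
  are treated as degenerate: collinear anchors are skipped with a warning,
  and the passes stop with an informative error when fewer distinct
  directions exist than processes requested.
* Squared residuals are maintained incrementally and clamped at zero;
  distances below $10^{-8}$ (row norms of $\bar{Q}$ are at most 1) are
  numerically zero.
* Argmax ties break to the lowest gene index, making all selections
  deterministic; if a second-pass replacement would duplicate an existing
  anchor (possible only under exact ties), the original anchor is retained
  with a warning.
* `b` must satisfy $2 \le b \le s$; with a single sample every row of
  $\bar{Q}$ coincides and no anchors are resolvable.
* Blank fields in expression tables are parse errors, never imputed;
  negative values are rejected (the method requires linear-scale data).

## Known limitations

* Negative discrimination — using the *absence* of expression as a marker —
  is not implemented.
* Marker exclusivity is a hard constraint; genes that are merely enriched
  (not exclusive) bias the fit when passed as markers, which is why the
  pipeline defaults to a small number of top-ranked distinguishers.
* The alignment and solver enumerations are exact but exponential in $b$;
  practical limits are $b \le 8$ processes for alignment and $b \le 12$ for
  the solvers — generous for tissue deconvolution, but not for fine-grained
  cell atlases.
* No between-sample normalisation or batch correction is applied; samples
  enter the Gram matrix with their library sizes.
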