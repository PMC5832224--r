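# anchorDeconv

Unsupervised discovery of **distinguisher genes** (anchor/marker genes) in
bulk gene-expression mixtures, and marker-driven **complete
deconvolution** of sample compositions and pure signatures.

## The problem

Bulk tissue samples are heterogeneous: each profile mixes several cell
types or biological processes in unknown proportions.  With linear-scale
expression `X` (genes × samples), pure signatures `A` (genes × processes)
and mixing fractions `P` (processes × samples, columns on the simplex),

```
X ≈ A · P
```

Estimating both `A` and `P` from `X` alone is only identifiable under
**separability** — every process owns at least one gene expressed in that
process alone.  anchorDeconv finds such genes directly from the mixed data
by locating the extreme rows of the gene–gene conditional-expression
matrix `Q̄` (row-normalised `X Xᵀ`, whose (i,j) entry is the probability a
second random fragment belongs to gene j given the first belongs to gene
i), then uses them to seed and constrain an alternating non-negative
estimation of `A` and `P`.

The core algorithm is a two-pass greedy farthest-point search: the first
distinguisher is the `Q̄` row of largest norm, subsequent ones are farthest
from the affine hull of those already chosen, and a leave-one-out second
pass replaces anchors that a later selection supersedes.  Everything runs
in a factored geometry (the g×g matrix is never built; O(g·s²)
construction, O(g·s) per anchor), with a constant "expression spike" (the
0.75 quantile of positive values by default) that keeps noisy
low-expression genes from masquerading as markers.  The deconvolution is
alternating non-negative least squares with marker-exclusivity constraints
and an exact per-sample simplex step, which makes the fit identifiable and
its residual trace monotone.

A simulation module generates ground-truthed mixtures (separable
signatures, fixed-table or Dirichlet mixing designs, multiplicative
log-normal noise with mean x and SD σx), and an evaluation module provides
permutation-aligned RMSE, signature correlations, cosine similarity, and
the uniform-guess baseline.

## Worked example

```r
library(anchorDeconv)

# a ground-truthed mixture: 500 genes, 3 processes, 10 samples,
# 20% relative log-normal noise, 3 replicates
ds  <- simulateDataset(g = 500, b = 3, s = 10, sigmaRel = 0.2,
                       replicates = 3, seed = 42)
X   <- observedMatrix(ds)

res <- findDistinguishers(X, b = 3, nPerProcess = 5)
res
#> DistinguisherResult: b = 3 processes, spike = 29.71
#>   anchors: gene0462, gene0440, gene0478
#>   best-distinguisher hyperplane distances: 0.007275, 0.010140, 0.006346

fit <- deconvolveByDistinguishers(X, markersFromDistinguishers(res, 2))
fit
#> DeconvolutionResult: 3 processes x 30 samples; 500 genes
#>   converged: TRUE after 48 iterations; final residual 744.132

Pt <- sampleProportions(ds)[, rep(1:10, 3)]   # truth, per replicate block
evaluateDeconvolution(Pt, sampleProportions(fit),
                      processSignatures(ds), processSignatures(fit))
#> EvaluationReport
#>   mean proportions RMSE:    0.0488375
#>   uniform-baseline RMSE:    0.221649
#>   signature Pearson:        0.9953, 0.9951, 0.9929
#>   concatenated cosine:      0.992395
#>   process matching:         1 2 3
```

Each of the three anchors is one of the generator's planted exclusive
genes (`anchorTruth(ds)`), the estimated compositions have a mean
per-sample RMSE of 0.049 against a worse-than-random threshold of 0.22,
and the recovered signatures correlate > 0.99 with the pure ones.  The
`bestLengths(res)` matrix holds the ranked hyperplane distances behind the
anchor list; scanning its first row over candidate process counts
(`bestLengthsScan()`) is the diagnostic for choosing `b`.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/anchordeconv.R", package="anchorDeconv"))')" \
    simulate --genes 500 --processes 3 --samples 10 --sigma 0.2 \
    --replicates 3 --seed 42 --out-prefix sim_
# then: distinguish / deconvolve / evaluate / scan  (see `help`)
```

Expression tables are tab-separated with quoted sample names on the first
line and a gene id leading each row; marker files are two-column
(process, gene) TSVs.  Lines starting with `#` are comments.

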