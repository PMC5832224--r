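# Ground-truthed synthetic mixtures: separable pure signatures, fixed or
# Dirichlet mixing designs, and multiplicative log-normal noise
# parameterised by its arithmetic mean and relative standard deviation.

.genPureCore <- function(g, b, anchorsPerProcess,
                         anchorRange = c(200, 1000),
                         backgroundRange = c(1, 100)) {
  nAnchor <- b * anchorsPerProcess
  geneIds <- sprintf("gene%04d", seq_len(g))
  procIds <- paste0("proc", seq_len(b))
  # shared genes: positive log-uniform loadings in every process
  A <- matrix(exp(runif(g * b, log(backgroundRange[1L]),
                        log(backgroundRange[2L]))),
              nrow = g, ncol = b, dimnames = list(geneIds, procIds))
  anchorIdx <- sample.int(g, nAnchor)
  owner <- rep(seq_len(b), each = anchorsPerProcess)
  A[anchorIdx, ] <- 0
  A[cbind(anchorIdx, owner)] <-
    exp(runif(nAnchor, log(anchorRange[1L]), log(anchorRange[2L])))
  truth <- split(geneIds[anchorIdx], owner)
  names(truth) <- procIds
  list(signatures = A, anchorTruth = truth)
}

#' Generate separable pure signatures
#'
#' Builds a non-negative genes-by-processes signature matrix in which each
#' process owns `anchorsPerProcess` exclusive, strongly expressed genes
#' (log-uniform in `anchorRange`) while all remaining genes carry positive
#' log-uniform loadings in every process (`backgroundRange`).  Separability
#' -- every process having at least one exclusive anchor gene -- therefore
#' holds by construction.
#'
#' @param g number of genes (>= b * anchorsPerProcess).
#' @param b number of processes.
#' @param anchorsPerProcess exclusive genes designed per process (>= 1).
#' @param seed RNG seed.
#' @param anchorRange,backgroundRange log-uniform expression ranges for
#'   exclusive and shared genes.
#' @return list with elements `signatures` (g x b matrix) and
#'   `anchorTruth` (per-process list of exclusive gene ids).
#' @export
generatePureSignatures <- function(g, b, anchorsPerProcess = 2L, seed = 1L,
                                   anchorRange = c(200, 1000),
                                   backgroundRange = c(1, 100)) {
  g <- as.integer(g); b <- as.integer(b)
  anchorsPerProcess <- as.integer(anchorsPerProcess)
  if (anchorsPerProcess < 1L)
    stop("anchorsPerProcess must be at least 1")
  if (g < b * anchorsPerProcess)
    stop("g too small: need at least b * anchorsPerProcess = ",
         b * anchorsPerProcess, " genes")
  withr::with_seed(seed,
    .genPureCore(g, b, anchorsPerProcess, anchorRange, backgroundRange))
}

.dirichletCore <- function(alpha, s) {
  b <- length(alpha)
  G <- matrix(rgamma(b * s, shape = rep(alpha, s)), nrow = b, ncol = s)
  sweep(G, 2L, colSums(G), "/")
}

#' Draw Dirichlet mixing proportions
#'
#' @param alpha length-b positive concentration vector.
#' @param s number of samples (independent draws).
#' @param seed RNG seed.
#' @return b x s matrix of proportions; every column sums to one.
#' @export
dirichletProportions <- function(alpha, s, seed = 1L) {
  if (!is.numeric(alpha) || any(is.na(alpha)) || any(alpha <= 0))
    stop("alpha entries must be positive")
  P <- withr::with_seed(seed, .dirichletCore(alpha, as.integer(s)))
  dimnames(P) <- list(paste0("proc", seq_along(alpha)),
                      paste0("sample", seq_len(ncol(P))))
  P
}

#' Wrap a fixed mixing-proportion table
#'
#' Validates a processes-by-samples table of mixing fractions: entries must
#' be non-negative and every column is renormalised to sum exactly to one
#' (with a warning when the deviation exceeds 1e-6).
#'
#' @param table b x s numeric matrix or data.frame of proportions.
#' @return validated b x s proportions matrix.
#' @seealso [exampleMixingDesign()] for the packaged 10-sample, 5-tissue
#'   design.
#' @export
fixedDesign <- function(table) {
  P <- as.matrix(table)
  if (!is.numeric(P)) stop("proportion table must be numeric")
  if (any(is.na(P)) || any(P < 0))
    stop("proportion table must be non-negative with no missing values")
  cs <- colSums(P)
  if (any(cs == 0)) stop("proportion column sums to zero")
  if (any(abs(cs - 1) > 1e-6))
    warning("proportion column(s) deviate from sum 1 by more than 1e-6; ",
            "renormalising")
  P <- sweep(P, 2L, cs, "/")
  if (is.null(rownames(P))) rownames(P) <- paste0("proc", seq_len(nrow(P)))
  if (is.null(colnames(P))) colnames(P) <- paste0("sample", seq_len(ncol(P)))
  P
}

#' Packaged 10-sample, 5-tissue mixing design
#'
#' A synthetic fixed mixing table in the style of published multi-tissue
#' mixture experiments: each of the five tissues dominates two of the ten
#' samples (once strongly at 0.60, once mildly at 0.36, the remaining
#' tissues sharing the rest equally).  Its uniform-baseline RMSE -- the
#' error of always guessing equal fractions -- is 0.14.
#'
#' @return 5 x 10 proportions matrix.
#' @export
exampleMixingDesign <- function() {
  path <- system.file("extdata", "mixing_design_10x5_synthetic.tsv",
                      package = "anchorDeconv", mustWork = TRUE)
  src <- .readLinesNoComment(path)
  con <- textConnection(src$lines)
  on.exit(close(con))
  tab <- utils::read.delim(con, row.names = 1L, check.names = FALSE)
  fixedDesign(as.matrix(tab))
}

#' Mix pure signatures into noiseless samples
#'
#' @param signatures g x b non-negative pure signature matrix.
#' @param proportions b x s proportions matrix (columns sum to one).
#' @return g x s noiseless mixed expression matrix `signatures %*%
#'   proportions`.
#' @export
mixSamples <- function(signatures, proportions) {
  A <- as.matrix(signatures); P <- as.matrix(proportions)
  if (ncol(A) != nrow(P))
    stop("shape mismatch: signatures have ", ncol(A),
         " processes but proportions have ", nrow(P))
  X <- A %*% P
  rownames(X) <- rownames(A)
  colnames(X) <- colnames(P)
  X
}

.lognormNoiseCore <- function(X, sigmaRel, replicates) {
  if (sigmaRel == 0) {
    out <- X[, rep(seq_len(ncol(X)), replicates), drop = FALSE]
  } else {
    sl2 <- log(1 + sigmaRel^2)
    sdlog <- sqrt(sl2)
    out <- matrix(0, nrow = nrow(X), ncol = ncol(X) * replicates)
    for (r in seq_len(replicates)) {
      cols <- (r - 1L) * ncol(X) + seq_len(ncol(X))
      block <- X
      pos <- which(block > 0)
      block[pos] <- rlnorm(length(pos),
                           meanlog = log(block[pos]) - sl2 / 2,
                           sdlog = sdlog)
      out[, cols] <- block
    }
    rownames(out) <- rownames(X)
  }
  if (replicates > 1L) {
    colnames(out) <- paste0(rep(colnames(X), replicates), "_r",
                            rep(seq_len(replicates), each = ncol(X)))
  } else {
    colnames(out) <- colnames(X)
  }
  out
}

#' Add multiplicative log-normal noise
#'
#' A noiseless value x > 0 is replaced by a draw from the unique log-normal
#' distribution with arithmetic mean x and standard deviation
#' `sigmaRel * x`: in log space the variance is
#' \eqn{\sigma_{ln}^2 = \log(1 + \sigma^2)} and the mean
#' \eqn{\log x - \sigma_{ln}^2 / 2}.  Zeros stay zero (a log-normal with
#' mean zero is degenerate).  With `replicates > 1` each replicate block is
#' an independent draw and sample ids gain an `_r<k>` suffix.
#'
#' @param X genes-by-samples noiseless matrix.
#' @param sigmaRel relative standard deviation (>= 0; 0 copies the input).
#' @param replicates number of replicate column blocks (>= 1).
#' @param seed RNG seed.
#' @return g x (s * replicates) noised matrix.
#' @export
addLognormalNoise <- function(X, sigmaRel, replicates = 1L, seed = 1L) {
  X <- asExpressionMatrix(X)
  if (!is.numeric(sigmaRel) || length(sigmaRel) != 1L || is.na(sigmaRel) ||
      sigmaRel < 0)
    stop("sigmaRel must be a single non-negative number")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be at least 1")
  withr::with_seed(seed, .lognormNoiseCore(X, sigmaRel, replicates))
}

#' Simulate a ground-truthed mixture dataset
#'
#' Bundles the full generative pipeline: separable pure signatures, a
#' mixing design (Dirichlet draws or a fixed table), noiseless mixing, and
#' log-normal noise with replicate blocks.  Deterministic given `seed`.
#'
#' @param g,b,s genes, processes, samples.  When `table` is given, b and s
#'   are taken from its shape.
#' @param anchorsPerProcess exclusive anchor genes designed per process.
#' @param design "dirichlet" or "table".
#' @param alpha Dirichlet concentration (default flat, rep(1, b)).
#' @param table fixed b x s proportions table (design = "table").
#' @param sigmaRel relative SD of the log-normal noise.
#' @param replicates replicate blocks per sample.
#' @param seed RNG seed.
#' @param anchorRange,backgroundRange passed to the signature generator.
#' @return a [SyntheticDataset-class] object.
#' @examples
#' ds <- simulateDataset(g = 100, b = 4, s = 12, sigmaRel = 0.2,
#'                       replicates = 3, seed = 7)
#' dim(observedMatrix(ds))  # 100 x 36
#' @export
simulateDataset <- function(g, b, s, anchorsPerProcess = 2L,
                            design = c("dirichlet", "table"),
                            alpha = NULL, table = NULL, sigmaRel = 0,
                            replicates = 1L, seed = 1L,
                            anchorRange = c(200, 1000),
                            backgroundRange = c(1, 100)) {
  design <- match.arg(design)
  if (design == "table") {
    if (is.null(table)) stop("design = 'table' requires a proportion table")
    P <- fixedDesign(table)
    b <- nrow(P); s <- ncol(P)
  }
  g <- as.integer(g); b <- as.integer(b); s <- as.integer(s)
  replicates <- as.integer(replicates)
  seed <- as.integer(seed)
  if (is.null(alpha)) alpha <- rep(1, b)
  withr::with_seed(seed, {
    pure <- .genPureCore(g, b, anchorsPerProcess, anchorRange,
                         backgroundRange)
    if (design == "dirichlet") {
      if (length(alpha) != b) stop("alpha must have length b")
      if (any(alpha <= 0)) stop("alpha entries must be positive")
      P <- .dirichletCore(alpha, s)
      dimnames(P) <- list(colnames(pure$signatures),
                          paste0("sample", seq_len(s)))
    } else {
      rownames(P) <- colnames(pure$signatures)
    }
    X0 <- mixSamples(pure$signatures, P)
    obs <- .lognormNoiseCore(X0, sigmaRel, replicates)
    new("SyntheticDataset", signatures = pure$signatures, proportions = P,
        designOrigin = if (design == "table") "fixed_table" else "dirichlet",
        sigmaRel = as.numeric(sigmaRel), replicates = replicates,
        seed = seed, observed = obs, anchorTruth = pure$anchorTruth)
  })
}
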