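# Metrics for comparing estimated compositions and signatures to ground
# truth.  Complete deconvolution recovers components only up to a label
# permutation, so metrics are computed after an optimal matching of
# estimated to true processes.

#' Match estimated processes to true processes
#'
#' Finds the bijection maximising the sum of Pearson correlations between
#' matched proportion rows, by exhaustive search over permutations
#' (b <= 8).  Zero-variance rows contribute correlation 0 with a warning.
#'
#' @param trueP,estP b x s proportions matrices.
#' @return integer vector `perm` with `perm[k]` the estimated process
#'   matched to true process k.
#' @export
alignComponents <- function(trueP, estP) {
  trueP <- as.matrix(trueP); estP <- as.matrix(estP)
  if (!all(dim(trueP) == dim(estP)))
    stop("true and estimated proportions must have equal dimensions")
  b <- nrow(trueP)
  if (b == 1L) return(1L)
  if (b > 8L) stop("alignment by enumeration supports at most 8 processes")
  C <- matrix(0, b, b)
  warned <- FALSE
  for (i in seq_len(b)) for (j in seq_len(b)) {
    if (stats::sd(trueP[i, ]) == 0 || stats::sd(estP[j, ]) == 0) {
      warned <- TRUE
      C[i, j] <- 0
    } else {
      C[i, j] <- cor(trueP[i, ], estP[j, ])
    }
  }
  if (warned)
    warning("constant proportion row(s); correlation treated as 0")
  perms <- .permutations(b)
  scores <- vapply(perms, function(p)
    sum(C[cbind(seq_len(b), p)]), numeric(1))
  as.integer(perms[[which.max(scores)]])
}

#' Mean per-sample RMSE between true and estimated proportions
#'
#' For each sample the root mean squared error over the b components is
#' computed; the reported value is the average across samples.  Set
#' `pooled = TRUE` for a single RMSE over all b * s cells instead.
#'
#' @param trueP,estP b x s proportions matrices.
#' @param permutation alignment from [alignComponents()] (default:
#'   identity).
#' @param pooled use the pooled convention instead of per-sample averaging.
#' @return non-negative scalar.
#' @export
proportionsRMSE <- function(trueP, estP, permutation = NULL,
                            pooled = FALSE) {
  trueP <- as.matrix(trueP); estP <- as.matrix(estP)
  if (!all(dim(trueP) == dim(estP)))
    stop("true and estimated proportions must have equal dimensions")
  if (is.null(permutation)) permutation <- seq_len(nrow(trueP))
  D <- trueP - estP[permutation, , drop = FALSE]
  if (pooled) return(sqrt(mean(D * D)))
  mean(sqrt(colMeans(D * D)))
}

#' RMSE of the uniform-composition guess
#'
#' The error that a constant prediction of equal fractions 1/b would incur
#' against the true design; estimates with a larger RMSE are worse than
#' random guessing.
#'
#' @param trueP b x s true proportions matrix.
#' @param pooled pooled convention flag, as in [proportionsRMSE()].
#' @return non-negative scalar.
#' @export
uniformBaselineRMSE <- function(trueP, pooled = FALSE) {
  trueP <- as.matrix(trueP)
  U <- matrix(1 / nrow(trueP), nrow(trueP), ncol(trueP))
  proportionsRMSE(trueP, U, pooled = pooled)
}

#' Per-process Pearson correlation of signatures
#'
#' @param trueA,estA g x b signature matrices.
#' @param permutation alignment from [alignComponents()] (default:
#'   identity).
#' @return length-b vector of correlations over genes; NA (with a warning)
#'   for zero-variance columns.
#' @export
signatureCorrelations <- function(trueA, estA, permutation = NULL) {
  trueA <- as.matrix(trueA); estA <- as.matrix(estA)
  if (!all(dim(trueA) == dim(estA)))
    stop("true and estimated signatures must have equal dimensions")
  b <- ncol(trueA)
  if (is.null(permutation)) permutation <- seq_len(b)
  out <- numeric(b)
  for (k in seq_len(b)) {
    x <- trueA[, k]; y <- estA[, permutation[k]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance signature column ", k,
              "; correlation undefined")
      out[k] <- NA_real_
    } else {
      out[k] <- cor(x, y)
    }
  }
  out
}

#' Cosine similarity of concatenated signatures
#'
#' The aligned signature matrices are flattened process by process into two
#' long vectors x and y; the returned value is (x . y) / (|x| |y|), on the
#' linear expression scale.
#'
#' @param trueA,estA g x b signature matrices.
#' @param permutation alignment from [alignComponents()] (default:
#'   identity).
#' @return scalar in [-1, 1].
#' @export
concatenatedCosine <- function(trueA, estA, permutation = NULL) {
  trueA <- as.matrix(trueA); estA <- as.matrix(estA)
  if (!all(dim(trueA) == dim(estA)))
    stop("true and estimated signatures must have equal dimensions")
  if (is.null(permutation)) permutation <- seq_len(ncol(trueA))
  x <- as.vector(trueA)
  y <- as.vector(estA[, permutation, drop = FALSE])
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) stop("cosine undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Evaluate a deconvolution against ground truth
#'
#' Aligns estimated to true processes on the proportion rows, then computes
#' the mean per-sample proportions RMSE, the uniform-guess baseline, and --
#' when signatures are supplied -- per-process Pearson correlations and the
#' concatenated cosine similarity.
#'
#' @param trueP,estP b x s proportions matrices.
#' @param trueA,estA optional g x b signature matrices.
#' @return an [EvaluationReport-class] object.
#' @export
evaluateDeconvolution <- function(trueP, estP, trueA = NULL, estA = NULL) {
  perm <- alignComponents(trueP, estP)
  rmse <- proportionsRMSE(trueP, estP, perm)
  base <- uniformBaselineRMSE(trueP)
  if (!is.null(trueA) && !is.null(estA)) {
    pear <- signatureCorrelations(trueA, estA, perm)
    cosv <- concatenatedCosine(trueA, estA, perm)
  } else {
    pear <- rep(NA_real_, nrow(as.matrix(trueP)))
    cosv <- NA_real_
  }
  new("EvaluationReport", permutation = perm, meanRMSE = rmse,
      perProcessPearson = pear, concatenatedCosine = cosv,
      uniformBaselineRMSE = base)
}
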