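# Marker-seeded complete deconvolution: initial proportions from marker
# gene profiles, then alternating non-negative least squares for
# signatures (per gene) and proportions (per sample, renormalised to the
# simplex).

#' Initial proportion estimates from marker gene profiles
#'
#' Each marker gene's expression profile across samples is rescaled by its
#' maximum and profiles are averaged within each marker set, giving a
#' process score per sample.  Because the mixed expression of a gene
#' exclusive to process k is proportional to that process's proportion row,
#' each score row estimates a proportion row up to an unknown per-process
#' scale; the scales are calibrated by a small non-negative least-squares
#' fit of the score rows to the per-sample sum-to-one constraint, and the
#' columns are finally normalised to the simplex.  On noiseless mixtures
#' with truly exclusive markers this initialisation is already exact.
#'
#' @param X genes-by-samples linear expression matrix.
#' @param markers a [MarkerSets-class] object; every marker gene must be a
#'   row of `X`.
#' @return b x s matrix of initial proportions, columns summing to one.
#' @export
initProportionsFromMarkers <- function(X, markers) {
  X <- asExpressionMatrix(X)
  stopifnot(is(markers, "MarkerSets"))
  b <- length(markers@processIds)
  scores <- matrix(0, nrow = b, ncol = ncol(X),
                   dimnames = list(markers@processIds, colnames(X)))
  for (k in seq_len(b)) {
    genes <- markers@members[[k]]
    missing <- setdiff(genes, rownames(X))
    if (length(missing))
      stop("marker gene(s) absent from the expression matrix: ",
           paste(head(missing, 5L), collapse = ", "))
    prof <- X[genes, , drop = FALSE]
    mx <- apply(prof, 1L, max)
    if (any(mx == 0))
      stop("marker gene ", genes[which(mx == 0)[1L]],
           " has zero expression in every sample")
    scores[k, ] <- colMeans(prof / mx)
  }
  cs <- colSums(scores)
  if (any(cs == 0))
    stop("sample ", colnames(X)[which(cs == 0)[1L]],
         " has all-zero marker scores")
  # calibrate per-process scales c >= 0 so that sum_k c_k score_k,j ~ 1
  ones <- matrix(1, nrow = ncol(X), ncol = 1L)
  cvec <- as.vector(.nnlsBatch(t(scores), ones))
  if (all(cvec > 0)) scores <- scores * cvec
  cs <- colSums(scores)
  if (any(cs == 0))
    stop("sample ", colnames(X)[which(cs == 0)[1L]],
         " has all-zero marker scores")
  sweep(scores, 2L, cs, "/")
}

#' Fit pure signatures given proportions
#'
#' Per-gene non-negative least squares of the gene's expression across
#' samples against the proportion rows (shared design, exact batch
#' solver).  When marker sets are supplied, marker genes are treated as
#' exclusive to their process: their signature entries for every other
#' process are fixed at zero and the remaining coefficient is the
#' single-variable non-negative least-squares solution.  This exclusivity
#' constraint is what makes the separable factorisation identifiable when
#' the fit is iterated.
#'
#' @param X genes-by-samples linear expression matrix.
#' @param proportions b x s matrix with columns summing to one.
#' @param markers optional [MarkerSets-class] (process order must match the
#'   rows of `proportions`).
#' @return g x b non-negative signature matrix.
#' @export
fitSignatures <- function(X, proportions, markers = NULL) {
  X <- asExpressionMatrix(X)
  P <- as.matrix(proportions)
  if (ncol(X) != ncol(P))
    stop("X and proportions must have the same number of samples")
  if (ncol(X) < nrow(P))
    stop("need at least as many samples as processes")
  if (any(abs(colSums(P) - 1) > 1e-6))
    stop("proportion columns must sum to one")
  if (qr(t(P))$rank < nrow(P))
    stop("proportions not identifiable: proportion matrix is rank deficient")
  .fitSignaturesCore(X, P, markers)
}

# signature step without the identifiability validation (the alternation
# may pass transiently ill-conditioned proportions; the NNLS enumeration
# simply skips singular supports)
.fitSignaturesCore <- function(X, P, markers = NULL) {
  A <- t(.nnlsBatch(t(P), t(X)))
  if (!is.null(markers)) {
    stopifnot(is(markers, "MarkerSets"))
    if (length(markers@processIds) != nrow(P))
      stop("markers must have one set per proportion row")
    for (k in seq_along(markers@members)) {
      genes <- intersect(markers@members[[k]], rownames(X))
      if (!length(genes)) next
      idx <- match(genes, rownames(X))
      pk <- P[k, ]
      A[idx, ] <- 0
      A[idx, k] <- pmax(0, as.vector(X[idx, , drop = FALSE] %*% pk) /
                          sum(pk * pk))
    }
  }
  dimnames(A) <- list(rownames(X),
                      if (is.null(rownames(P)))
                        paste0("process", seq_len(nrow(P)))
                      else rownames(P))
  A
}

#' Fit proportions given pure signatures
#'
#' Per-sample non-negative least squares of the sample's expression against
#' the signature columns, followed by renormalisation of each sample's
#' coefficients to sum to one.
#'
#' @param X genes-by-samples linear expression matrix.
#' @param signatures g x b non-negative signature matrix of rank b.
#' @return b x s proportions matrix with columns summing to one.
#' @export
fitProportions <- function(X, signatures) {
  X <- asExpressionMatrix(X)
  A <- as.matrix(signatures)
  if (nrow(X) != nrow(A))
    stop("X and signatures must have the same number of genes")
  if (any(A < 0)) stop("signatures must be non-negative")
  if (qr(A)$rank < ncol(A))
    stop("signature matrix is rank deficient")
  P <- .nnlsBatch(A, X)
  cs <- colSums(P)
  if (any(cs == 0))
    stop("all-zero proportion fit for sample ",
         colnames(X)[which(cs == 0)[1L]])
  P <- sweep(P, 2L, cs, "/")
  dimnames(P) <- list(if (is.null(colnames(A)))
                        paste0("process", seq_len(ncol(A)))
                      else colnames(A),
                      colnames(X))
  P
}

# proportion step of the alternation: exact least squares on the
# per-sample probability simplex (not NNLS + renormalisation, which can
# increase the constrained objective and would break monotone descent)
.fitProportionsSimplex <- function(X, A) {
  P <- .simplexLsqBatch(A, X)
  dimnames(P) <- list(colnames(A), colnames(X))
  P
}

#' Complete deconvolution seeded by marker gene sets
#'
#' Initialises proportions from the marker profiles
#' ([initProportionsFromMarkers()]), then alternates a simplex-constrained
#' proportion step with [fitSignatures()] until the relative change of the
#' Frobenius reconstruction residual falls below `tol` or `maxIter`
#' iterations are reached.  Two properties of the alternation are load
#' bearing: marker genes are constrained to be exclusive to their process
#' in every signature refit (without this the non-negative factorisation
#' of a mixture is generally not unique and the alternation can drift to a
#' perfect reconstruction with the wrong compositions), and the proportion
#' step minimises over the per-sample probability simplex exactly, so each
#' half-step is a true coordinate descent and the residual trace is
#' non-increasing.  When numerical round-off stalls the descent the
#' previous (better) iterate is kept and the fit reports convergence.
#'
#' @param X genes-by-samples linear expression matrix (or
#'   SummarizedExperiment).
#' @param markers a [MarkerSets-class]; one set per biological process.
#' @param maxIter maximum number of alternating iterations (0 returns the
#'   initialisation plus a single signature fit).
#' @param tol relative tolerance on the residual decrease.
#' @return a [DeconvolutionResult-class] object.
#' @examples
#' ds <- simulateDataset(g = 60, b = 3, s = 8, seed = 1)
#' mk <- MarkerSets(anchorTruth(ds))
#' fit <- deconvolveByDistinguishers(observedMatrix(ds), mk)
#' round(sampleProportions(fit), 3)
#' @export
deconvolveByDistinguishers <- function(X, markers, maxIter = 100L,
                                       tol = 1e-8) {
  X <- asExpressionMatrix(X)
  maxIter <- as.integer(maxIter)
  if (length(maxIter) != 1L || is.na(maxIter) || maxIter < 0L)
    stop("maxIter must be a non-negative integer")
  P <- initProportionsFromMarkers(X, markers)
  A <- .fitSignaturesCore(X, P, markers)
  rPrev <- .frob(X - A %*% P)
  trace <- rPrev
  converged <- FALSE
  nIter <- 0L
  for (it in seq_len(maxIter)) {
    Pn <- .fitProportionsSimplex(X, A)
    An <- .fitSignaturesCore(X, Pn, markers)
    r <- .frob(X - An %*% Pn)
    if (r > rPrev * (1 + 1e-6) + 1e-9)
      stop("alternating fit failed: reconstruction residual increased ",
           "from ", format(rPrev), " to ", format(r), " at iteration ", it)
    nIter <- it
    if (r >= rPrev) {              # numerical plateau: keep better iterate
      converged <- TRUE
      break
    }
    P <- Pn; A <- An
    trace <- c(trace, r)
    if ((rPrev - r) <= tol * max(rPrev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rPrev <- r
  }
  new("DeconvolutionResult", proportions = P, signatures = A,
      processIds = markers@processIds, converged = converged,
      nIterations = nIter, objectiveTrace = trace)
}
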