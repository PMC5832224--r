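# Internal helpers shared across modules: input coercion/validation,
# batch NNLS, permutation enumeration, and the instrumented op counter.

#' Coerce and validate a linear-scale expression matrix
#'
#' Accepts a numeric matrix (genes in rows, samples in columns) or a
#' \code{SummarizedExperiment} (first assay used).  Values must be finite,
#' non-negative and on a linear (not log) scale; gene and sample identifiers
#' must be unique.  Missing dimnames are filled with \code{gene<i>} /
#' \code{sample<j>}.
#'
#' @param x matrix or SummarizedExperiment.
#' @return a validated numeric matrix with complete dimnames.
#' @export
asExpressionMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input given but the package is not available")
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("expression matrix must have at least one gene and one sample")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (any(x < 0))
    stop("expression matrix contains negative values; linear-scale ",
         "non-negative expression is required")
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate gene identifier(s): ", paste(head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  x
}

# Frobenius norm
.frob <- function(m) sqrt(sum(m * m))

# All permutations of 1..n as a list (n <= 8 guarded by callers)
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", 0L)
  for (p in .permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Batch non-negative least squares with a shared design matrix.
#
# Solves min ||C x - y||^2 subject to x >= 0 for every column y of B.
# Because the design C (n x b) is shared by all right-hand sides and b is
# small (number of biological processes), the exact optimum is found by
# enumerating candidate support sets: for each subset S of columns the
# unconstrained least-squares solution restricted to S is computed for all
# columns at once; among subsets whose solution is feasible (non-negative on
# S) the one with the smallest residual is the NNLS optimum, since the true
# optimal support always yields a feasible candidate.
#
# Returns a b x ncol(B) coefficient matrix.
.nnlsBatch <- function(C, B) {
  b <- ncol(C)
  if (b > 12L)
    stop("batch NNLS supports at most 12 components (got ", b, ")")
  B <- as.matrix(B)
  m <- ncol(B)
  CtC <- crossprod(C)
  CtB <- crossprod(C, B)
  bn2 <- colSums(B * B)
  X <- matrix(0, nrow = b, ncol = m)        # x = 0, the empty support
  bestRes <- bn2
  scale <- max(diag(CtC), .Machine$double.eps)
  negTol <- 1e-9 * (sqrt(max(bn2) / scale) + 1)
  for (mask in seq_len(2L^b - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(b) - 1L)) != 0L)
    A <- CtC[S, S, drop = FALSE]
    sol <- tryCatch(solve(A, CtB[S, , drop = FALSE]), error = function(e) NULL)
    if (is.null(sol)) next
    feas <- colSums(sol < -negTol) == 0L
    if (!any(feas)) next
    solf <- pmax(sol, 0)
    # residual^2 = ||y||^2 - 2 x'C'y + x'C'Cx, columnwise
    res <- bn2 - 2 * colSums(solf * CtB[S, , drop = FALSE]) +
      colSums(solf * (A %*% solf))
    upd <- feas & (res < bestRes - 1e-12 * (bn2 + 1))
    if (any(upd)) {
      X[S, upd] <- solf[, upd, drop = FALSE]
      X[setdiff(seq_len(b), S), upd] <- 0
      bestRes[upd] <- res[upd]
    }
  }
  X
}

# Batch least squares on the probability simplex with a shared design.
#
# Solves min ||A p - y||^2 subject to p >= 0 and sum(p) = 1 for every
# column y of B.  Exact by enumeration of active faces: for each support S
# the minimiser over the face {p_S free, sum = 1} solves the bordered KKT
# system; the global optimum is the best primal-feasible face minimiser
# (its own active face always appears, and every feasible candidate bounds
# the optimum from above).  Singleton faces are always feasible, so a
# solution always exists.
.simplexLsqBatch <- function(A, B) {
  b <- ncol(A)
  if (b > 12L)
    stop("simplex-constrained fit supports at most 12 components")
  B <- as.matrix(B)
  m <- ncol(B)
  CtC <- crossprod(A)
  CtB <- crossprod(A, B)
  bn2 <- colSums(B * B)
  P <- matrix(0, nrow = b, ncol = m)
  bestRes <- rep(Inf, m)
  for (mask in seq_len(2L^b - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(b) - 1L)) != 0L)
    k <- length(S)
    M <- rbind(cbind(CtC[S, S, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    sol <- tryCatch(solve(M, rbind(CtB[S, , drop = FALSE], rep(1, m))),
                    error = function(e) NULL)
    if (is.null(sol)) next
    p <- sol[seq_len(k), , drop = FALSE]
    feas <- colSums(p < -1e-9) == 0L
    if (!any(feas)) next
    p <- pmax(p, 0)
    p <- sweep(p, 2L, colSums(p), "/")
    res <- bn2 - 2 * colSums(p * CtB[S, , drop = FALSE]) +
      colSums(p * (CtC[S, S, drop = FALSE] %*% p))
    upd <- feas & (res < bestRes)
    if (any(upd)) {
      P[S, upd] <- p[, upd, drop = FALSE]
      P[setdiff(seq_len(b), S), upd] <- 0
      bestRes[upd] <- res[upd]
    }
  }
  P
}

# --- instrumented operation counter ---------------------------------------
# Counts basis-direction additions and full g-row projection passes so that
# tests can assert the complexity contracts of the factored geometry.

.opEnv <- new.env(parent = emptyenv())
.opEnv$basisAdds <- 0L
.opEnv$rowPasses <- 0L

.opReset <- function() {
  .opEnv$basisAdds <- 0L
  .opEnv$rowPasses <- 0L
  invisible(NULL)
}

.opCounts <- function() list(basisAdds = .opEnv$basisAdds,
                             rowPasses = .opEnv$rowPasses)

.opBump <- function(adds = 0L, passes = 0L) {
  .opEnv$basisAdds <- .opEnv$basisAdds + adds
  .opEnv$rowPasses <- .opEnv$rowPasses + passes
  invisible(NULL)
}
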