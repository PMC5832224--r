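# Gene filtering and the computational expression spike.  Low-expression
# genes are noisy and make unreliable distinguishers; adding a constant
# low-level expression ("spike") to every value hides the possibility that
# a weakly expressed gene is exclusive to one process, while leaving
# strongly expressed genes essentially unchanged.

#' Drop genes with zero total expression
#'
#' Genes whose expression is zero in every sample carry no information and
#' break the row normalisation of the conditional-expression geometry; they
#' are removed (original order preserved).
#'
#' @param X genes-by-samples matrix (or SummarizedExperiment).
#' @return the matrix restricted to genes with positive row sums.
#' @export
dropZeroGenes <- function(X) {
  X <- asExpressionMatrix(X)
  keep <- rowSums(X) > 0
  if (!any(keep)) stop("no expressed genes: all gene rows sum to zero")
  X[keep, , drop = FALSE]
}

#' Compute the expression spike level
#'
#' By default the spike is the 0.75 quantile of the strictly positive
#' expression values, using linear interpolation between closest order
#' statistics (h = 1 + (n-1) q, i.e. `stats::quantile(..., type = 7)`).
#' An explicit value overrides the quantile.
#'
#' @param X genes-by-samples matrix.
#' @param quantile fraction in [0,1]; default 0.75.
#' @param value optional explicit non-negative spike overriding the
#'   quantile.
#' @return a single non-negative spike level.
#' @export
computeSpike <- function(X, quantile = 0.75, value = NULL) {
  if (!is.null(value)) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < 0)
      stop("explicit spike value must be a single non-negative number")
    return(as.numeric(value))
  }
  if (!is.numeric(quantile) || length(quantile) != 1L || is.na(quantile) ||
      quantile < 0 || quantile > 1)
    stop("spike quantile must be a single number in [0, 1]")
  X <- asExpressionMatrix(X)
  pos <- X[X > 0]
  if (length(pos) == 0L)
    stop("cannot compute spike: no positive expression values ",
         "(supply an explicit value)")
  unname(stats::quantile(pos, probs = quantile, type = 7, names = FALSE))
}

#' Add a constant expression spike to every value
#'
#' @param X genes-by-samples matrix.
#' @param spike single non-negative value to add to every entry.
#' @return the spiked matrix (same ids, same shape).
#' @export
applySpike <- function(X, spike) {
  X <- asExpressionMatrix(X)
  if (!is.numeric(spike) || length(spike) != 1L || is.na(spike) || spike < 0)
    stop("spike must be a single non-negative number")
  X + spike
}
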