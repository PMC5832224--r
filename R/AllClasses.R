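#' Factored gene-gene conditional-expression geometry
#'
#' Holds the implicit representation of the row-normalised conditional
#' expression matrix \eqn{\bar{Q}} derived from a linear-scale expression
#' matrix \eqn{X} (genes x samples) via \eqn{Q = X X^T}, with each row of
#' \eqn{Q} rescaled to sum to one.  Row \eqn{i} of \eqn{\bar{Q}} equals
#' \eqn{y_i X^T} with \eqn{y_i = x_i / d_i} and \eqn{d_i = x_i \cdot t},
#' \eqn{t} the per-sample totals, so all inner products between
#' \eqn{\bar{Q}} rows reduce to \eqn{y_i S y_j^T} with the s-by-s Gram
#' matrix \eqn{S = X^T X}.  Distance and projection queries therefore cost
#' O(s) per gene after a one-time O(g s^2) construction; the g-by-g matrix
#' is never materialised.
#'
#' @slot S s x s Gram matrix \eqn{X^T X}.
#' @slot Y g x s matrix of scaled gene rows \eqn{y_i}.
#' @slot YS cached product \eqn{Y S} used for vectorised queries.
#' @slot d length-g positive normalisers (row sums of \eqn{Q}).
#' @slot rowNorm2 length-g squared Euclidean norms of the \eqn{\bar{Q}} rows.
#' @slot geneIds,sampleIds identifiers carried over from the input matrix.
#' @seealso [buildGeometry()], [affineResidualDistance()]
#' @export
setClass("ConditionalGeometry",
  representation(S = "matrix", Y = "matrix", YS = "matrix", d = "numeric",
                 rowNorm2 = "numeric", geneIds = "character",
                 sampleIds = "character"))

setValidity("ConditionalGeometry", function(object) {
  msg <- character(0)
  g <- nrow(object@Y); s <- ncol(object@Y)
  if (!all(dim(object@S) == c(s, s))) msg <- c(msg, "S must be s x s")
  if (!all(dim(object@YS) == c(g, s))) msg <- c(msg, "YS must be g x s")
  if (length(object@d) != g) msg <- c(msg, "d must have one entry per gene")
  if (any(object@d <= 0)) msg <- c(msg, "all row normalisers d must be > 0")
  if (length(object@geneIds) != g) msg <- c(msg, "geneIds length mismatch")
  if (length(object@sampleIds) != s) msg <- c(msg, "sampleIds length mismatch")
  if (length(msg)) msg else TRUE
})

#' Orthonormal projection basis for an anchor set
#'
#' Internal product of the incremental affine-hull machinery: the first
#' anchor's conditional-expression row is the affine origin and the
#' remaining anchors contribute directions orthonormalised under the
#' S-induced inner product.  Directions are stored as length-s coefficient
#' vectors (a direction u represents the g-vector \eqn{u X^T}).
#'
#' @slot originGene index of the origin anchor (0 when the basis is empty).
#' @slot origin length-s coefficient vector of the origin row.
#' @slot directions s x k matrix of orthonormal direction coefficients.
#' @export
setClass("ProjectionBasis",
  representation(originGene = "integer", origin = "numeric",
                 directions = "matrix"))

#' Marker gene sets, one per biological process
#'
#' @slot processIds process (cell type) identifiers, in order.
#' @slot members list of character vectors of gene identifiers, one per
#'   process, disjoint across processes.
#' @seealso [readMarkerSets()], [markersFromDistinguishers()]
#' @export
setClass("MarkerSets",
  representation(processIds = "character", members = "list"))

setValidity("MarkerSets", function(object) {
  msg <- character(0)
  b <- length(object@processIds)
  if (b < 1L) msg <- c(msg, "at least one process required")
  if (length(object@members) != b)
    msg <- c(msg, "one member list per process required")
  if (anyDuplicated(object@processIds))
    msg <- c(msg, "duplicate process identifiers")
  genes <- unlist(object@members, use.names = FALSE)
  if (any(!nzchar(genes))) msg <- c(msg, "empty gene identifier")
  if (anyDuplicated(genes))
    msg <- c(msg, paste0("gene(s) assigned to more than one process: ",
                         paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "every process needs at least one marker gene")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerSets object
#'
#' @param members named list of character vectors (names = process ids), or
#'   an unnamed list with `processIds` supplied separately.
#' @param processIds optional character vector of process identifiers.
#' @return a [MarkerSets-class] object.
#' @export
MarkerSets <- function(members, processIds = names(members)) {
  if (is.null(processIds))
    processIds <- paste0("process", seq_along(members))
  obj <- new("MarkerSets", processIds = as.character(processIds),
             members = lapply(members, as.character))
  validObject(obj)
  obj
}

#' Result of a distinguisher-gene search
#'
#' @slot b number of biological processes sought.
#' @slot anchors integer indices (into the retained gene set) of the final
#'   distinguishers, in selection order.
#' @slot anchorIds gene identifiers of the final distinguishers.
#' @slot runnersUp list (one data.frame per process) with columns
#'   \code{gene_id} and \code{distance}, ranked by decreasing signed
#'   distance from the other processes' hyperplane.
#' @slot bestLengths numeric matrix, one column per process; row r holds the
#'   r-th ranked distance (0-padded).  Its first row is the hyperplane
#'   distance of each best distinguisher -- a sudden drop across increasing
#'   b flags an over-estimated number of processes.
#' @slot spike the expression spike that was added before geometry
#'   construction.
#' @slot geneIds identifiers of the genes retained after filtering.
#' @export
setClass("DistinguisherResult",
  representation(b = "integer", anchors = "integer", anchorIds = "character",
                 runnersUp = "list", bestLengths = "matrix",
                 spike = "numeric", geneIds = "character"))

setValidity("DistinguisherResult", function(object) {
  msg <- character(0)
  if (length(object@anchors) != object@b)
    msg <- c(msg, "need exactly b anchors")
  if (anyDuplicated(object@anchors)) msg <- c(msg, "anchors must be distinct")
  if (length(object@runnersUp) != object@b)
    msg <- c(msg, "one runners-up table per process required")
  for (df in object@runnersUp) {
    if (!all(c("gene_id", "distance") %in% names(df))) {
      msg <- c(msg, "runners-up tables need gene_id and distance columns")
      break
    }
    if (any(df$distance < 0) || is.unsorted(rev(df$distance)))
      msg <- c(msg, "runners-up distances must be non-negative, descending")
  }
  if (ncol(object@bestLengths) != object@b)
    msg <- c(msg, "bestLengths needs one column per process")
  if (length(msg)) msg else TRUE
})

#' Result of marker-seeded deconvolution
#'
#' @slot proportions b x s matrix of mixing fractions; columns sum to one.
#' @slot signatures g x b non-negative matrix of pure per-process signatures.
#' @slot processIds process identifiers.
#' @slot converged whether the alternating fit met the tolerance.
#' @slot nIterations number of alternating iterations performed.
#' @slot objectiveTrace Frobenius reconstruction residual after each
#'   signature refit (non-increasing).
#' @export
setClass("DeconvolutionResult",
  representation(proportions = "matrix", signatures = "matrix",
                 processIds = "character", converged = "logical",
                 nIterations = "integer", objectiveTrace = "numeric"))

setValidity("DeconvolutionResult", function(object) {
  msg <- character(0)
  if (any(object@proportions < 0) || any(object@signatures < 0))
    msg <- c(msg, "proportions and signatures must be non-negative")
  cs <- colSums(object@proportions)
  if (any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "proportion columns must sum to 1 (tol 1e-9)")
  tr <- object@objectiveTrace
  if (length(tr) > 1L &&
      any(diff(tr) > 1e-9 * (abs(tr[-length(tr)]) + 1)))
    msg <- c(msg, "objective trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Ground-truthed synthetic mixture dataset
#'
#' @slot signatures g x b true pure signatures.
#' @slot proportions b x s true mixing fractions (columns sum to one).
#' @slot designOrigin "fixed_table" or "dirichlet".
#' @slot sigmaRel relative standard deviation of the multiplicative
#'   log-normal noise.
#' @slot replicates number of independently-noised replicates per sample.
#' @slot seed RNG seed the dataset was generated from.
#' @slot observed g x (s * replicates) observed mixed expression matrix.
#' @slot anchorTruth list, per process, of the designed exclusive gene ids.
#' @export
setClass("SyntheticDataset",
  representation(signatures = "matrix", proportions = "matrix",
                 designOrigin = "character", sigmaRel = "numeric",
                 replicates = "integer", seed = "integer",
                 observed = "matrix", anchorTruth = "list"))

setValidity("SyntheticDataset", function(object) {
  msg <- character(0)
  if (any(object@observed < 0)) msg <- c(msg, "observed must be non-negative")
  if (ncol(object@observed) !=
      ncol(object@proportions) * object@replicates)
    msg <- c(msg, "observed must have s * replicates columns")
  if (length(msg)) msg else TRUE
})

#' Accuracy report for a deconvolution against ground truth
#'
#' @slot permutation integer vector mapping true process k to the matched
#'   estimated process.
#' @slot meanRMSE mean over samples of the per-sample RMSE between true and
#'   aligned estimated proportions.
#' @slot perProcessPearson per-process Pearson correlation between true and
#'   aligned estimated signatures (NA when signatures were not supplied).
#' @slot concatenatedCosine cosine similarity of the concatenated aligned
#'   signatures (NA when not supplied).
#' @slot uniformBaselineRMSE RMSE of the constant uniform (1/b) guess
#'   against the true proportions; estimates above it are worse than random.
#' @export
setClass("EvaluationReport",
  representation(permutation = "integer", meanRMSE = "numeric",
                 perProcessPearson = "numeric",
                 concatenatedCosine = "numeric",
                 uniformBaselineRMSE = "numeric"))
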