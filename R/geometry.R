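# Factored representation of the gene-gene conditional-expression matrix.
#
# With X the g x s linear expression matrix, Q = X X^T and Q-bar is Q with
# each row rescaled to sum to one; its (i,j) entry is the probability that
# a second random sequence fragment belongs to gene j given that a first
# fragment from the same randomly chosen sample belongs to gene i.
# Distinguisher discovery only needs inner products between Q-bar rows,
# and row i of Q-bar equals y_i X^T with y_i = x_i / d_i, so
# <row_i, row_j> = y_i S y_j^T with S = X^T X.  Everything below works in
# this s-dimensional coefficient space; the g x g matrix never exists.

# Relative tolerance below which a residual direction is considered
# degenerate (collinear anchors).
.DEG_TOL <- 1e-9

#' Build the factored conditional-expression geometry
#'
#' Constructs the implicit representation of the row-normalised
#' conditional-expression matrix in O(g s^2) time and O(g s) memory.
#'
#' @param X genes-by-samples linear expression matrix; every gene row must
#'   have a positive sum (see [dropZeroGenes()]).
#' @return a [ConditionalGeometry-class] object.
#' @examples
#' X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' geom <- buildGeometry(X)
#' affineResidualDistance(geom, 1, integer(0))  # sqrt(0.5)
#' @export
buildGeometry <- function(X) {
  X <- asExpressionMatrix(X)
  tot <- colSums(X)                  # per-sample totals over genes
  d <- as.vector(X %*% tot)          # row sums of Q = X X^T
  if (any(d <= 0)) {
    bad <- rownames(X)[which(d <= 0)[1L]]
    stop("gene with zero total expression: ", bad,
         " (drop zero genes before building the geometry)")
  }
  S <- crossprod(X)                  # s x s Gram matrix
  Y <- X / d
  YS <- Y %*% S
  new("ConditionalGeometry", S = S, Y = Y, YS = YS, d = d,
      rowNorm2 = unname(rowSums(YS * Y)),
      geneIds = rownames(X), sampleIds = colnames(X))
}

#' Explicit conditional-expression matrix (small-instance oracle)
#'
#' Materialises the dense row-normalised g x g conditional-expression
#' matrix.  Intended as a test oracle and for inspection of small
#' instances only; refuses to run beyond 2000 genes.
#'
#' @param X genes-by-samples linear expression matrix.
#' @return dense g x g matrix with rows summing to one.
#' @export
explicitConditionalMatrix <- function(X) {
  X <- asExpressionMatrix(X)
  if (nrow(X) > 2000L)
    stop("explicit conditional matrix refused for g > 2000 genes; ",
         "use the factored geometry instead")
  Q <- tcrossprod(X)
  d <- rowSums(Q)
  if (any(d <= 0))
    stop("gene with zero total expression: ",
         rownames(X)[which(d <= 0)[1L]])
  Q / d
}

# --- incremental affine-hull basis ----------------------------------------
# A basis state tracks, for an anchor set, the affine origin (first anchor's
# coefficient vector), the orthonormal directions spanning the differences
# of the other anchors from the origin (under the S inner product), and the
# squared residual distance of every gene's Q-bar row from the anchors'
# affine hull.  Adding one anchor costs one g-row pass (O(g s)).

.basisEmpty <- function(geom) {
  list(originGene = 0L, origin = NULL, originS = NULL,
       dirs = matrix(0, nrow = ncol(geom@Y), ncol = 0L),
       Sdirs = matrix(0, nrow = ncol(geom@Y), ncol = 0L),
       originProj = numeric(0),
       res2 = geom@rowNorm2)
}

# Add anchor (gene index a) to a basis state.  Returns the updated state;
# when the new direction is numerically collinear with the existing hull
# the state is returned unchanged with attribute "degenerate" set.
.basisAdd <- function(geom, st, a) {
  .opBump(adds = 1L, passes = 1L)
  if (st$originGene == 0L) {
    o <- geom@Y[a, ]
    So <- as.vector(geom@S %*% o)
    oo <- sum(o * So)
    q <- as.vector(geom@Y %*% So)    # y_i . S o for all genes
    st$originGene <- a
    st$origin <- o
    st$originS <- So
    st$res2 <- pmax(geom@rowNorm2 - 2 * q + oo, 0)
    return(st)
  }
  v <- geom@Y[a, ] - st$origin
  if (ncol(st$dirs) > 0L) {
    coefs <- as.vector(crossprod(st$Sdirs, v))
    v <- v - as.vector(st$dirs %*% coefs)
  }
  Sv <- as.vector(geom@S %*% v)
  n2 <- sum(v * Sv)
  maxNorm <- sqrt(max(geom@rowNorm2))
  if (sqrt(max(n2, 0)) < .DEG_TOL * maxNorm) {
    attr(st, "degenerate") <- TRUE
    return(st)
  }
  u <- v / sqrt(n2)
  Su <- Sv / sqrt(n2)
  # <z_i, u>_S = y_i S u - origin S u  for all genes, one O(g s) pass
  proj <- as.vector(geom@Y %*% Su) - sum(st$origin * Su)
  st$dirs <- cbind(st$dirs, u, deparse.level = 0)
  st$Sdirs <- cbind(st$Sdirs, Su, deparse.level = 0)
  st$res2 <- pmax(st$res2 - proj * proj, 0)
  st
}

.buildBasis <- function(geom, anchors) {
  st <- .basisEmpty(geom)
  for (a in anchors) {
    st <- .basisAdd(geom, st, a)
    if (isTRUE(attr(st, "degenerate"))) {
      warning("anchor ", geom@geneIds[a],
              " is collinear with the existing anchor hull; skipped")
      attr(st, "degenerate") <- NULL
    }
  }
  st
}

# Residual coefficient vector of one gene's row relative to a basis state
# (in coefficient space), plus its squared S-norm.
.residualVector <- function(geom, st, gene) {
  if (st$originGene == 0L) {
    z <- geom@Y[gene, ]
  } else {
    z <- geom@Y[gene, ] - st$origin
  }
  if (ncol(st$dirs) > 0L) {
    coefs <- as.vector(crossprod(st$Sdirs, z))
    z <- z - as.vector(st$dirs %*% coefs)
  }
  z
}

# Signed scalar projections of every gene's residual onto the unit residual
# direction of `target`; one O(g s) pass.
.signedDistances <- function(geom, st, target) {
  w <- .residualVector(geom, st, target)
  Sw <- as.vector(geom@S %*% w)
  wn <- sqrt(max(sum(w * Sw), 0))
  maxNorm <- sqrt(max(geom@rowNorm2))
  if (wn < .DEG_TOL * maxNorm)
    stop("target lies in anchor hull: gene ", geom@geneIds[target],
         " has no residual direction")
  Su <- Sw / wn
  .opBump(passes = 1L)
  val <- as.vector(geom@Y %*% Su)
  if (st$originGene != 0L) val <- val - sum(st$origin * Su)
  val
}

#' Distance of a gene's conditional-expression row from an anchor hull
#'
#' Euclidean distance between the gene's row of the conditional-expression
#' matrix and the affine hull of the anchors' rows, computed through the
#' factored geometry.  With no anchors this is the row's norm (the
#' first-anchor selection criterion); with one anchor it is the distance to
#' that anchor's row; in general the row is recentred on the first anchor
#' and the remaining anchor directions are projected out.
#'
#' @param geom a [ConditionalGeometry-class].
#' @param gene gene index (or id).
#' @param anchors integer vector of anchor gene indices (possibly empty).
#' @return a non-negative distance; exactly 0 when `gene` is an anchor.
#' @export
affineResidualDistance <- function(geom, gene, anchors = integer(0)) {
  stopifnot(is(geom, "ConditionalGeometry"))
  gene <- .resolveGene(geom, gene)
  anchors <- .resolveGene(geom, anchors)
  if (gene %in% anchors) return(0)
  st <- .buildBasis(geom, anchors)
  sqrt(st$res2[gene])
}

#' Signed distance along a target distinguisher's direction
#'
#' Residuals (after projecting out the anchors' affine hull) are compared
#' along the unit direction of the target gene's residual: the returned
#' scalar projection is positive for genes on the target's side of the
#' hyperplane.  This is the ranking criterion for runners-up.
#'
#' @param geom a [ConditionalGeometry-class].
#' @param gene gene index (or id) to score.
#' @param anchors anchor gene indices (the hull); must not contain `target`.
#' @param target gene index whose residual direction defines the axis.
#' @return signed scalar projection; 0 for genes inside the hull.
#' @export
signedDirectionDistance <- function(geom, gene, anchors, target) {
  stopifnot(is(geom, "ConditionalGeometry"))
  gene <- .resolveGene(geom, gene)
  anchors <- .resolveGene(geom, anchors)
  target <- .resolveGene(geom, target)
  if (target %in% anchors)
    stop("target must not be one of the anchors")
  st <- .buildBasis(geom, anchors)
  val <- .signedDistances(geom, st, target)
  val[anchors] <- 0
  val[gene]
}

#' Projection basis for an anchor set
#'
#' Exposes the orthonormal basis (under the S-induced inner product) that
#' the incremental machinery builds for an anchor set; mainly useful for
#' inspection and testing.
#'
#' @param geom a [ConditionalGeometry-class].
#' @param anchors anchor gene indices.
#' @return a [ProjectionBasis-class] object.
#' @export
projectionBasis <- function(geom, anchors) {
  stopifnot(is(geom, "ConditionalGeometry"))
  anchors <- .resolveGene(geom, anchors)
  st <- .buildBasis(geom, anchors)
  new("ProjectionBasis",
      originGene = as.integer(st$originGene),
      origin = if (st$originGene == 0L) numeric(0) else st$origin,
      directions = st$dirs)
}

# map gene ids to indices (integers pass through, with bounds check)
.resolveGene <- function(geom, gene) {
  if (length(gene) == 0L) return(integer(0))
  if (is.character(gene)) {
    idx <- match(gene, geom@geneIds)
    if (anyNA(idx))
      stop("unknown gene id(s): ",
           paste(gene[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(gene)
  if (any(idx < 1L | idx > nrow(geom@Y)))
    stop("gene index out of range")
  idx
}
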