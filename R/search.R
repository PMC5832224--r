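# Two-pass greedy distinguisher selection, runners-up ranking, and the
# bestLengths diagnostic.

#' First pass: greedy farthest-point anchor selection
#'
#' The first tentative distinguisher is the gene whose conditional-
#' expression row has the largest Euclidean norm.  Each subsequent one is
#' the gene whose row is farthest from the affine hull of those already
#' selected (recentring on the first anchor, then orthogonal projection).
#' Ties are broken by the lowest gene index.
#'
#' @param geom a [ConditionalGeometry-class].
#' @param b number of biological processes sought; must satisfy
#'   2 <= b <= number of samples.
#' @return integer vector of b tentative anchor gene indices, in selection
#'   order.
#' @export
firstPass <- function(geom, b) {
  stopifnot(is(geom, "ConditionalGeometry"))
  s <- length(geom@sampleIds)
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 2L || b > s)
    stop("b must satisfy 2 <= b <= number of samples (s = ", s, ")")
  maxNorm <- sqrt(max(geom@rowNorm2))
  st <- .basisEmpty(geom)
  anchors <- integer(0)
  for (k in seq_len(b)) {
    best <- unname(which.max(st$res2))
    if (sqrt(st$res2[best]) < .DEG_TOL * maxNorm)
      stop("geometry degenerate: only ", k - 1L,
           " distinct directions exist but b = ", b, " anchors requested")
    anchors <- c(anchors, best)
    st <- .basisAdd(geom, st, best)
    if (isTRUE(attr(st, "degenerate")))
      stop("geometry degenerate: only ", k - 1L,
           " distinct directions exist but b = ", b, " anchors requested")
  }
  anchors
}

# Leave-one-out divide-and-conquer sweep.  Evaluates, for each position in
# pos..b (in order), the argmax of the residual distance given all other
# current anchors, reusing sub-basis constructions: each recursion level
# adds each anchor to at most one branch state, so the whole sweep performs
# O(b log2 b) basis additions instead of the naive b (b - 1).
# Returns list(pos, gene) for the first position where a replacement is
# warranted, or NULL if the sweep completes without replacement.
.looSweep <- function(geom, anchors, from) {
  b <- length(anchors)
  base <- .basisEmpty(geom)
  for (a in anchors[seq_len(from - 1L)]) base <- .basisAdd(geom, base, a)
  recurse <- function(st, idxs) {
    if (length(idxs) == 1L) {
      pos <- idxs
      cur <- anchors[pos]
      best <- unname(which.max(st$res2))
      if (best != cur && !(best %in% anchors)) return(list(pos = pos, gene = best))
      if (best != cur && best %in% anchors[-pos]) {
        warning("second pass: candidate replacement for position ", pos,
                " duplicates an existing anchor; original retained")
      }
      return(NULL)
    }
    mid <- length(idxs) %/% 2L
    left <- idxs[seq_len(mid)]
    right <- idxs[-seq_len(mid)]
    stL <- st
    for (a in anchors[right]) stL <- .basisAdd(geom, stL, a)
    out <- recurse(stL, left)
    if (!is.null(out)) return(out)
    stR <- st
    for (a in anchors[left]) stR <- .basisAdd(geom, stR, a)
    recurse(stR, right)
  }
  recurse(base, seq.int(from, b))
}

#' Second pass: leave-one-out refinement of the anchors
#'
#' A single sweep over the anchor positions in selection order: each anchor
#' is replaced by the gene farthest from the affine hull of the other
#' anchors, so that every final distinguisher is farthest not only from the
#' previously selected but also from the subsequently selected ones.
#' Sub-basis projections are reused through a divide-and-conquer split
#' (O(b log2 b) basis constructions per sweep segment); after a replacement
#' the reuse is restarted from the next position with the updated set.
#'
#' @param geom a [ConditionalGeometry-class].
#' @param anchors integer anchor indices from [firstPass()].
#' @return integer vector of final anchor indices, order preserved.
#' @export
secondPass <- function(geom, anchors) {
  stopifnot(is(geom, "ConditionalGeometry"))
  anchors <- .resolveGene(geom, anchors)
  b <- length(anchors)
  if (b < 2L) return(anchors)
  pos <- 1L
  while (pos <= b) {
    upd <- .looSweep(geom, anchors, pos)
    if (is.null(upd)) break
    anchors[upd$pos] <- upd$gene
    pos <- upd$pos + 1L
  }
  anchors
}

#' Rank runners-up and assemble the bestLengths diagnostic
#'
#' For each process k the genes are ranked by their signed scalar
#' projection onto the direction of anchor k's residual from the affine
#' hull of the other anchors; only genes on the anchor's side (positive
#' projection) are kept, and the `nPerProcess` most distant are returned.
#' The anchor itself need not rank first.  The bestLengths matrix collects
#' the r-th ranked distance of each process in row r (0-padded).
#'
#' @param geom a [ConditionalGeometry-class].
#' @param anchors final anchor indices (after [secondPass()]).
#' @param nPerProcess number of ranked genes to keep per process.
#' @param spike spike level recorded in the result (metadata only).
#' @return a [DistinguisherResult-class] object.
#' @export
runnersUp <- function(geom, anchors, nPerProcess, spike = NA_real_) {
  stopifnot(is(geom, "ConditionalGeometry"))
  anchors <- .resolveGene(geom, anchors)
  nPerProcess <- as.integer(nPerProcess)
  if (length(nPerProcess) != 1L || is.na(nPerProcess) || nPerProcess < 1L)
    stop("nPerProcess must be a positive integer")
  b <- length(anchors)
  lists <- vector("list", b)
  bl <- matrix(0, nrow = nPerProcess, ncol = b,
               dimnames = list(NULL, geom@geneIds[anchors]))
  for (k in seq_len(b)) {
    st <- .buildBasis(geom, anchors[-k])
    sd <- .signedDistances(geom, st, anchors[k])
    sd[anchors[-k]] <- 0
    keep <- which(sd > 0)
    ord <- keep[order(sd[keep], decreasing = TRUE)]
    ord <- head(ord, nPerProcess)
    lists[[k]] <- data.frame(gene_id = geom@geneIds[ord],
                             distance = sd[ord],
                             stringsAsFactors = FALSE)
    if (length(ord))
      bl[seq_along(ord), k] <- sd[ord]
  }
  new("DistinguisherResult", b = b, anchors = anchors,
      anchorIds = geom@geneIds[anchors], runnersUp = lists,
      bestLengths = bl, spike = as.numeric(spike),
      geneIds = geom@geneIds)
}

#' Find distinguisher genes in a mixed expression matrix
#'
#' End-to-end pipeline: drop all-zero genes, compute and add the expression
#' spike, build the factored conditional-expression geometry, run the
#' greedy first pass and the leave-one-out second pass, and rank
#' runners-up.  Fully deterministic.
#'
#' @param X genes-by-samples linear expression matrix (or
#'   SummarizedExperiment).
#' @param b number of biological processes sought (2 <= b <= samples).
#' @param nPerProcess number of ranked distinguishers returned per process.
#' @param spikeQuantile quantile of positive values used for the spike
#'   (default 0.75); ignored when `spikeValue` is given.
#' @param spikeValue optional explicit spike level (0 disables spiking).
#' @return a [DistinguisherResult-class] object.
#' @examples
#' ds <- simulateDataset(g = 60, b = 3, s = 8, seed = 1)
#' res <- findDistinguishers(observedMatrix(ds), b = 3, nPerProcess = 5)
#' anchorGenes(res)
#' @export
findDistinguishers <- function(X, b, nPerProcess = 10L,
                               spikeQuantile = 0.75, spikeValue = NULL) {
  X <- dropZeroGenes(X)
  spike <- computeSpike(X, quantile = spikeQuantile, value = spikeValue)
  Xs <- applySpike(X, spike)
  geom <- buildGeometry(Xs)
  anchors <- firstPass(geom, b)
  anchors <- secondPass(geom, anchors)
  runnersUp(geom, anchors, nPerProcess, spike = spike)
}

#' Scan the bestLengths diagnostic over candidate process counts
#'
#' Runs the full two-pass selection for every b in 2..bMax and reports the
#' first row of the bestLengths matrix (the hyperplane distance of each
#' best distinguisher).  A sudden drop of these values past some b
#' indicates that asking for more biological processes is questionable;
#' inspection is left to the user, no automatic cutoff is applied.
#'
#' @param X genes-by-samples linear expression matrix.
#' @param bMax largest number of processes to try (<= number of samples).
#' @param spikeQuantile,spikeValue spike configuration as in
#'   [findDistinguishers()].
#' @return numeric matrix with one row per b (rownames "b=2"...), columns
#'   1..bMax holding the first-row bestLengths values, NA-padded.
#' @export
bestLengthsScan <- function(X, bMax, spikeQuantile = 0.75,
                            spikeValue = NULL) {
  X <- dropZeroGenes(X)
  bMax <- as.integer(bMax)
  if (length(bMax) != 1L || is.na(bMax) || bMax < 2L || bMax > ncol(X))
    stop("bMax must satisfy 2 <= bMax <= number of samples")
  spike <- computeSpike(X, quantile = spikeQuantile, value = spikeValue)
  geom <- buildGeometry(applySpike(X, spike))
  out <- matrix(NA_real_, nrow = bMax - 1L, ncol = bMax,
                dimnames = list(paste0("b=", 2:bMax), NULL))
  for (b in 2:bMax) {
    anchors <- secondPass(geom, firstPass(geom, b))
    for (k in seq_len(b)) {
      st <- .buildBasis(geom, anchors[-k])
      sd <- .signedDistances(geom, st, anchors[k])
      sd[anchors[-k]] <- 0
      out[b - 1L, k] <- max(sd)
    }
  }
  out
}

#' Build disjoint marker sets from a distinguisher result
#'
#' Runners-up lists of different processes can overlap on noisy data; a
#' gene appearing in several lists is assigned to the process where its
#' distance is largest, so the result satisfies the disjointness contract
#' of [MarkerSets-class].
#'
#' @param result a [DistinguisherResult-class].
#' @param nPerProcess optional cap on markers kept per process (default:
#'   all available).
#' @return a [MarkerSets-class] object.
#' @export
markersFromDistinguishers <- function(result, nPerProcess = NULL) {
  stopifnot(is(result, "DistinguisherResult"))
  tabs <- result@runnersUp
  b <- result@b
  all <- do.call(rbind, lapply(seq_len(b), function(k)
    cbind(tabs[[k]], process = k)))
  # keep each gene only where its distance is largest
  all <- all[order(-all$distance), ]
  all <- all[!duplicated(all$gene_id), ]
  members <- lapply(seq_len(b), function(k) {
    gk <- all[all$process == k, ]
    gk <- gk[order(-gk$distance), "gene_id"]
    if (!is.null(nPerProcess)) gk <- head(gk, nPerProcess)
    gk
  })
  if (any(lengths(members) == 0L))
    stop("process ", which(lengths(members) == 0L)[1L],
         " retained no markers after resolving overlaps")
  MarkerSets(members, processIds = result@anchorIds)
}
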