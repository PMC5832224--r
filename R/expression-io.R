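# Readers and writers for the tab-separated expression-table dialect
# (first line: quoted sample names; first column: gene/probe id) and for
# two-column marker-set files.  Lines starting with '#' are comments.

.stripQuotes <- function(x) sub('^["\']?(.*?)["\']?$', "\\1", x)

.readLinesNoComment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#")
  list(lines = lines[keep], lineNo = which(keep))
}

#' Read a tab-separated expression table
#'
#' Parses the genes-by-samples dialect used throughout the package: the
#' first non-comment line holds the sample names (quoted or unquoted), and
#' every following line holds a gene/probe identifier followed by one
#' numeric linear-scale expression value per sample.  Scientific notation
#' is accepted; blank fields, negative values, ragged rows and duplicate
#' identifiers are rejected.
#'
#' @param path path to the file.
#' @return a validated numeric matrix (genes x samples) with gene ids as
#'   rownames and sample ids as colnames.
#' @seealso [writeExpressionTable()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionTable(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("A", "B"))), tf)
#' readExpressionTable(tf)
#' @export
readExpressionTable <- function(path) {
  src <- .readLinesNoComment(path)
  lines <- src$lines
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sampleIds <- .stripQuotes(header)
  # tolerate a leading (possibly empty) id-column header
  if (length(sampleIds) > 1L &&
      (sampleIds[1L] == "" || tolower(sampleIds[1L]) %in%
         c("gene", "gene_id", "id", "probe")))
    sampleIds <- sampleIds[-1L]
  if (any(!nzchar(sampleIds))) stop("empty sample name in header")
  if (anyDuplicated(sampleIds))
    stop("duplicate sample name(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  s <- length(sampleIds)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("no genes: file has a header but no data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore it so a blank last cell
  # is caught as a blank field, not a ragged row
  trail <- endsWith(body, "\t")
  fields[trail] <- lapply(fields[trail], function(f) c(f, ""))
  nf <- lengths(fields)
  bad <- which(nf != s + 1L)
  if (length(bad)) {
    ln <- src$lineNo[-1L][bad[1L]]
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 ln, s + 1L, nf[bad[1L]]))
  }
  geneIds <- .stripQuotes(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(geneIds))
    stop("duplicate gene id(s): ",
         paste(head(unique(geneIds[duplicated(geneIds)]), 5L),
               collapse = ", "))
  raw <- unlist(lapply(fields, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    row <- (bad - 1L) %/% s + 1L
    stop(sprintf("non-numeric or blank field '%s' at line %d",
                 raw[bad], src$lineNo[-1L][row]))
  }
  if (any(vals < 0)) {
    row <- (which(vals < 0)[1L] - 1L) %/% s + 1L
    stop(sprintf("negative expression value at line %d (gene %s); %s",
                 src$lineNo[-1L][row], geneIds[row],
                 "linear-scale non-negative expression is required"))
  }
  X <- matrix(vals, nrow = length(geneIds), ncol = s, byrow = TRUE,
              dimnames = list(geneIds, sampleIds))
  asExpressionMatrix(X)
}

#' Write an expression matrix as a tab-separated table
#'
#' Sample names are written in double quotes on the first line; each data
#' row holds the gene id and the expression values at full precision, so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param X genes-by-samples matrix (or SummarizedExperiment).
#' @param path output path.
#' @param comment optional comment line(s) written first, prefixed with '#'.
#' @return invisibly, `path`.
#' @export
writeExpressionTable <- function(X, path, comment = NULL) {
  X <- asExpressionMatrix(X)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(sprintf('"%s"', colnames(X)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(X)), function(i)
    paste(c(rownames(X)[i], sprintf("%.17g", X[i, ])), collapse = "\t"), "")
  writeLines(rows, con)
  invisible(path)
}

#' Read marker gene sets from a two-column file
#'
#' Each non-comment line holds a process identifier and a gene identifier,
#' tab-separated.  Processes appear in first-occurrence order; genes within
#' a process keep file order.  A gene listed under two different processes
#' is an error.
#'
#' @param path path to the file.
#' @return a [MarkerSets-class] object.
#' @export
readMarkerSets <- function(path) {
  src <- .readLinesNoComment(path)
  lines <- src$lines[nzchar(src$lines)]
  if (length(lines) < 1L) stop("no marker sets: file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad))
    stop(sprintf(
      "parse error at line %d: expected 2 tab-separated fields, found %d",
      src$lineNo[nzchar(src$lines)][bad[1L]], nf[bad[1L]]))
  proc <- .stripQuotes(vapply(fields, `[[`, "", 1L))
  gene <- .stripQuotes(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(gene)) || any(!nzchar(proc)))
    stop("empty process or gene identifier in marker file")
  procOrder <- unique(proc)
  members <- lapply(procOrder, function(p) unique(gene[proc == p]))
  flat <- unlist(members, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("gene(s) listed under more than one process: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  MarkerSets(members, processIds = procOrder)
}

#' Write marker gene sets to a two-column file
#'
#' @param markers a [MarkerSets-class] object.
#' @param path output path.
#' @param comment optional comment line(s).
#' @return invisibly, `path`.
#' @export
writeMarkerSets <- function(markers, path, comment = NULL) {
  stopifnot(is(markers, "MarkerSets"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  for (k in seq_along(markers@processIds))
    writeLines(paste(markers@processIds[k], markers@members[[k]], sep = "\t"),
               con)
  invisible(path)
}
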