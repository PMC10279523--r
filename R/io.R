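# Delimited-matrix I/O with sample-ID alignment, config files, and
# clustering-quality metrics.

.sepForPath <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load a multi-omics dataset from delimited matrices
#'
#' Each file must be a delimited matrix with a header row and a unique
#' sample-ID first column (delimiter inferred from the extension: comma for
#' .csv, tab otherwise). The intact sample universe is the union of all
#' per-omics IDs in first-seen order; each omics keeps its own row order.
#'
#' @param paths character vector of file paths, one per omics layer.
#' @return A [MultiOmicsSet-class].
#' @export
loadMultiOmics <- function(paths) {
  omics <- vector("list", length(paths))
  for (v in seq_along(paths)) {
    df <- utils::read.table(paths[v], header = TRUE, sep = .sepForPath(paths[v]),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop(sprintf("%s: duplicated sample ID '%s'", basename(paths[v]),
                   ids[duplicated(ids)][1L]), call. = FALSE)
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
      if (!is.numeric(vals[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
        stop(sprintf("%s: non-numeric value at row %d, column '%s'",
                     basename(paths[v]), if (is.na(bad)) 1L else bad,
                     colnames(vals)[j]), call. = FALSE)
      }
    }
    X <- as.matrix(vals)
    if (any(!is.finite(X)))
      stop(sprintf("%s: non-finite values present", basename(paths[v])),
           call. = FALSE)
    rownames(X) <- ids
    omics[[v]] <- X
  }
  intact <- unique(unlist(lapply(omics, rownames), use.names = FALSE))
  MultiOmicsSet(omics, intactIDs = intact)
}

.writeMatrixTSV <- function(X, path, idCol = "sample_id", sep = "\t") {
  df <- data.frame(rownames(X),
                   apply(X, 2, function(x) formatC(x, digits = 12, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colnames(X))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write a multi-omics dataset as delimited files
#'
#' Writes one TSV per omics layer (\code{<prefix><v>.tsv}, sample IDs in
#' the first column, 12 significant digits — enough for absolute round-trip
#' error below 1e-9 at expression scale) and, when true labels are
#' present, a two-column \code{labels.tsv}. Files round-trip through
#' [loadMultiOmics()].
#'
#' @param ds a [MultiOmicsSet-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix for the omics matrices.
#' @return invisibly, the paths written (omics files first).
#' @export
writeMultiOmics <- function(ds, dir, prefix = "omics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (v in seq_len(nOmics(ds))) {
    p <- file.path(dir, sprintf("%s%d.tsv", prefix, v))
    .writeMatrixTSV(ds@omics[[v]], p)
    paths <- c(paths, p)
  }
  if (!is.null(trueLabels(ds))) {
    p <- file.path(dir, "labels.tsv")
    utils::write.table(
      data.frame(sample_id = intactIDs(ds), label = trueLabels(ds)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels named integer vector (names are sample IDs).
#' @param path output file.
#' @export
writeClusterLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), cluster = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a training configuration from YAML or JSON
#'
#' The file holds any subset of the arguments of [gcnConfig()]; omitted
#' fields keep their defaults.
#'
#' @param path a .yaml/.yml or .json file.
#' @return list of class \code{"gcnConfig"}.
#' @export
readGCNConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  known <- names(formals(gcnConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config field '%s'", unknown[1L]), call. = FALSE)
  do.call(gcnConfig, vals)
}

#' Clustering-quality metrics
#'
#' Reports the mean silhouette width of the labels on the embedding, and,
#' when ground truth is supplied, the adjusted Rand index and normalized
#' mutual information (both invariant to label permutation).
#'
#' @param labels integer cluster labels.
#' @param truth optional integer ground-truth labels of the same length.
#' @param H embedding matrix with one row per sample.
#' @return list with \code{silhouette}, and \code{ari}/\code{nmi} when
#'   truth is given; silhouette is NA (with a warning) for a single
#'   cluster.
#' @export
evaluateClustering <- function(labels, truth = NULL, H = NULL) {
  labels <- as.integer(labels)
  out <- list()
  if (!is.null(H)) {
    if (length(labels) != nrow(H))
      stop("labels length differs from number of embedding rows", call. = FALSE)
    if (length(unique(labels)) < 2L) {
      warning("silhouette undefined for a single cluster", call. = FALSE)
      out$silhouette <- NA_real_
    } else {
      sil <- cluster::silhouette(labels, stats::dist(H))
      out$silhouette <- mean(sil[, "sil_width"])
    }
  }
  if (!is.null(truth)) {
    truth <- as.integer(truth)
    if (length(truth) != length(labels))
      stop("truth and labels lengths differ", call. = FALSE)
    out$ari <- mclust::adjustedRandIndex(labels, truth)
    out$nmi <- igraph::compare(labels, truth, method = "nmi")
  }
  out
}
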