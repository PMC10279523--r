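#' @import methods
NULL

#' Container for a (possibly partial) multi-omics dataset
#'
#' A \code{MultiOmicsSet} holds \code{V} numeric expression matrices
#' (samples x features), one per omics layer, aligned to a common "intact"
#' patient universe by sample identifiers stored as matrix rownames. An
#' omics layer may cover only a subset of the intact samples (a *partial*
#' dataset): whole rows are absent, never NA-masked. Optionally carries
#' ground-truth cluster labels, used by the synthetic generator and the
#' evaluation helpers.
#'
#' @slot omics list of numeric matrices, each with unique rownames (sample
#'   IDs) and column names (feature IDs).
#' @slot intactIDs character vector of the \code{N} intact sample IDs; every
#'   per-omics sample ID must occur here, and every intact ID must be
#'   covered by at least one omics layer.
#' @slot trueLabels integer vector of length \code{N} (1-based cluster
#'   labels) or length 0 when unknown.
#'
#' @seealso [simulateMultiOmics()], [loadMultiOmics()], [fitPredict()]
#' @export
setClass("MultiOmicsSet",
  representation(
    omics = "list",
    intactIDs = "character",
    trueLabels = "integer"
  )
)

setValidity("MultiOmicsSet", function(object) {
  msgs <- character()
  if (length(object@omics) < 1L)
    msgs <- c(msgs, "at least one omics matrix is required")
  if (anyDuplicated(object@intactIDs))
    msgs <- c(msgs, "intactIDs contains duplicates")
  seen <- character()
  for (v in seq_along(object@omics)) {
    X <- object@omics[[v]]
    if (!is.matrix(X) || !is.numeric(X)) {
      msgs <- c(msgs, sprintf("omics %d is not a numeric matrix", v))
      next
    }
    if (is.null(rownames(X)))
      msgs <- c(msgs, sprintf("omics %d has no sample IDs (rownames)", v))
    else {
      if (anyDuplicated(rownames(X)))
        msgs <- c(msgs, sprintf("omics %d has duplicated sample IDs", v))
      missing <- setdiff(rownames(X), object@intactIDs)
      if (length(missing))
        msgs <- c(msgs, sprintf("omics %d sample ID '%s' absent from intactIDs",
                                v, missing[1L]))
      seen <- union(seen, rownames(X))
    }
    if (any(!is.finite(X)))
      msgs <- c(msgs, sprintf("omics %d contains non-finite values", v))
  }
  uncovered <- setdiff(object@intactIDs, seen)
  if (length(uncovered))
    msgs <- c(msgs, sprintf("intact sample '%s' is absent from every omics",
                            uncovered[1L]))
  nl <- length(object@trueLabels)
  if (nl > 0L) {
    if (nl != length(object@intactIDs))
      msgs <- c(msgs, "trueLabels length differs from number of intact samples")
    else if (any(object@trueLabels < 1L))
      msgs <- c(msgs, "trueLabels must be positive integers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultiOmicsSet
#'
#' @param omics list of numeric matrices with sample-ID rownames.
#' @param intactIDs optional character vector of intact sample IDs; default
#'   is the union of all per-omics IDs in first-seen order.
#' @param trueLabels optional integer vector of ground-truth cluster labels
#'   (length \code{N}, values in \code{1..C}).
#' @return A validated [MultiOmicsSet-class] object.
#' @examples
#' X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' MultiOmicsSet(list(X))
#' @export
MultiOmicsSet <- function(omics, intactIDs = NULL, trueLabels = NULL) {
  if (is.null(intactIDs)) {
    intactIDs <- unique(unlist(lapply(omics, rownames), use.names = FALSE))
  }
  new("MultiOmicsSet",
      omics = omics,
      intactIDs = as.character(intactIDs),
      trueLabels = if (is.null(trueLabels)) integer(0) else as.integer(trueLabels))
}

#' Fitted subtype model
#'
#' Result of [fitPredict()]: the consensus embedding \code{H} (one row per
#' intact sample), final cluster labels from eigengap-guided spectral
#' clustering, and the per-epoch loss trajectory of both training phases.
#'
#' @slot H numeric matrix \code{N x d}, rownames are intact sample IDs.
#' @slot labels named integer vector of cluster labels (1-based).
#' @slot nClusters integer, the cluster count selected by the eigengap rule.
#' @slot lossHistory data.frame with columns \code{phase}, \code{epoch},
#'   \code{lNar}, \code{lGsr}, \code{lSs}, \code{total}, plus the
#'   fine-tuning row-stochasticity diagnostics \code{qDev}/\code{pDev}
#'   (max deviation of a Q/P row sum from 1; NA during pre-training).
#' @slot config list echo of the [gcnConfig()] used.
#' @export
setClass("SubtypeFit",
  representation(
    H = "matrix",
    labels = "integer",
    nClusters = "integer",
    lossHistory = "data.frame",
    config = "list"
  )
)

setValidity("SubtypeFit", function(object) {
  msgs <- character()
  if (nrow(object@lossHistory) < 1L)
    msgs <- c(msgs, "lossHistory is empty")
  if (length(object@labels) != nrow(object@H))
    msgs <- c(msgs, "labels length differs from number of embedding rows")
  if (length(msgs)) msgs else TRUE
})
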