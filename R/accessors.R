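#' @describeIn MultiOmicsSet-class number of omics layers
#' @param object a \code{MultiOmicsSet} or \code{SubtypeFit}
#' @export
setGeneric("nOmics", function(object) standardGeneric("nOmics"))

#' @export
setMethod("nOmics", "MultiOmicsSet", function(object) length(object@omics))

#' @describeIn MultiOmicsSet-class number of intact samples N
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "MultiOmicsSet", function(object) length(object@intactIDs))

#' @describeIn MultiOmicsSet-class list of omics matrices
#' @export
setGeneric("omicsMatrices", function(object) standardGeneric("omicsMatrices"))

#' @export
setMethod("omicsMatrices", "MultiOmicsSet", function(object) object@omics)

#' @describeIn MultiOmicsSet-class intact sample identifiers
#' @export
setGeneric("intactIDs", function(object) standardGeneric("intactIDs"))

#' @export
setMethod("intactIDs", "MultiOmicsSet", function(object) object@intactIDs)

#' @describeIn MultiOmicsSet-class ground-truth labels, or NULL when unknown
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))

#' @export
setMethod("trueLabels", "MultiOmicsSet", function(object) {
  if (length(object@trueLabels)) object@trueLabels else NULL
})

setMethod("show", "MultiOmicsSet", function(object) {
  cat(sprintf("MultiOmicsSet: %d omics, %d intact samples\n",
              nOmics(object), nSamples(object)))
  for (v in seq_along(object@omics)) {
    X <- object@omics[[v]]
    cat(sprintf("  omics %d: %d samples x %d features%s\n", v,
                nrow(X), ncol(X),
                if (nrow(X) < nSamples(object)) " (partial)" else ""))
  }
  if (length(object@trueLabels))
    cat(sprintf("  true labels: %d clusters\n", length(unique(object@trueLabels))))
  invisible(NULL)
})

#' @describeIn SubtypeFit-class consensus embedding H (N x d)
#' @param object a \code{SubtypeFit}
#' @export
setGeneric("consensus", function(object) standardGeneric("consensus"))

#' @export
setMethod("consensus", "SubtypeFit", function(object) object@H)

#' @describeIn SubtypeFit-class named integer cluster labels
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @export
setMethod("clusterLabels", "SubtypeFit", function(object) object@labels)

#' @describeIn SubtypeFit-class selected number of clusters
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @export
setMethod("nClusters", "SubtypeFit", function(object) object@nClusters)

#' @describeIn SubtypeFit-class per-epoch loss trajectory
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @export
setMethod("lossHistory", "SubtypeFit", function(object) object@lossHistory)

setMethod("show", "SubtypeFit", function(object) {
  cat(sprintf("SubtypeFit: %d samples embedded in %d dimensions, %d subtypes\n",
              nrow(object@H), ncol(object@H), object@nClusters))
  tab <- table(object@labels)
  cat("  cluster sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  last <- object@lossHistory[nrow(object@lossHistory), ]
  cat(sprintf("  final loss: total=%.4g (nar=%.4g, gsr=%.4g, ss=%.4g)\n",
              last$total, last$lNar, last$lGsr, last$lSs))
  invisible(NULL)
})
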