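#' Simulate a multi-omics dataset with planted cluster structure
#'
#' Draws \code{V} omics matrices that share one latent partition of the
#' samples into \code{C} clusters. Within each omics, cluster centroids sit
#' along mutually orthogonal random directions so that every pair of
#' centroids is exactly \code{separation * noiseSD} apart in feature space;
#' samples are their cluster centroid plus i.i.d. Gaussian noise of standard
#' deviation \code{noiseSD}. Labels are balanced to within one sample. The
#' generator mimics the consensus-structure assumption of multi-omics
#' subtyping cohorts, not realistic omics marginals (no count
#' overdispersion, no bounded methylation scale).
#'
#' @param nSamples number of intact samples N (N >= nClusters).
#' @param nOmics number of omics layers V (>= 1).
#' @param nClusters number of planted clusters C (>= 2).
#' @param dims integer vector of length V: features per omics; every entry
#'   must be >= nClusters so that orthogonal centroid directions exist.
#' @param separation nonnegative inter-centroid distance, in units of
#'   \code{noiseSD}. 0 plants no signal at all.
#' @param noiseSD positive noise standard deviation.
#' @param seed integer seed; the result is bit-identical across calls with
#'   the same seed.
#' @return A [MultiOmicsSet-class] with \code{trueLabels} set.
#' @examples
#' ds <- simulateMultiOmics(60, 2, 3, dims = c(10, 15), separation = 6, seed = 1)
#' table(trueLabels(ds))
#' @export
simulateMultiOmics <- function(nSamples, nOmics, nClusters, dims,
                               separation, noiseSD = 1, seed = 1L) {
  .checkCount <- function(x, name, min) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid field '%s': must be an integer >= %d", name, min),
           call. = FALSE)
  }
  .checkCount(nSamples, "nSamples", 2)
  .checkCount(nOmics, "nOmics", 1)
  .checkCount(nClusters, "nClusters", 2)
  if (nSamples < nClusters)
    stop("invalid field 'nSamples': must be >= nClusters", call. = FALSE)
  if (length(dims) != nOmics || any(!is.finite(dims)) || any(dims < 1) ||
      any(dims != round(dims)))
    stop("invalid field 'dims': need one positive integer per omics",
         call. = FALSE)
  if (any(dims < nClusters))
    stop("invalid field 'dims': each omics needs >= nClusters features for orthogonal centroids",
         call. = FALSE)
  if (length(separation) != 1L || !is.finite(separation) || separation < 0)
    stop("invalid field 'separation': must be a nonnegative scalar", call. = FALSE)
  if (length(noiseSD) != 1L || !is.finite(noiseSD) || noiseSD <= 0)
    stop("invalid field 'noiseSD': must be a positive scalar", call. = FALSE)

  set.seed(as.integer(seed))
  N <- as.integer(nSamples); V <- as.integer(nOmics); C <- as.integer(nClusters)
  # balanced round-robin labels, then shuffled
  labels <- sample(rep_len(seq_len(C), N))
  ids <- sprintf("S%04d", seq_len(N))

  omics <- vector("list", V)
  for (v in seq_len(V)) {
    Dv <- as.integer(dims[v])
    # orthonormal random directions; pairwise centroid distance = sep * sd
    Qmat <- qr.Q(qr(matrix(stats::rnorm(Dv * C), Dv, C)))[, seq_len(C), drop = FALSE]
    centroids <- t(Qmat) * (separation * noiseSD / sqrt(2))
    X <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(N * Dv, sd = noiseSD), N, Dv)
    dimnames(X) <- list(ids, sprintf("om%d_f%d", v, seq_len(Dv)))
    omics[[v]] <- X
  }
  MultiOmicsSet(omics, intactIDs = ids, trueLabels = labels)
}

#' Delete a random fraction of samples from one omics layer
#'
#' Emulates the partial-dataset condition of multi-omics cohorts: a fraction
#' \code{theta} of the patients lose their measurements in one omics layer
#' entirely (whole rows removed, not NA-masked). All other layers, the
#' intact sample universe and any true labels are untouched.
#'
#' @param ds a [MultiOmicsSet-class].
#' @param omicsIndex which omics layer to thin (1-based).
#' @param theta fraction in \code{[0, 1)} of that layer's rows to delete;
#'   exactly \code{round(theta * Nv)} rows are removed.
#' @param seed integer seed controlling which rows are sampled.
#' @return A new [MultiOmicsSet-class]; identical to \code{ds} when
#'   \code{theta} rounds to zero rows.
#' @examples
#' ds <- simulateMultiOmics(50, 2, 2, dims = c(5, 5), separation = 4, seed = 1)
#' nrow(omicsMatrices(applyMissingness(ds, 1, 0.3, seed = 2))[[1]])
#' @export
applyMissingness <- function(ds, omicsIndex, theta, seed = 1L) {
  stopifnot(is(ds, "MultiOmicsSet"))
  V <- nOmics(ds)
  if (length(omicsIndex) != 1L || omicsIndex < 1 || omicsIndex > V ||
      omicsIndex != round(omicsIndex))
    stop(sprintf("omicsIndex must be an integer in 1..%d", V), call. = FALSE)
  if (length(theta) != 1L || !is.finite(theta) || theta < 0 || theta >= 1)
    stop("theta must lie in [0, 1)", call. = FALSE)
  X <- ds@omics[[omicsIndex]]
  nv <- nrow(X)
  nDrop <- as.integer(round(theta * nv))
  if (nDrop == 0L) return(ds)
  if (nv - nDrop < 1L)
    stop("deletion would empty the omics layer", call. = FALSE)
  set.seed(as.integer(seed))
  drop <- sample.int(nv, nDrop)
  omics <- ds@omics
  omics[[omicsIndex]] <- X[-drop, , drop = FALSE]
  new("MultiOmicsSet", omics = omics, intactIDs = ds@intactIDs,
      trueLabels = ds@trueLabels)
}
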