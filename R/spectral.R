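# Spectral clustering of the consensus embedding: RBF-on-kNN similarity,
# symmetric normalized Laplacian, eigengap model selection, and the
# standard row-normalized k-means discretization of the trace relaxation.

#' RBF similarity restricted to k-nearest-neighbor pairs
#'
#' \eqn{S_{ij} = \exp(-\|h_i - h_j\|^2 / t)} when i and j are kNN-related by
#' the OR rule, else 0; zero diagonal. With \code{t = "auto"} the bandwidth
#' is the mean squared distance over the retained neighbor pairs, a
#' scale-free local-scaling surrogate.
#'
#' @param H embedding matrix \code{N x d}.
#' @param k neighbor count (defaults to [defaultK()] of N).
#' @param t positive bandwidth, or \code{"auto"}.
#' @return an object of class \code{"SimilarityMatrix"}: list with
#'   symmetric nonnegative \code{S} (entries in [0, 1]) and the bandwidth
#'   \code{t} used.
#' @export
buildSimilarity <- function(H, k = defaultK(nrow(H)), t = "auto") {
  H <- as.matrix(H)
  n <- nrow(H)
  if (k < 1 || k >= n)
    stop(sprintf("k must satisfy 1 <= k < %d", n), call. = FALSE)
  d2 <- as.matrix(stats::dist(H))^2
  dimnames(d2) <- NULL
  adj <- .knnAdjacency(d2, as.integer(k))
  if (identical(t, "auto")) {
    t <- mean(d2[adj == 1])
    if (!is.finite(t) || t <= 0) t <- 1  # all points coincide
  }
  if (!is.numeric(t) || t <= 0) stop("bandwidth t must be positive", call. = FALSE)
  S <- exp(-d2 / t) * adj
  diag(S) <- 0
  structure(list(S = S, t = t), class = "SimilarityMatrix")
}

#' Symmetric normalized graph Laplacian
#'
#' \eqn{L = I - D^{-1/2} S D^{-1/2}} with \eqn{D_{ii} = \sum_j S_{ij}}.
#' Eigenvalues lie in [0, 2]; the multiplicity of eigenvalue 0 equals the
#' number of connected components.
#'
#' @param S a \code{"SimilarityMatrix"} or a symmetric nonnegative matrix.
#' @return symmetric matrix L.
#' @export
normalizedLaplacian <- function(S) {
  M <- if (inherits(S, "SimilarityMatrix")) S$S else as.matrix(S)
  deg <- rowSums(M)
  if (any(deg <= 0))
    stop(sprintf("node %d is isolated (zero similarity to all others); increase k",
                 which(deg <= 0)[1L]), call. = FALSE)
  s <- 1 / sqrt(deg)
  L <- diag(nrow(M)) - M * outer(s, s)
  (L + t(L)) / 2
}

#' Choose the cluster count by the eigengap rule
#'
#' Scans i over \code{[cMin, cMax]} and returns the i with the largest gap
#' \eqn{\lambda_{i+1} - \lambda_i} in the ascending eigenvalue ladder of the
#' normalized Laplacian; ties go to the smallest i (parsimony). The
#' index-weighted variant scores \eqn{(\lambda_{i+1} - \lambda_i) \cdot i}
#' instead.
#'
#' @param eigenvalues numeric vector sorted ascending.
#' @param cMin,cMax search range (default 2..15).
#' @param indexWeighted logical; use the index-weighted gap score.
#' @return integer cluster count.
#' @export
estimateNumClusters <- function(eigenvalues, cMin = 2L, cMax = 15L,
                                indexWeighted = FALSE) {
  n <- length(eigenvalues)
  cMax <- min(as.integer(cMax), n - 1L)
  if (cMin < 1L || cMin > cMax)
    stop("invalid cluster-count range", call. = FALSE)
  if (is.unsorted(eigenvalues, strictly = FALSE))
    stop("eigenvalues must be sorted ascending", call. = FALSE)
  idx <- seq.int(cMin, cMax)
  gaps <- eigenvalues[idx + 1L] - eigenvalues[idx]
  score <- if (indexWeighted) gaps * idx else gaps
  idx[which.max(score)]  # which.max returns the first (smallest i) on ties
}

#' Spectral partition from the normalized Laplacian
#'
#' Takes the C eigenvectors with smallest eigenvalues (the minimizer of
#' \eqn{\mathrm{Tr}(B^T L B)} over orthonormal B), row-normalizes them, and
#' discretizes with k-means (20 restarts, seeded) in the Ng-Jordan-Weiss
#' manner.
#'
#' @param L symmetric normalized Laplacian.
#' @param C number of clusters (>= 2).
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return an object of class \code{"SpectralSolution"}: list with
#'   \code{values} (all eigenvalues, ascending), \code{B} (orthonormal
#'   \code{N x C} eigenvector matrix), \code{labels} (integer, 1..C),
#'   \code{C}, and \code{trace} (\eqn{\mathrm{Tr}(B^T L B)}).
#' @export
spectralCluster <- function(L, C, seed = 1L, nstart = 20L) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (C < 2 || C > n) stop(sprintf("C must lie in 2..%d", n), call. = FALSE)
  eig <- eigen(L, symmetric = TRUE)
  values <- rev(eig$values)                      # ascending
  B <- eig$vectors[, seq.int(n, n - C + 1L), drop = FALSE]  # smallest C, ascending
  rn <- sqrt(rowSums(B^2))
  Bn <- B / pmax(rn, 1e-12)
  set.seed(as.integer(seed))
  # Lloyd iterations: Hartigan-Wong's Quick-TRANSfer stage thrashes on the
  # near-duplicate rows typical of well-separated spectral embeddings.
  # Individual restarts may hit an empty cluster; that is what the restarts
  # are for, so that warning is muffled (emptiness of the final partition
  # is checked by the caller).
  km <- withCallingHandlers(
    stats::kmeans(Bn, centers = as.integer(C), nstart = as.integer(nstart),
                  iter.max = 200L, algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(values = values, B = B,
                 labels = as.integer(km$cluster), C = as.integer(C),
                 trace = sum(diag(t(B) %*% L %*% B))),
            class = "SpectralSolution")
}

# full eigengap + partition pipeline on an embedding; returns labels, C,
# and the eigenvalue ladder (used at fine-tune init and for final labels)
.clusterEmbedding <- function(H, k = defaultK(nrow(H)), t = "auto",
                              cRange = c(2L, 15L), C = NULL, seed = 1L,
                              indexWeighted = FALSE, maxRetries = 5L) {
  S <- buildSimilarity(H, k = k, t = t)
  L <- normalizedLaplacian(S)
  values <- rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (is.null(C))
    C <- estimateNumClusters(values, cRange[1L], cRange[2L],
                             indexWeighted = indexWeighted)
  sol <- NULL
  for (r in seq_len(maxRetries)) {
    sol <- spectralCluster(L, C, seed = seed + r - 1L)
    if (length(unique(sol$labels)) == C) break
    sol <- NULL
  }
  if (is.null(sol))
    stop("spectral discretization produced an empty cluster after retries",
         call. = FALSE)
  list(labels = sol$labels, C = C, values = values, solution = sol)
}
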