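# kNN similarity graphs, their renormalized propagation operators, and the
# indicator matrices aligning partial omics to the intact sample universe.

#' Default neighbor count for sample-similarity graphs
#'
#' \code{ceiling(log2(n)) + 1}, clamped to \code{[2, n - 1]}: grows slowly
#' with cohort size so graphs stay sparse yet connected on small fixtures.
#'
#' @param n number of samples in the graph.
#' @return integer neighbor count.
#' @export
defaultK <- function(n) {
  if (n < 3) stop("need at least 3 samples for a kNN graph", call. = FALSE)
  min(max(as.integer(ceiling(log2(n))) + 1L, 2L), as.integer(n) - 1L)
}

# neighbor sets from a squared-distance matrix; ties at the k-th neighbor
# broken by lower row index (stable order)
.knnAdjacency <- function(d2, k) {
  n <- nrow(d2)
  adj <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ord <- order(d2[, j])       # stable: ties keep lower index first
    ord <- ord[ord != j]        # self excluded from Nei(.)
    adj[ord[seq_len(k)], j] <- 1
  }
  # OR rule: edge if i in Nei(j) or j in Nei(i)
  adj <- pmax(adj, t(adj))
  diag(adj) <- 0
  adj
}

#' Build a binary k-nearest-neighbor graph over samples
#'
#' Connects i and j when i is among the k nearest Euclidean neighbors of j
#' *or* vice versa (OR-symmetrization), self excluded, zero diagonal. This
#' is the similarity graph each omics layer feeds to its graph
#' convolutional encoder.
#'
#' @param X numeric matrix (samples x features), all finite.
#' @param k neighbor count, \code{1 <= k < nrow(X)}.
#' @return an object of class \code{"AdjacencyGraph"}: list with binary
#'   symmetric \code{adj} and the \code{k} used.
#' @examples
#' g <- buildKnnGraph(matrix(c(0, 1, 10, 11), 4, 1), k = 1)
#' g$adj
#' @export
buildKnnGraph <- function(X, k) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  n <- nrow(X)
  if (k < 1 || k >= n)
    stop(sprintf("k must satisfy 1 <= k < %d", n), call. = FALSE)
  d2 <- as.matrix(stats::dist(X))^2
  structure(list(adj = .knnAdjacency(d2, as.integer(k)), k = as.integer(k)),
            class = "AdjacencyGraph")
}

#' Renormalized propagation operator of a graph
#'
#' Computes \eqn{D^{-1/2}(A + I)D^{-1/2}} where \eqn{D} is the diagonal
#' degree matrix of \eqn{A + I}. Adding the identity before normalization
#' guarantees positive degrees (an isolated node reduces to a diagonal 1)
#' and keeps the operator's spectral radius at most 1.
#'
#' @param g an \code{"AdjacencyGraph"} or a binary symmetric adjacency matrix.
#' @return symmetric numeric matrix, the propagation operator.
#' @examples
#' normalizeAdjacency(buildKnnGraph(matrix(rnorm(10), 5, 2), k = 2))
#' @export
normalizeAdjacency <- function(g) {
  A <- if (inherits(g, "AdjacencyGraph")) g$adj else as.matrix(g)
  Ap <- A + diag(nrow(A))
  s <- 1 / sqrt(rowSums(Ap))
  Ap * outer(s, s)
}

#' Indicator matrix mapping omics-local rows to intact-sample columns
#'
#' Binary \code{Nv x N} matrix with a single 1 per row: entry (i, j) is 1
#' exactly when the i-th sample of the omics layer is the j-th intact
#' sample. These matrices let partial omics participate in consensus fusion
#' without imputation.
#'
#' @param omicsIDs sample IDs of the omics layer (duplicate-free, each
#'   present in \code{intactIDs}).
#' @param intactIDs sample IDs of the intact universe (duplicate-free).
#' @return an object of class \code{"IndicatorMatrix"}: list with binary
#'   \code{mat}, \code{rowIDs}, \code{colIDs}, and \code{idx}
#'   (\code{match(omicsIDs, intactIDs)}).
#' @examples
#' buildIndicatorMatrix(c("s1", "s3"), c("s1", "s2", "s3"))$mat
#' @export
buildIndicatorMatrix <- function(omicsIDs, intactIDs) {
  if (anyDuplicated(omicsIDs))
    stop(sprintf("duplicated omics sample ID '%s'",
                 omicsIDs[duplicated(omicsIDs)][1L]), call. = FALSE)
  if (anyDuplicated(intactIDs))
    stop(sprintf("duplicated intact sample ID '%s'",
                 intactIDs[duplicated(intactIDs)][1L]), call. = FALSE)
  idx <- match(omicsIDs, intactIDs)
  if (anyNA(idx))
    stop(sprintf("omics sample ID '%s' absent from intact IDs",
                 omicsIDs[which(is.na(idx))[1L]]), call. = FALSE)
  nv <- length(omicsIDs); n <- length(intactIDs)
  mat <- matrix(0, nv, n, dimnames = list(omicsIDs, intactIDs))
  mat[cbind(seq_len(nv), idx)] <- 1
  structure(list(mat = mat, rowIDs = as.character(omicsIDs),
                 colIDs = as.character(intactIDs), idx = idx),
            class = "IndicatorMatrix")
}
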