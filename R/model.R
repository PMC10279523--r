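# The graph convolutional autoencoder: per-omics encoders, consensus
# fusion, attribute and bilinear graph decoders, and all loss terms.
#
# The model is a flat named list of weight matrices ("enc.v.m", "dec.v.m",
# "wg.v", "mu") plus shape metadata; the forward/backward passes used in
# training live in train.R. The functions here are the canonical
# definitions of each operation and are what the tests exercise against
# explicit-loop oracles.

# indicator as row-index vector; NULL means full data in intact order
.indicatorIdx <- function(G) {
  if (is.null(G)) return(NULL)
  if (inherits(G, "IndicatorMatrix")) return(G$idx)
  stop("G must be an IndicatorMatrix or NULL", call. = FALSE)
}

.selectRows <- function(H, G) {
  idx <- .indicatorIdx(G)
  if (is.null(idx)) H else H[idx, , drop = FALSE]
}

#' Encode one omics layer with a stack of graph convolutions
#'
#' Applies \eqn{Z_m = \tanh(T Z_{m-1} W_m)} for \eqn{m = 1..M}, where
#' \eqn{T} is the renormalized propagation operator of the omics' kNN graph
#' and \eqn{Z_0 = X}. The last layer's width is the shared embedding
#' dimension d.
#'
#' @param X numeric matrix \code{Nv x Dv} (layer input).
#' @param op propagation operator from [normalizeAdjacency()].
#' @param weights list of weight matrices, chained shapes.
#' @return matrix \code{Nv x d}, the omics embedding.
#' @export
encodeOmics <- function(X, op, weights) {
  Z <- as.matrix(X)
  for (m in seq_along(weights)) {
    W <- weights[[m]]
    if (ncol(Z) != nrow(W))
      stop(sprintf("encoder layer %d: input has %d columns but weight expects %d",
                   m, ncol(Z), nrow(W)), call. = FALSE)
    Z <- tanh(op %*% Z %*% W)
  }
  Z
}

#' Fuse per-omics embeddings into the consensus representation
#'
#' Row j of H is the mean of the embeddings of intact sample j over the
#' omics layers that measured it; indicator matrices route each omics-local
#' row to its intact position, so partial layers contribute only where they
#' have data.
#'
#' @param ZList list of per-omics embedding matrices (same column count d).
#' @param GList list of [buildIndicatorMatrix()] results (or \code{NULL}
#'   entries for layers that are complete and in intact order).
#' @param N number of intact samples; defaults to the indicator column
#'   count, or to \code{nrow(ZList[[1]])} when all entries of GList are NULL.
#' @return matrix \code{N x d}, the consensus embedding H.
#' @export
fuseConsensus <- function(ZList, GList = NULL, N = NULL) {
  V <- length(ZList)
  if (is.null(GList)) GList <- vector("list", V)
  if (length(GList) != V)
    stop("ZList and GList lengths differ", call. = FALSE)
  if (is.null(N)) {
    withG <- which(!vapply(GList, is.null, logical(1)))
    N <- if (length(withG)) length(GList[[withG[1L]]]$colIDs) else nrow(ZList[[1L]])
  }
  d <- ncol(ZList[[1L]])
  acc <- matrix(0, N, d)
  cnt <- numeric(N)
  for (v in seq_len(V)) {
    Z <- ZList[[v]]
    if (ncol(Z) != d) stop("embedding dimensions differ across omics", call. = FALSE)
    idx <- .indicatorIdx(GList[[v]])
    if (is.null(idx)) {
      if (nrow(Z) != N)
        stop(sprintf("omics %d embedding has %d rows but N = %d and no indicator given",
                     v, nrow(Z), N), call. = FALSE)
      acc <- acc + Z
      cnt <- cnt + 1
    } else {
      acc[idx, ] <- acc[idx, , drop = FALSE] + Z
      cnt[idx] <- cnt[idx] + 1
    }
  }
  if (any(cnt == 0))
    stop(sprintf("intact sample %d is absent from every omics (zero fusion weight)",
                 which(cnt == 0)[1L]), call. = FALSE)
  acc / cnt
}

#' Reconstruct one omics' expression matrix from the consensus embedding
#'
#' Mirror of the encoder: a dense layer maps the omics' rows of H back to
#' the last hidden width, \eqn{\hat Z_M = \tanh((G H)\hat W_M)}, followed by
#' graph-convolution layers \eqn{\hat Z_{m-1} = \tanh(T \hat Z_m \hat W_{m-1})}
#' down to the reconstructed attributes with Dv columns.
#'
#' @param H consensus embedding \code{N x d}.
#' @param op propagation operator of the omics' graph (\code{Nv x Nv}).
#' @param weights list of decoder weight matrices in application order
#'   (first maps d to the last hidden width; last outputs Dv columns).
#' @param G indicator for the omics layer, or NULL for full data.
#' @return matrix \code{Nv x Dv}, the reconstructed attributes.
#' @export
decodeAttributes <- function(H, op, weights, G = NULL) {
  Z <- .selectRows(H, G)
  for (m in seq_along(weights)) {
    W <- weights[[m]]
    if (ncol(Z) != nrow(W))
      stop(sprintf("decoder layer %d: input has %d columns but weight expects %d",
                   m, ncol(Z), nrow(W)), call. = FALSE)
    Z <- if (m == 1L) tanh(Z %*% W) else tanh(op %*% Z %*% W)
  }
  Z
}

#' Reconstruct one omics' similarity graph from the consensus embedding
#'
#' Bilinear decoder \eqn{\hat A = \tanh((G H) \tilde W (G H)^T)}; a
#' per-omics weight matrix lets one shared embedding reproduce several
#' different graphs, which a plain inner product could not.
#'
#' @param H consensus embedding \code{N x d}.
#' @param Wg bilinear weight matrix \code{d x d} (no symmetry required).
#' @param G indicator for the omics layer, or NULL for full data.
#' @return matrix \code{Nv x Nv} with entries in (-1, 1).
#' @export
decodeGraph <- function(H, Wg, G = NULL) {
  B <- .selectRows(H, G)
  if (ncol(B) != nrow(Wg) || nrow(Wg) != ncol(Wg))
    stop(sprintf("graph decoder weight must be %d x %d", ncol(B), ncol(B)),
         call. = FALSE)
  tanh(B %*% Wg %*% t(B))
}

#' Attribute reconstruction loss
#'
#' Sum over omics of the squared Frobenius distance between each layer's
#' expression matrix and its reconstruction.
#'
#' @param XList,XhatList lists of matched-shape matrices.
#' @return nonnegative scalar.
#' @export
attributeReconstructionLoss <- function(XList, XhatList) {
  if (length(XList) != length(XhatList))
    stop("XList and XhatList lengths differ", call. = FALSE)
  tot <- 0
  for (v in seq_along(XList)) {
    if (!all(dim(XList[[v]]) == dim(XhatList[[v]])))
      stop(sprintf("omics %d: shape mismatch", v), call. = FALSE)
    tot <- tot + sum((XList[[v]] - XhatList[[v]])^2)
  }
  tot
}

#' Graph structure reconstruction loss
#'
#' Sum over omics of the squared Frobenius distance between each layer's
#' binary adjacency and its reconstruction. Because the decoder output lies
#' in (-1, 1), the loss is strictly positive whenever the adjacency has any
#' edge.
#'
#' @param AList,AhatList lists of matched-shape square matrices.
#' @return nonnegative scalar.
#' @export
graphReconstructionLoss <- function(AList, AhatList) {
  attributeReconstructionLoss(AList, AhatList)
}

#' Student-t soft cluster assignment
#'
#' \eqn{Q_{ij} = (1 + \|h_i - \mu_j\|^2)^{-1}} normalized over clusters: the
#' similarity of each embedded sample to each cluster center under a
#' one-degree-of-freedom Student t kernel. Rows sum to 1.
#'
#' @param H embedding \code{N x d}.
#' @param mu cluster centers \code{C x d}, C >= 2.
#' @return matrix \code{N x C}, row-stochastic.
#' @export
softAssignment <- function(H, mu) {
  H <- as.matrix(H); mu <- as.matrix(mu)
  if (nrow(mu) < 2L) stop("need at least 2 cluster centers", call. = FALSE)
  if (ncol(H) != ncol(mu)) stop("H and mu dimensions differ", call. = FALSE)
  d2 <- outer(rowSums(H^2), rep(1, nrow(mu))) +
    outer(rep(1, nrow(H)), rowSums(mu^2)) - 2 * H %*% t(mu)
  d2[d2 < 0] <- 0
  s <- 1 / (1 + d2)
  s / pmax(rowSums(s), 1e-12)
}

#' Target distribution for self-supervised refinement
#'
#' Squares the soft assignment and renormalizes by soft cluster frequency,
#' \eqn{P_{ij} \propto Q_{ij}^2 / \sum_i Q_{ij}}, sharpening confident
#' assignments while discouraging large clusters from swallowing everything.
#' With a single sample, P equals Q (algebraic fixed point).
#'
#' @param Q row-stochastic positive matrix from [softAssignment()].
#' @return matrix of the same shape, row-stochastic.
#' @export
targetDistribution <- function(Q) {
  f <- colSums(Q)
  if (any(f <= 0))
    stop(sprintf("soft cluster %d is empty (column sum 0)", which(f <= 0)[1L]),
         call. = FALSE)
  W <- sweep(Q^2, 2, f, "/")
  W / pmax(rowSums(W), 1e-12)
}

#' Self-supervision loss KL(P || Q)
#'
#' Kullback-Leibler divergence between the target distribution P and the
#' soft assignment Q, natural logarithm, with the convention 0 log 0 = 0.
#'
#' @param P,Q row-stochastic matrices of equal shape.
#' @return nonnegative scalar.
#' @export
selfSupervisedLoss <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("P and Q shapes differ", call. = FALSE)
  pos <- P > 0
  if (any(Q[pos] <= 0))
    stop("Q is zero where P is positive: divergence is infinite", call. = FALSE)
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Combine the three loss terms
#'
#' \code{total = lNar + alpha * lGsr + beta * lSs}; alpha and beta are the
#' trade-off weights (both default to 1 throughout the package).
#'
#' @param lNar,lGsr,lSs nonnegative loss components.
#' @param alpha,beta nonnegative trade-off weights.
#' @return an object of class \code{"LossBreakdown"}: list with the three
#'   components, the weights, and \code{total}.
#' @export
totalLoss <- function(lNar, lGsr, lSs, alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0)
    stop("alpha and beta must be nonnegative", call. = FALSE)
  if (lNar < 0 || lGsr < 0 || lSs < 0)
    stop("loss components must be nonnegative", call. = FALSE)
  structure(list(lNar = lNar, lGsr = lGsr, lSs = lSs,
                 alpha = alpha, beta = beta,
                 total = lNar + alpha * lGsr + beta * lSs),
            class = "LossBreakdown")
}

# ---- parameter initialization ------------------------------------------

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

# model: flat named parameter list + shape metadata. Encoder widths per
# omics are Dv -> hidden (depth-1 times) -> d; decoders mirror them.
.initModel <- function(dims, d, hidden = NULL, depth = 2L) {
  V <- length(dims)
  if (is.null(hidden)) hidden <- pmin(256L, as.integer(dims))
  hidden <- rep_len(as.integer(hidden), V)
  params <- list()
  encW <- decW <- vector("list", V)
  for (v in seq_len(V)) {
    widths <- c(dims[v], rep(hidden[v], depth - 1L), d)
    for (m in seq_len(depth)) {
      params[[sprintf("enc.%d.%d", v, m)]] <- .glorot(widths[m], widths[m + 1L])
    }
    rwidths <- rev(widths)
    for (m in seq_len(depth)) {
      params[[sprintf("dec.%d.%d", v, m)]] <- .glorot(rwidths[m], rwidths[m + 1L])
    }
    params[[sprintf("wg.%d", v)]] <- .glorot(d, d)
  }
  list(params = params, dims = as.integer(dims), d = as.integer(d),
       hidden = hidden, depth = as.integer(depth), V = V, mu = NULL)
}
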