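# Training orchestration: z-score normalization, graph/indicator
# construction, full-batch pre-training on the two reconstruction losses,
# and self-supervised fine-tuning with periodic target refresh.

#' Default consensus embedding dimension
#'
#' 0.8 times the smallest per-omics feature count when that count is below
#' 2000, otherwise 1600.
#'
#' @param dims per-omics feature counts.
#' @return integer embedding dimension.
#' @examples
#' defaultEmbeddingDim(c(500, 2000, 12000))  # 400
#' defaultEmbeddingDim(c(3000, 5000))        # 1600
#' @export
defaultEmbeddingDim <- function(dims) {
  if (length(dims) < 1L) stop("dims must be nonempty", call. = FALSE)
  m <- min(dims)
  if (m < 2000) as.integer(round(0.8 * m)) else 1600L
}

#' Training configuration
#'
#' Collects every tunable of the model and trainer with the package
#' defaults: learning rate 0.001, trade-off weights alpha = beta = 1,
#' eigengap search range [2, 15], two-layer encoders, Adam updates.
#' Anything left \code{NULL} is derived from the data at fit time
#' (embedding dimension via [defaultEmbeddingDim()], hidden width
#' \code{min(256, Dv)}, neighbor count via [defaultK()]).
#'
#' @param learningRate positive gradient step size.
#' @param alpha,beta nonnegative trade-off weights for the graph
#'   reconstruction and self-supervision losses.
#' @param d embedding dimension, or NULL for the default rule.
#' @param hidden hidden layer width (scalar or per-omics), or NULL.
#' @param depth number of encoder layers M (decoders mirror it).
#' @param pretrainEpochs,finetuneEpochs epoch budgets for the two phases.
#'   Training is full-batch, so one epoch is exactly one gradient update;
#'   the pre-training default of 2000 updates corresponds to roughly 200
#'   minibatch epochs at conventional batch sizes and is what the
#'   reconstruction losses need to plateau on cohort-scale data.
#'   Fine-tuning usually stops much earlier via \code{convergenceTol}.
#' @param pRefreshInterval epochs between target-distribution refreshes.
#' @param convergenceTol stop fine-tuning when the fraction of samples
#'   changing cluster between refreshes falls below this.
#' @param kNeighbors neighbor count for all kNN graphs, or NULL.
#' @param cRange integer vector of length 2: eigengap search range.
#' @param indexWeightedGap use the index-weighted eigengap variant.
#' @param optimizer "adam" or "sgd".
#' @param useIndicatorPath NA (auto: indicators only when some omics is
#'   partial), TRUE (always route through indicator matrices) or FALSE
#'   (error if the data are partial). The two routes are bit-identical on
#'   full data.
#' @param seed integer seed governing all randomness of a fit.
#' @return list of class \code{"gcnConfig"}.
#' @export
gcnConfig <- function(learningRate = 0.001, alpha = 1, beta = 1,
                      d = NULL, hidden = NULL, depth = 2L,
                      pretrainEpochs = 2000L, finetuneEpochs = 100L,
                      pRefreshInterval = 5L, convergenceTol = 0.001,
                      kNeighbors = NULL, cRange = c(2L, 15L),
                      indexWeightedGap = FALSE,
                      optimizer = c("adam", "sgd"),
                      useIndicatorPath = NA, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learningRate > 0, alpha >= 0, beta >= 0,
            depth >= 1, pretrainEpochs >= 1, finetuneEpochs >= 1,
            pRefreshInterval >= 1,
            convergenceTol > 0, convergenceTol < 1,
            length(cRange) == 2, cRange[1] >= 2, cRange[2] >= cRange[1])
  structure(list(learningRate = learningRate, alpha = alpha, beta = beta,
                 d = d, hidden = hidden, depth = as.integer(depth),
                 pretrainEpochs = as.integer(pretrainEpochs),
                 finetuneEpochs = as.integer(finetuneEpochs),
                 pRefreshInterval = as.integer(pRefreshInterval),
                 convergenceTol = convergenceTol,
                 kNeighbors = kNeighbors,
                 cRange = as.integer(cRange),
                 indexWeightedGap = isTRUE(indexWeightedGap),
                 optimizer = optimizer,
                 useIndicatorPath = useIndicatorPath,
                 seed = as.integer(seed)),
            class = "gcnConfig")
}

# per-feature z-score; zero-variance features dropped with a warning
.zscoreMatrix <- function(X, label = "omics") {
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("%s: dropped %d zero-variance feature(s)",
                    label, sum(!keep)), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(X) == 0L) stop(sprintf("%s: no informative features", label), call. = FALSE)
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

# assemble everything the forward/backward passes need
.prepareData <- function(ds, config) {
  V <- nOmics(ds); N <- nSamples(ds)
  ids <- intactIDs(ds)
  X <- A <- Top <- idxList <- vector("list", V)
  full <- TRUE
  for (v in seq_len(V)) {
    Xv <- .zscoreMatrix(ds@omics[[v]], label = sprintf("omics %d", v))
    attr(Xv, "scaled:center") <- NULL
    attr(Xv, "scaled:scale") <- NULL
    X[[v]] <- Xv
    k <- if (is.null(config$kNeighbors)) defaultK(nrow(Xv)) else config$kNeighbors
    g <- buildKnnGraph(Xv, k)
    A[[v]] <- g$adj
    Top[[v]] <- normalizeAdjacency(g)
    idx <- match(rownames(Xv), ids)
    aligned <- nrow(Xv) == N && all(idx == seq_len(N))
    if (!aligned) full <- FALSE
    idxList[[v]] <- idx
  }
  useInd <- config$useIndicatorPath
  if (is.na(useInd)) useInd <- !full
  if (!useInd && !full)
    stop("dataset is partial but useIndicatorPath = FALSE", call. = FALSE)
  if (!useInd) idxList <- vector("list", V)  # NULL entries: no-indicator path
  cnt <- numeric(N)
  for (v in seq_len(V)) {
    if (is.null(idxList[[v]])) cnt <- cnt + 1 else cnt[idxList[[v]]] <- cnt[idxList[[v]]] + 1
  }
  list(X = X, A = A, T = Top, idx = idxList, counts = cnt,
       N = N, V = V, ids = ids, dims = vapply(X, ncol, integer(1)))
}

# ---- forward / backward -------------------------------------------------

# forward pass storing intermediates; P = fixed target distribution (or
# NULL outside fine-tuning)
.forward <- function(model, prep, P = NULL, alpha = 1, beta = 1) {
  V <- prep$V; M <- model$depth; pars <- model$params
  Zs <- Spre <- vector("list", V)
  for (v in seq_len(V)) {
    Z <- prep$X[[v]]
    acts <- pres <- vector("list", M)
    for (m in seq_len(M)) {
      S <- prep$T[[v]] %*% Z
      pres[[m]] <- S
      Z <- tanh(S %*% pars[[sprintf("enc.%d.%d", v, m)]])
      acts[[m]] <- Z
    }
    Zs[[v]] <- acts; Spre[[v]] <- pres
  }
  acc <- matrix(0, prep$N, model$d)
  for (v in seq_len(V)) {
    idx <- prep$idx[[v]]
    if (is.null(idx)) acc <- acc + Zs[[v]][[M]]
    else acc[idx, ] <- acc[idx, , drop = FALSE] + Zs[[v]][[M]]
  }
  H <- acc / prep$counts
  B <- dec <- decS <- Xhat <- Ahat <- vector("list", V)
  lNar <- 0; lGsr <- 0
  for (v in seq_len(V)) {
    idx <- prep$idx[[v]]
    Bv <- if (is.null(idx)) H else H[idx, , drop = FALSE]
    B[[v]] <- Bv
    dacts <- dpres <- vector("list", M)
    Z <- Bv
    for (m in seq_len(M)) {
      if (m == 1L) {
        Z <- tanh(Z %*% pars[[sprintf("dec.%d.%d", v, m)]])
      } else {
        S <- prep$T[[v]] %*% Z
        dpres[[m]] <- S
        Z <- tanh(S %*% pars[[sprintf("dec.%d.%d", v, m)]])
      }
      dacts[[m]] <- Z
    }
    dec[[v]] <- dacts; decS[[v]] <- dpres
    Xhat[[v]] <- Z
    Ahat[[v]] <- tanh(Bv %*% pars[[sprintf("wg.%d", v)]] %*% t(Bv))
    lNar <- lNar + sum((prep$X[[v]] - Xhat[[v]])^2)
    lGsr <- lGsr + sum((prep$A[[v]] - Ahat[[v]])^2)
  }
  Q <- NULL; lSs <- 0
  if (!is.null(model$mu) && !is.null(P)) {
    Q <- softAssignment(H, model$mu)
    lSs <- selfSupervisedLoss(P, Q)
  }
  list(Zs = Zs, Spre = Spre, H = H, B = B, dec = dec, decS = decS,
       Xhat = Xhat, Ahat = Ahat, Q = Q,
       lNar = lNar, lGsr = lGsr, lSs = lSs,
       total = lNar + alpha * lGsr + beta * lSs)
}

# analytic gradients of the total loss w.r.t. every parameter
.backward <- function(model, prep, fw, P = NULL, alpha = 1, beta = 1) {
  V <- prep$V; M <- model$depth; pars <- model$params
  g <- lapply(pars, function(W) matrix(0, nrow(W), ncol(W)))
  dH <- matrix(0, prep$N, model$d)
  for (v in seq_len(V)) {
    Tv <- prep$T[[v]]; Bv <- fw$B[[v]]
    # attribute decoder
    dZ <- 2 * (fw$Xhat[[v]] - prep$X[[v]])
    if (M >= 2L) {
      for (m in seq.int(M, 2L)) {
        act <- fw$dec[[v]][[m]]
        dU <- dZ * (1 - act^2)
        nm <- sprintf("dec.%d.%d", v, m)
        g[[nm]] <- g[[nm]] + crossprod(fw$decS[[v]][[m]], dU)
        dZ <- Tv %*% tcrossprod(dU, pars[[nm]])
      }
    }
    act <- fw$dec[[v]][[1L]]
    dU <- dZ * (1 - act^2)
    nm <- sprintf("dec.%d.1", v)
    g[[nm]] <- g[[nm]] + crossprod(Bv, dU)
    dB <- tcrossprod(dU, pars[[nm]])
    # bilinear graph decoder
    Ahat <- fw$Ahat[[v]]
    dM <- (2 * alpha) * (Ahat - prep$A[[v]]) * (1 - Ahat^2)
    Wg <- pars[[sprintf("wg.%d", v)]]
    g[[sprintf("wg.%d", v)]] <- g[[sprintf("wg.%d", v)]] +
      crossprod(Bv, dM %*% Bv)
    dB <- dB + dM %*% (Bv %*% t(Wg)) + crossprod(dM, Bv %*% Wg)
    idx <- prep$idx[[v]]
    if (is.null(idx)) dH <- dH + dB
    else dH[idx, ] <- dH[idx, , drop = FALSE] + dB
  }
  gmu <- NULL
  if (!is.null(model$mu) && !is.null(P) && beta > 0) {
    H <- fw$H; mu <- model$mu
    d2 <- outer(rowSums(H^2), rep(1, nrow(mu))) +
      outer(rep(1, nrow(H)), rowSums(mu^2)) - 2 * H %*% t(mu)
    d2[d2 < 0] <- 0
    s <- 1 / (1 + d2)
    Wm <- (P - fw$Q) * s
    dH <- dH + beta * 2 * (rowSums(Wm) * H - Wm %*% mu)
    gmu <- beta * (-2) * (crossprod(Wm, H) - colSums(Wm) * mu)
  }
  dAcc <- dH / prep$counts
  for (v in seq_len(V)) {
    idx <- prep$idx[[v]]
    dZ <- if (is.null(idx)) dAcc else dAcc[idx, , drop = FALSE]
    Tv <- prep$T[[v]]
    for (m in seq.int(M, 1L)) {
      act <- fw$Zs[[v]][[m]]
      dU <- dZ * (1 - act^2)
      nm <- sprintf("enc.%d.%d", v, m)
      g[[nm]] <- g[[nm]] + crossprod(fw$Spre[[v]][[m]], dU)
      if (m > 1L) dZ <- Tv %*% tcrossprod(dU, pars[[nm]])
    }
  }
  list(params = g, mu = gmu)
}

# ---- optimizers ---------------------------------------------------------

.optInit <- function(model) {
  zeros <- lapply(model$params, function(W) matrix(0, nrow(W), ncol(W)))
  list(m = zeros, v = zeros, mMu = NULL, vMu = NULL, t = 0L)
}

.optStep <- function(model, grads, st, lr, optimizer = "adam",
                     b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (optimizer == "sgd") {
    for (nm in names(model$params))
      model$params[[nm]] <- model$params[[nm]] - lr * grads$params[[nm]]
    if (!is.null(grads$mu)) model$mu <- model$mu - lr * grads$mu
    return(list(model = model, state = st))
  }
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(model$params)) {
    gW <- grads$params[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gW
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gW^2
    model$params[[nm]] <- model$params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  if (!is.null(grads$mu)) {
    if (is.null(st$mMu)) {
      st$mMu <- matrix(0, nrow(model$mu), ncol(model$mu))
      st$vMu <- st$mMu
    }
    st$mMu <- b1 * st$mMu + (1 - b1) * grads$mu
    st$vMu <- b2 * st$vMu + (1 - b2) * grads$mu^2
    model$mu <- model$mu - lr * (st$mMu / c1) / (sqrt(st$vMu / c2) + eps)
  }
  list(model = model, state = st)
}

# ---- training phases ----------------------------------------------------

#' Pre-train the autoencoder on the reconstruction losses
#'
#' Full-batch gradient training of the encoders, attribute decoders and
#' graph decoders minimizing \code{lNar + alpha * lGsr}; self-supervision
#' is excluded in this phase. Deterministic given the config seed.
#'
#' @param ds a [MultiOmicsSet-class].
#' @param config a [gcnConfig()].
#' @return list with \code{model} (internal parameter state), \code{H}
#'   (consensus embedding after the final epoch), \code{prep} (prepared
#'   data), and \code{lossHistory} (data.frame, one row per epoch).
#' @export
pretrainGCN <- function(ds, config = gcnConfig()) {
  set.seed(config$seed)
  prep <- .prepareData(ds, config)
  d <- if (is.null(config$d)) defaultEmbeddingDim(prep$dims) else as.integer(config$d)
  d <- max(2L, min(d, 4L * min(prep$dims)))
  model <- .initModel(prep$dims, d, hidden = config$hidden, depth = config$depth)
  st <- .optInit(model)
  hist <- vector("list", config$pretrainEpochs)
  fw <- NULL
  for (ep in seq_len(config$pretrainEpochs)) {
    fw <- .forward(model, prep, P = NULL, alpha = config$alpha, beta = config$beta)
    if (!is.finite(fw$total))
      stop(sprintf("non-finite loss at pre-training epoch %d", ep), call. = FALSE)
    hist[[ep]] <- data.frame(phase = "pretrain", epoch = ep,
                             lNar = fw$lNar, lGsr = fw$lGsr, lSs = 0,
                             total = fw$lNar + config$alpha * fw$lGsr,
                             qDev = NA_real_, pDev = NA_real_)
    gr <- .backward(model, prep, fw, P = NULL, alpha = config$alpha,
                    beta = config$beta)
    upd <- .optStep(model, gr, st, config$learningRate, config$optimizer)
    model <- upd$model; st <- upd$state
  }
  fwFinal <- .forward(model, prep, P = NULL, alpha = config$alpha,
                      beta = config$beta)
  H <- fwFinal$H
  rownames(H) <- prep$ids
  list(model = model, H = H, prep = prep, optState = st,
       lossHistory = do.call(rbind, hist))
}

#' Fine-tune with self-supervision and produce the final clustering
#'
#' Estimates the cluster count once by the eigengap rule on the pre-trained
#' embedding, initializes cluster centers from the spectral partition, then
#' trains with the full loss (reconstructions plus KL self-supervision)
#' while refreshing the target distribution every
#' \code{pRefreshInterval} epochs, stopping early when cluster memberships
#' stabilize. Final labels come from spectral clustering of the final
#' embedding with the frozen cluster count.
#'
#' @param pre result of [pretrainGCN()].
#' @param config the same [gcnConfig()].
#' @return A [SubtypeFit-class].
#' @export
finetuneGCN <- function(pre, config = gcnConfig()) {
  model <- pre$model; prep <- pre$prep
  H <- pre$H
  kSpec <- if (is.null(config$kNeighbors)) defaultK(prep$N) else config$kNeighbors
  init <- .clusterEmbedding(H, k = kSpec, cRange = config$cRange,
                            seed = config$seed + 1L,
                            indexWeighted = config$indexWeightedGap)
  C <- init$C
  mu <- matrix(0, C, model$d)
  for (c in seq_len(C)) mu[c, ] <- colMeans(H[init$labels == c, , drop = FALSE])
  model$mu <- mu
  st <- pre$optState
  P <- NULL
  prevLabels <- NULL
  hist <- list()
  for (ep in seq_len(config$finetuneEpochs)) {
    if ((ep - 1L) %% config$pRefreshInterval == 0L) {
      fwQ <- .forward(model, prep, P = NULL)
      Q <- softAssignment(fwQ$H, model$mu)
      P <- targetDistribution(Q)
      labs <- max.col(Q, ties.method = "first")
      if (!is.null(prevLabels)) {
        changed <- mean(labs != prevLabels)
        if (changed < config$convergenceTol) {
          prevLabels <- labs
          break
        }
      }
      prevLabels <- labs
    }
    fw <- .forward(model, prep, P = P, alpha = config$alpha, beta = config$beta)
    if (!is.finite(fw$total))
      stop(sprintf("non-finite loss at fine-tuning epoch %d", ep), call. = FALSE)
    hist[[length(hist) + 1L]] <-
      data.frame(phase = "finetune", epoch = ep,
                 lNar = fw$lNar, lGsr = fw$lGsr, lSs = fw$lSs, total = fw$total,
                 # row-stochasticity diagnostics for Q and the frozen target P
                 qDev = max(abs(rowSums(fw$Q) - 1)),
                 pDev = max(abs(rowSums(P) - 1)))
    gr <- .backward(model, prep, fw, P = P, alpha = config$alpha,
                    beta = config$beta)
    upd <- .optStep(model, gr, st, config$learningRate, config$optimizer)
    model <- upd$model; st <- upd$state
  }
  fwFinal <- .forward(model, prep, P = NULL)
  H <- fwFinal$H
  rownames(H) <- prep$ids
  final <- .clusterEmbedding(H, k = kSpec, C = C, seed = config$seed + 2L)
  labels <- final$labels
  names(labels) <- prep$ids
  lossHistory <- rbind(pre$lossHistory, do.call(rbind, hist))
  new("SubtypeFit", H = H, labels = labels, nClusters = as.integer(C),
      lossHistory = lossHistory, config = unclass(config))
}

#' Fit the model and predict subtypes
#'
#' End-to-end pipeline: per-feature z-score normalization of every omics
#' layer, kNN graph and indicator construction, reconstruction
#' pre-training, self-supervised fine-tuning, and eigengap-guided spectral
#' clustering of the consensus embedding. Works unchanged on partial
#' datasets (omics layers covering only a subset of patients).
#'
#' @param ds a [MultiOmicsSet-class], full or partial.
#' @param config a [gcnConfig()].
#' @return A [SubtypeFit-class].
#' @examples
#' \donttest{
#' ds <- simulateMultiOmics(90, 2, 3, dims = c(12, 15), separation = 8, seed = 1)
#' fit <- fitPredict(ds, gcnConfig(pretrainEpochs = 30, finetuneEpochs = 10))
#' table(clusterLabels(fit), trueLabels(ds))
#' }
#' @export
fitPredict <- function(ds, config = gcnConfig()) {
  stopifnot(is(ds, "MultiOmicsSet"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  pre <- stage("pretrain", pretrainGCN(ds, config))
  stage("finetune", finetuneGCN(pre, config))
}
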