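# shared fixtures, all generated in code

# tiny deterministic coordinates for graph tests
lineX <- function() matrix(c(0, 1, 10, 11), 4, 1)

# small multi-omics set used by model-level tests
tinySet <- function(n = 8, dims = c(4, 5), clusters = 2, sep = 3, seed = 7) {
  simulateMultiOmics(n, length(dims), clusters, dims, separation = sep, seed = seed)
}

# prepared data + initialized model with fixed shapes (internal surfaces)
tinyModel <- function(ds = tinySet(), d = 3, hidden = 3, seed = 5) {
  cfg <- gcnConfig(d = d, hidden = hidden, seed = seed)
  prep <- omicsGCN:::.prepareData(ds, cfg)
  set.seed(seed)
  model <- omicsGCN:::.initModel(prep$dims, d, hidden = hidden, depth = 2L)
  list(prep = prep, model = model, cfg = cfg)
}

# explicit-loop tanh graph-convolution layer: per-node accumulation oracle
loopGCNLayer <- function(op, Z, W) {
  n <- nrow(Z)
  agg <- matrix(0, n, ncol(Z))
  for (i in seq_len(n))
    for (j in seq_len(n))
      agg[i, ] <- agg[i, ] + op[i, j] * Z[j, ]
  pre <- matrix(0, n, ncol(W))
  for (i in seq_len(n))
    for (q in seq_len(ncol(W)))
      pre[i, q] <- sum(agg[i, ] * W[, q])
  tanh(pre)
}

# the easy synthetic benchmark family used by the recovery experiments
easyBenchmark <- function(seed) {
  simulateMultiOmics(300, 2, 3, dims = c(50, 80), separation = 8,
                     noiseSD = 1, seed = seed)
}

ariOf <- function(labels, truth) mclust::adjustedRandIndex(labels, truth)

# fits for the recovery/robustness experiments are expensive; cache them
# across acceptance test blocks within one run
benchCache <- new.env(parent = emptyenv())

benchFit <- function(theta, seedIndex) {
  key <- sprintf("t%s_s%d", theta, seedIndex)
  if (!is.null(benchCache[[key]])) return(benchCache[[key]])
  ds <- easyBenchmark(100 + seedIndex)
  dst <- if (theta > 0) applyMissingness(ds, 1, theta, seed = 200 + seedIndex) else ds
  fit <- suppressWarnings(fitPredict(dst, gcnConfig(seed = seedIndex)))
  out <- list(fit = fit, ari = ariOf(clusterLabels(fit), trueLabels(ds)),
              C = nClusters(fit))
  benchCache[[key]] <- out
  out
}
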