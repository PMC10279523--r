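test_that("encoder layers match an explicit message-passing loop", {
  set.seed(41)
  X <- matrix(rnorm(5 * 3), 5, 3)
  op <- normalizeAdjacency(buildKnnGraph(X, 2))
  W1 <- matrix(rnorm(3 * 4), 3, 4) * 0.5
  W2 <- matrix(rnorm(4 * 2), 4, 2) * 0.5
  Z <- encodeOmics(X, op, list(W1, W2))
  ref <- loopGCNLayer(op, loopGCNLayer(op, X, W1), W2)
  expect_lt(max(abs(Z - ref)), 1e-10)
})

test_that("encoder zero-weight and linear-regime limits hold", {
  X <- matrix(rnorm(12), 4, 3)
  op <- diag(4)
  expect_equal(encodeOmics(X, op, list(matrix(0, 3, 2))), matrix(0, 4, 2))
  # tanh is linear to first order: tiny pre-activations pass through
  W <- matrix(runif(6, -1, 1) * 1e-3 / max(abs(X)), 3, 2)
  expect_lt(max(abs(encodeOmics(X, op, list(W)) - X %*% W)), 1e-6)
})

test_that("encoder reports the offending layer on shape mismatch", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(encodeOmics(X, diag(4), list(matrix(0, 2, 2))), "layer 1")
  expect_error(encodeOmics(X, diag(4), list(matrix(0, 3, 2), matrix(0, 3, 1))),
               "layer 2")
})

test_that("consensus fusion averages available embeddings per sample", {
  Z1 <- matrix(rnorm(6), 3, 2)
  Z2 <- matrix(rnorm(6), 3, 2)
  # single full omics: H = Z exactly
  expect_equal(fuseConsensus(list(Z1)), Z1)
  # two full omics: plain mean
  expect_equal(fuseConsensus(list(Z1, Z2)), (Z1 + Z2) / 2)

  # partial: sample b measured only in omics 1
  intact <- c("a", "b", "c")
  G1 <- buildIndicatorMatrix(intact, intact)
  G2 <- buildIndicatorMatrix(c("a", "c"), intact)
  H <- fuseConsensus(list(Z1, Z2[c(1, 3), , drop = FALSE]), list(G1, G2))
  # hand evaluation of the fusion ratio per sample
  expect_equal(H[1, ], (Z1[1, ] + Z2[1, ]) / 2)
  expect_equal(H[2, ], Z1[2, ])
  expect_equal(H[3, ], (Z1[3, ] + Z2[3, ]) / 2)
})

test_that("fusion errors when a sample is covered by no omics", {
  intact <- c("a", "b")
  G <- buildIndicatorMatrix("a", intact)
  expect_error(fuseConsensus(list(matrix(1, 1, 2)), list(G)), "absent from every omics")
})

test_that("indicator and no-indicator fusion are bit-identical on full data", {
  set.seed(13)
  Z1 <- matrix(rnorm(10), 5, 2); Z2 <- matrix(rnorm(10), 5, 2)
  ids <- paste0("s", 1:5)
  G <- buildIndicatorMatrix(ids, ids)
  expect_identical(fuseConsensus(list(Z1, Z2), list(G, G)),
                   fuseConsensus(list(Z1, Z2)))
})

test_that("attribute decoder matches a hand-unrolled two-layer computation", {
  set.seed(43)
  H <- matrix(rnorm(4 * 2), 4, 2)
  op <- normalizeAdjacency(buildKnnGraph(H, 2))
  Wd1 <- matrix(rnorm(2 * 3), 2, 3) * 0.5
  Wd2 <- matrix(rnorm(3 * 5), 3, 5) * 0.5
  X1 <- decodeAttributes(H, op, list(Wd1, Wd2))
  ref <- loopGCNLayer(op, tanh(H %*% Wd1), Wd2)
  expect_lt(max(abs(X1 - ref)), 1e-10)

  # zero weights collapse the reconstruction
  expect_equal(decodeAttributes(H, op, list(matrix(0, 2, 3), matrix(0, 3, 5))),
               matrix(0, 4, 5))
  # identity indicator reduces the first layer to tanh(H W)
  G <- buildIndicatorMatrix(paste0("s", 1:4), paste0("s", 1:4))
  expect_identical(decodeAttributes(H, op, list(Wd1, Wd2), G),
                   decodeAttributes(H, op, list(Wd1, Wd2)))
})

test_that("bilinear graph decoder matches a double-loop oracle", {
  set.seed(47)
  H <- matrix(rnorm(3 * 2), 3, 2)
  Wg <- matrix(rnorm(4), 2, 2)
  Ahat <- decodeGraph(H, Wg)
  ref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    ref[i, j] <- tanh(sum(H[i, ] * (Wg %*% H[j, ])))
  expect_lt(max(abs(Ahat - ref)), 1e-12)

  expect_equal(decodeGraph(H, matrix(0, 2, 2)), matrix(0, 3, 3))
  Ws <- Wg + t(Wg)
  expect_equal(decodeGraph(H, Ws), t(decodeGraph(H, Ws)))
  expect_true(all(abs(Ahat) < 1))
})

test_that("reconstruction losses are summed squared Frobenius norms", {
  X <- matrix(rnorm(4), 2, 2)
  expect_equal(attributeReconstructionLoss(list(X), list(X)), 0)
  Xd <- X; Xd[1, 2] <- Xd[1, 2] + 0.3
  expect_equal(attributeReconstructionLoss(list(X), list(Xd)), 0.09)

  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(graphReconstructionLoss(list(A), list(matrix(0, 2, 2))), 2)

  set.seed(3)
  P1 <- matrix(rnorm(16), 4, 4); P2 <- matrix(rnorm(16), 4, 4)
  Q1 <- matrix(rnorm(16), 4, 4); Q2 <- matrix(rnorm(16), 4, 4)
  ref <- 0
  for (i in 1:4) for (j in 1:4)
    ref <- ref + (P1[i, j] - Q1[i, j])^2 + (P2[i, j] - Q2[i, j])^2
  expect_lt(abs(graphReconstructionLoss(list(P1, P2), list(Q1, Q2)) - ref), 1e-12)
  expect_error(attributeReconstructionLoss(list(P1), list(matrix(0, 2, 2))),
               "shape")
})

test_that("graph loss stays positive whenever the adjacency has edges", {
  set.seed(19)
  for (rep in 1:5) {
    H <- matrix(rnorm(10), 5, 2)
    Wg <- matrix(rnorm(4), 2, 2) * 3
    A <- buildKnnGraph(matrix(rnorm(10), 5, 2), 2)$adj
    expect_gt(graphReconstructionLoss(list(A), list(decodeGraph(H, Wg))), 0)
  }
})

test_that("soft assignment follows the Student-t closed forms", {
  # equidistant point: uniform row
  mu <- rbind(c(1, 0), c(-1, 0))
  Q <- softAssignment(matrix(c(0, 5), 1, 2), mu)
  expect_equal(as.numeric(Q), c(0.5, 0.5))

  # h at the first center, unit squared distance to the second: (1, 1/2) -> (2/3, 1/3)
  Q <- softAssignment(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(1, 1)))
  expect_equal(as.numeric(Q), c(2 / 3, 1 / 3))

  set.seed(23)
  H <- matrix(rnorm(40), 10, 4)
  mu <- matrix(rnorm(12), 3, 4)
  Q <- softAssignment(H, mu)
  expect_lt(max(abs(rowSums(Q) - 1)), 1e-9)
  expect_true(all(Q > 0 & Q <= 1))
})

test_that("target distribution sharpens while preserving row stochasticity", {
  # single sample: P = Q exactly (algebraic fixed point)
  Q1 <- matrix(c(0.3, 0.2, 0.5), 1, 3)
  expect_equal(targetDistribution(Q1), Q1)

  # uniform Q stays uniform
  Qu <- matrix(1 / 4, 6, 4)
  expect_equal(targetDistribution(Qu), Qu)

  set.seed(29)
  H <- matrix(rnorm(40), 10, 4)
  Q <- softAssignment(H, matrix(rnorm(8), 2, 4))
  P <- targetDistribution(Q)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)

  Qbad <- cbind(matrix(0.5, 3, 2), 0)
  expect_error(targetDistribution(Qbad), "empty")
})

test_that("KL self-supervision loss has its textbook values and bounds", {
  Q <- matrix(c(0.4, 0.6), 1, 2)
  expect_equal(selfSupervisedLoss(Q, Q), 0)
  expect_equal(selfSupervisedLoss(matrix(c(1, 0), 1, 2),
                                  matrix(c(0.5, 0.5), 1, 2)), log(2))
  set.seed(37)
  for (rep in 1:10) {
    Q <- softAssignment(matrix(rnorm(20), 5, 4), matrix(rnorm(12), 3, 4))
    expect_gte(selfSupervisedLoss(targetDistribution(Q), Q), 0)
  }
  expect_error(selfSupervisedLoss(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2)),
               "infinite")
})

test_that("total loss combines components with the trade-off weights", {
  expect_equal(totalLoss(1, 2, 3)$total, 6)           # alpha = beta = 1 defaults
  expect_equal(totalLoss(0, 0, 0)$total, 0)
  expect_equal(totalLoss(1, 2, 3, alpha = 0.5, beta = 2)$total, 8)
  expect_error(totalLoss(1, 2, 3, alpha = -1), "nonnegative")
  lb <- totalLoss(0.7, 1.3, 0.2, alpha = 0.9, beta = 1.1)
  expect_lt(abs(lb$total - (lb$lNar + lb$alpha * lb$lGsr + lb$beta * lb$lSs)), 1e-9)
})

test_that("analytic gradients agree with central finite differences", {
  tm <- tinyModel()
  model <- tm$model; prep <- tm$prep
  set.seed(11)
  model$mu <- matrix(rnorm(2 * 3), 2, 3)
  fw0 <- omicsGCN:::.forward(model, prep)
  Q <- softAssignment(fw0$H, model$mu)
  P <- targetDistribution(Q)
  alpha <- 0.7; beta <- 1.3
  fw <- omicsGCN:::.forward(model, prep, P = P, alpha = alpha, beta = beta)
  gr <- omicsGCN:::.backward(model, prep, fw, P = P, alpha = alpha, beta = beta)
  lossAt <- function(m)
    omicsGCN:::.forward(m, prep, P = P, alpha = alpha, beta = beta)$total
  eps <- 1e-6
  set.seed(12)
  for (nm in names(model$params)) {
    W <- model$params[[nm]]
    for (k in sample(length(W), min(4, length(W)))) {
      up <- model; up$params[[nm]][k] <- W[k] + eps
      dn <- model; dn$params[[nm]][k] <- W[k] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_lt(abs(num - gr$params[[nm]][k]) /
                  max(1e-8, abs(num) + abs(gr$params[[nm]][k])), 1e-5,
                label = sprintf("gradient of %s[%d]", nm, k))
    }
  }
  for (k in seq_along(model$mu)) {
    up <- model; up$mu[k] <- model$mu[k] + eps
    dn <- model; dn$mu[k] <- model$mu[k] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_lt(abs(num - gr$mu[k]) / max(1e-8, abs(num) + abs(gr$mu[k])), 1e-5,
              label = sprintf("gradient of mu[%d]", k))
  }
})

test_that("training forward pass equals the exported operations composed", {
  tm <- tinyModel()
  model <- tm$model; prep <- tm$prep
  fw <- omicsGCN:::.forward(model, prep)
  for (v in 1:2) {
    enc <- list(model$params[[sprintf("enc.%d.1", v)]],
                model$params[[sprintf("enc.%d.2", v)]])
    Z <- encodeOmics(prep$X[[v]], prep$T[[v]], enc)
    expect_equal(fw$Zs[[v]][[2]], Z, tolerance = 1e-12)
  }
  H <- fuseConsensus(list(fw$Zs[[1]][[2]], fw$Zs[[2]][[2]]))
  expect_equal(fw$H, H, tolerance = 1e-12)
  for (v in 1:2) {
    dec <- list(model$params[[sprintf("dec.%d.1", v)]],
                model$params[[sprintf("dec.%d.2", v)]])
    expect_equal(fw$Xhat[[v]], decodeAttributes(H, prep$T[[v]], dec),
                 tolerance = 1e-12)
    expect_equal(fw$Ahat[[v]], decodeGraph(H, model$params[[sprintf("wg.%d", v)]]),
                 tolerance = 1e-12)
  }
  expect_equal(fw$lNar, attributeReconstructionLoss(prep$X, fw$Xhat))
  expect_equal(fw$lGsr, graphReconstructionLoss(prep$A, fw$Ahat))
})
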