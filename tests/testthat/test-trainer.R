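test_that("embedding-dimension rule follows the 0.8x / 1600 convention", {
  expect_equal(defaultEmbeddingDim(c(500, 2000, 12000)), 400L)
  expect_equal(defaultEmbeddingDim(c(3000, 5000)), 1600L)
  expect_equal(defaultEmbeddingDim(10), 8L)
  expect_equal(defaultEmbeddingDim(1999), 1599L)
  expect_error(defaultEmbeddingDim(integer(0)), "nonempty")
})

test_that("config defaults match the published settings", {
  cfg <- gcnConfig()
  expect_equal(cfg$learningRate, 0.001)
  expect_equal(cfg$alpha, 1)
  expect_equal(cfg$beta, 1)
  expect_equal(cfg$cRange, c(2L, 15L))
  expect_error(gcnConfig(learningRate = 0), "learningRate")
  expect_error(gcnConfig(cRange = c(5, 3)))
})

test_that("pre-training reduces the reconstruction losses deterministically", {
  ds <- tinySet(n = 60, dims = c(8, 10), clusters = 3, sep = 8, seed = 2)
  cfg <- gcnConfig(pretrainEpochs = 150, seed = 4)
  pre <- pretrainGCN(ds, cfg)
  h <- pre$lossHistory
  expect_equal(nrow(h), 150)
  obj <- h$lNar + cfg$alpha * h$lGsr
  # epoch-mean over the last 10% below the first 10%
  n10 <- 15
  expect_lt(mean(obj[(150 - n10 + 1):150]), mean(obj[1:n10]))
  expect_true(all(is.finite(obj)))

  pre2 <- pretrainGCN(ds, cfg)
  expect_identical(pre2$lossHistory, h)
  expect_identical(pre2$H, pre$H)
})

test_that("fine-tuning excludes self-supervision when beta is zero", {
  ds <- tinySet(n = 40, dims = c(6, 7), clusters = 2, sep = 8, seed = 3)
  cfg <- gcnConfig(pretrainEpochs = 60, finetuneEpochs = 12, beta = 0, seed = 1)
  fit <- suppressWarnings(fitPredict(ds, cfg))
  h <- lossHistory(fit)
  ft <- h[h$phase == "finetune", ]
  expect_gt(nrow(ft), 0)
  expect_true(all(abs(ft$total - (ft$lNar + ft$lGsr)) < 1e-9))
})

test_that("loss breakdown identity and assignment row sums hold every epoch", {
  ds <- tinySet(n = 50, dims = c(6, 8), clusters = 2, sep = 8, seed = 9)
  cfg <- gcnConfig(pretrainEpochs = 80, finetuneEpochs = 20, seed = 2,
                   alpha = 0.8, beta = 1.2)
  fit <- suppressWarnings(fitPredict(ds, cfg))
  h <- lossHistory(fit)
  expect_true(all(abs(h$total - (h$lNar + cfg$alpha * h$lGsr + cfg$beta * h$lSs))
                  < 1e-9))
  ft <- h[h$phase == "finetune", ]
  expect_true(all(ft$qDev < 1e-6))
  expect_true(all(ft$pDev < 1e-6))
})

test_that("labels are bit-identical across repeated seeded runs", {
  ds <- tinySet(n = 40, dims = c(6, 7), clusters = 2, sep = 8, seed = 5)
  cfg <- gcnConfig(pretrainEpochs = 50, finetuneEpochs = 10, seed = 3)
  f1 <- suppressWarnings(fitPredict(ds, cfg))
  f2 <- suppressWarnings(fitPredict(ds, cfg))
  expect_identical(clusterLabels(f1), clusterLabels(f2))
  expect_identical(consensus(f1), consensus(f2))
})

test_that("indicator and plain code paths agree bit-for-bit on full data", {
  ds <- tinySet(n = 40, dims = c(6, 7), clusters = 2, sep = 8, seed = 6)
  cfg <- function(ind) gcnConfig(pretrainEpochs = 40, finetuneEpochs = 10,
                                 seed = 2, useIndicatorPath = ind)
  fInd <- suppressWarnings(fitPredict(ds, cfg(TRUE)))
  fPlain <- suppressWarnings(fitPredict(ds, cfg(FALSE)))
  expect_identical(consensus(fInd), consensus(fPlain))
  expect_identical(clusterLabels(fInd), clusterLabels(fPlain))
  expect_identical(lossHistory(fInd), lossHistory(fPlain))
  # theta = 0 thinning is the same dataset object, hence the same result
  expect_identical(applyMissingness(ds, 1, 0, seed = 1), ds)
})

test_that("a partial single-omics-loss dataset still fits end to end", {
  ds <- tinySet(n = 50, dims = c(6, 8), clusters = 2, sep = 8, seed = 8)
  dst <- applyMissingness(ds, 2, 0.3, seed = 4)
  fit <- suppressWarnings(
    fitPredict(dst, gcnConfig(pretrainEpochs = 150, finetuneEpochs = 15, seed = 1)))
  expect_equal(length(clusterLabels(fit)), 50)
  expect_identical(names(clusterLabels(fit)), intactIDs(ds))
})

test_that("a single-omics dataset reduces to a plain graph autoencoder", {
  ds <- simulateMultiOmics(40, 1, 2, dims = 8, separation = 8, seed = 4)
  # small cohorts need denser graphs than the log2 default (20-sample
  # clusters fragment under k = 7)
  fit <- suppressWarnings(
    fitPredict(ds, gcnConfig(pretrainEpochs = 300, finetuneEpochs = 10,
                             kNeighbors = 12, seed = 1)))
  expect_equal(ariOf(clusterLabels(fit), trueLabels(ds)), 1)
})

test_that("errors are tagged with the failing stage", {
  ds <- tinySet(n = 20, dims = c(4, 5), clusters = 2, sep = 5, seed = 2)
  bad <- ds
  bad@omics[[1]][, 1] <- 1  # constant feature triggers the z-score warning path
  expect_warning(omicsGCN:::.zscoreMatrix(bad@omics[[1]]), "zero-variance")
  # partial data with the indicator path disabled fails in the pretrain stage
  dst <- applyMissingness(ds, 1, 0.2, seed = 1)
  expect_error(fitPredict(dst, gcnConfig(useIndicatorPath = FALSE)), "pretrain")
})
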