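test_that("parameter counting matches per-layer arithmetic", {
  expect_identical(countParameters(archConfig()), 8037L)
  # per-layer: 480+820+2210+220+210+3330+558+0 hidden, 57+152 heads
  perLayer <- c(1 * 11 * 40 + 40, 40 * 1 * 20 + 20, 20 * 11 * 10 + 10,
                10 * 1 * 20 + 20, 20 * 1 * 10 + 10, 10 * 11 * 30 + 30,
                30 * 1 * 18 + 18, 0, 18 * 3 + 3, 18 * 8 + 8)
  expect_equal(sum(perLayer), 8037)
  # a single 1->1 conv with kernel 1 has one weight and one bias
  tiny <- archConfig(depths = 1, kernels = 1, kinds = "conv",
                     classifierChannels = 0L, regressorChannels = 0L)
  expect_identical(countParameters(tiny), 2L)
  # widening C1 changes exactly the C1 and C2 weight terms
  wide <- archConfig(depths = c(80, 20, 10, 20, 10, 30, 18, 18))
  expect_equal(countParameters(wide),
               8037 + (1 * 11 * 80 + 80 - 480) + (80 * 20 + 20 - 820))
  expect_identical(receptiveField(archConfig()), 33L)
})

test_that("architecture validation rejects inconsistent layer lists", {
  expect_error(archConfig(depths = c(40, 20), kernels = 11), "same length")
  expect_error(archConfig(kernels = c(10, 1, 11, 1, 1, 11, 1, 3)), "odd")
  expect_error(archConfig(depths = c(40, 20, 10, 20, 10, 30, 18, 17)),
               "preserve depth")
})

test_that("network builds are seeded and deterministic", {
  n1 <- buildNetwork(seed = 3)
  n2 <- buildNetwork(seed = 3)
  n3 <- buildNetwork(seed = 4)
  expect_identical(n1@weights, n2@weights)
  expect_false(identical(n1@weights, n3@weights))
  expect_identical(countParameters(n1), 8037L)
})

test_that("forward pass normalizes scores and preserves length", {
  net <- buildNetwork(seed = 1)
  x <- runif(300)
  fw <- forwardNetwork(net, x)
  expect_identical(dim(fw$classScores), c(300L, 3L))
  expect_identical(dim(fw$regressor), c(300L, 8L))
  expect_lt(max(abs(rowSums(fw$classScores) - 1)), 1e-6)
  expect_error(forwardNetwork(net, runif(20)), "receptive field")
})

test_that("forward pass is translation covariant away from boundaries", {
  net <- buildNetwork(seed = 2)
  set.seed(8)
  x <- as.numeric(intensities(synthSpectrum1D(
    voigtPeaks(c(80, 140), c(1, 0.5), c(10, 8), c(0.3, 0.7)), 300,
    noiseSigma = 0.01, seed = 1)))
  shift <- 50
  xs <- c(x[(shift + 1):300], x[1:shift])   # circular shift left by 50
  a <- forwardNetwork(net, x)$classScores
  b <- forwardNetwork(net, xs)$classScores
  margin <- 16
  idx <- (margin + 1):(300 - shift - margin)    # valid in both frames
  expect_equal(b[idx, ], a[idx + shift, ], tolerance = 1e-5)

  z <- forwardNetwork(net, rep(0, 200))$classScores
  mid <- z[50:150, ]
  expect_lt(max(abs(sweep(mid, 2, mid[1, ]))), 1e-6)
})

test_that("the loss is zero at the optimum and honours masks and weights", {
  ex <- tinyCorpus()@train[[1]]
  n <- length(ex$intensities)
  perfect <- list(
    classScores = local({
      m <- matrix(0, n, 3); m[cbind(seq_len(n), ex$classLabels + 1)] <- 1; m
    }),
    regressor = local({
      r <- matrix(0, n, 8)
      i2 <- which(ex$classLabels == 2); i1 <- which(ex$classLabels == 1)
      r[i2, 1:4] <- ex$targets[i2, ]; r[i1, 5:8] <- ex$targets[i1, ]; r
    }))
  expect_equal(as.numeric(networkLoss(perfect, ex)), 0, tolerance = 1e-9)

  # uniform scores: cross-entropy is ln(3) times the mean class weight
  uni <- perfect
  uni$classScores <- matrix(1 / 3, n, 3)
  lw <- lossWeights()
  expected <- log(3) * mean(lw$classWeights[ex$classLabels + 1])
  expect_equal(as.numeric(networkLoss(uni, ex, lw)), expected,
               tolerance = 1e-9)

  # regressor errors at unmasked points do not contribute
  noisyOutside <- perfect
  noisyOutside$regressor[!ex$mask, ] <- 5
  expect_equal(as.numeric(networkLoss(noisyOutside, ex)), 0,
               tolerance = 1e-9)
})

test_that("compiled trainer loss matches the reference implementation", {
  corpus <- tinyCorpus()
  one <- new("TrainingCorpus", train = corpus@train[1], val = list(),
             config = corpus@config)
  net <- buildNetwork(seed = 5)
  tr <- trainNetwork(net, one, trainConfig(epochs = 1, retain = "final"))
  ref <- networkLoss(forwardNetwork(net, one@train[[1]]$intensities),
                     one@train[[1]])
  expect_equal(trainingHistory(tr)$trainLoss[1], as.numeric(ref),
               tolerance = 1e-4)
})

test_that("training descends and is reproducible", {
  corpus <- tinyCorpus()
  net <- buildNetwork(seed = 1)
  t1 <- trainNetwork(net, corpus, trainConfig(epochs = 50))
  h1 <- trainingHistory(t1)
  expect_lt(h1$trainLoss[50], h1$trainLoss[1])
  # loss is non-increasing in the vast majority of epochs
  expect_gte(mean(diff(h1$trainLoss) <= 1e-8), 0.9)
  t2 <- trainNetwork(net, corpus, trainConfig(epochs = 50))
  expect_identical(h1$trainLoss, trainingHistory(t2)$trainLoss)
  expect_identical(t1@weights, t2@weights)
})

test_that("weight checkpoints round-trip and validate their manifest", {
  net <- trainNetwork(buildNetwork(seed = 6), tinyCorpus(),
                      trainConfig(epochs = 5))
  probe <- runif(120)
  before <- forwardNetwork(net, probe)
  path <- tempfile(fileext = ".rds")
  saveWeights(net, path)
  back <- loadWeights(path)
  expect_identical(forwardNetwork(back, probe), before)
  expect_identical(countParameters(back), 8037L)
  expect_true(back@trained)

  # tampering with the stored depths must be caught
  obj <- readRDS(path)
  obj$arch$depths[1] <- 64L
  saveRDS(obj, path)
  expect_error(loadWeights(path), "manifest")
  # requesting a different architecture must be caught
  path2 <- tempfile(fileext = ".rds")
  saveWeights(net, path2)
  expect_error(loadWeights(path2, arch = archConfig(
    depths = c(80, 20, 10, 20, 10, 30, 18, 18))), "architecture")
})
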