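test_that("score smoothing averages over 3 points and renormalizes", {
  const <- matrix(rep(c(0.2, 0.3, 0.5), each = 10), 10, 3)
  expect_equal(smoothScores(const), const, tolerance = 1e-12)

  imp <- matrix(c(1, 0, 0), 9, 3, byrow = TRUE)
  imp[5, ] <- c(0, 0, 1)
  sm <- smoothScores(imp)
  expect_true(all(abs(rowSums(sm) - 1) < 1e-12))
  # the impulse spreads to exactly the 3 neighbouring points
  expect_true(all(sm[4:6, 3] > 0))
  expect_equal(sm[c(2, 8), 3], c(0, 0))
})

test_that("classification takes the argmax with peak-favouring ties", {
  s <- rbind(c(0.1, 0.2, 0.7), c(1, 0, 0), c(0.2, 0.4, 0.4))
  cl <- classifyPoints(s)
  expect_identical(cl$classes, c(2L, 0L, 2L))
  expect_equal(cl$confidence, c(0.9, 0, 0.8))
})

test_that("non-maximum suppression keeps one point per contiguous run", {
  classes <- c(0, 2, 2, 2, 0, 1, 1, 0, 0, 2)
  conf <- c(0, 0.6, 1.0, 0.6, 0, 0.8, 0.7, 0, 0, 0.9)
  sel <- nmsSelect(classes, conf)
  expect_identical(sel, c(2L, 5L, 9L))   # 0-based: middles and singleton
  expect_identical(nmsSelect(rep(0, 10), runif(10)), integer())
  # leftmost wins on ties
  expect_identical(nmsSelect(c(1, 1), c(0.5, 0.5)), 0L)
})

test_that("non-maximum suppression is idempotent", {
  set.seed(12)
  for (i in 1:25) {
    classes <- sample(0:2, 60, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    conf <- runif(60)
    sel <- nmsSelect(classes, conf)
    ind <- integer(60)
    ind[sel + 1] <- classes[sel + 1]
    expect_identical(nmsSelect(ind, conf), sel)
    # no two selected indices share a contiguous run
    if (length(sel) > 1)
      expect_true(all(vapply(seq_len(length(sel) - 1), function(j) {
        any(classes[(sel[j] + 1):(sel[j + 1] + 1)] == 0)
      }, TRUE)))
  }
})

test_that("regressor decoding reads the class-matched block and clamps", {
  reg <- matrix(0, 120, 8)
  reg[101, ] <- c(0.25, 0.8, 9.0, 0.5, -1, -1, -1, -1)
  classes <- integer(120); classes[101] <- 2L
  pk <- decodePeak(100, classes, reg)
  expect_equal(pk$position, 100.25)
  expect_equal(pk$amplitude, 0.8)
  expect_equal(pk$fwhh, 9.0)
  expect_equal(pk$eta, 0.5)

  reg[101, ] <- c(0, 0, 0, 0, -0.5, 0.6, 0.2, -0.1)
  classes[101] <- 1L
  pk1 <- decodePeak(100, classes, reg)
  expect_equal(pk1$position, 99.5)     # class-1 block used
  expect_equal(pk1$eta, 0)             # clamped from -0.1
  expect_equal(pk1$fwhh, 0.5)          # floored from 0.2
})

test_that("noise estimation is robust to sparse large peaks", {
  set.seed(44)
  pure <- rnorm(10000)
  est <- estimateNoise(pure)
  expect_equal(est$sigma, 1, tolerance = 0.05)
  expect_equal(est$cutoff, 5 * est$sigma)

  spiked <- pure
  spiked[1:80] <- 500    # <1% of points carry a huge peak
  expect_equal(estimateNoise(spiked)$sigma, 1, tolerance = 0.1)

  zero <- estimateNoise(numeric(128))
  expect_identical(zero$sigma, 0)
  expect_identical(zero$cutoff, 0)
})

test_that("the trained picker recovers isolated and resolved peaks", {
  net <- trainedNet()
  one <- synthSpectrum1D(voigtPeaks(150.4, 1, 10, 0.5), 300,
                         noiseSigma = 0.01, seed = 3)
  got <- pickPeaks1D(one, net)
  expect_identical(nPeaks(got), 1L)
  expect_lt(abs(peakTable(got)$position - 150.4), 1)

  two <- synthSpectrum1D(voigtPeaks(c(100, 130), c(1, 0.8), c(10, 10),
                                    c(0.3, 0.7)), 300,
                         noiseSigma = 0.01, seed = 4)
  got2 <- pickPeaks1D(two, net)
  expect_identical(nPeaks(got2), 2L)
  expect_lt(max(abs(sort(peakTable(got2)$position) - c(100, 130))), 1)

  noise <- synthSpectrum1D(voigtPeaks(numeric(0)), 300, noiseSigma = 1,
                           seed = 5)
  expect_identical(nPeaks(pickPeaks1D(noise, net)), 0L)
})

test_that("raising the noise cutoff never adds peaks", {
  net <- trainedNet()
  sp <- synthSpectrum1D(voigtPeaks(c(80, 150, 220), c(1, 0.25, 0.08),
                                   c(10, 8, 8), 0.5), 300,
                        noiseSigma = 0.02, seed = 6)
  counts <- vapply(c(0, 2, 5, 10, 30), function(k)
    nPeaks(pickPeaks1D(sp, net, pickConfig(kNoise = k))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("decoded peaks are refinement-ready reconstruction seeds", {
  # the raw regressor decode is a starting point, not a quantitative
  # fit: its reconstruction must be in the refinement basin (here
  # bounded at 25% of the maximum at the scaled-down training used in
  # these tests), and the simultaneous cluster refinement it seeds must
  # reproduce a noise-free model-class spectrum almost exactly
  net <- trainedNet()
  for (i in 1:5) {
    fx <- simulateRecovery1D(500 + i, snr = Inf)
    sp <- synthSpectrum1D(fx$peaks, 300)
    picked <- pickPeaks1D(sp, net)
    got <- peakTable(picked)
    expect_gt(nrow(got), 0)
    reconOf <- function(pk) Reduce(`+`, lapply(seq_len(nrow(pk)), function(j)
      pseudoVoigt(0:299, pk$position[j], pk$amplitude[j], pk$fwhh[j],
                  pk$eta[j])))
    expect_lt(max(abs(reconOf(got) - intensities(sp))),
              0.25 * max(intensities(sp)))
    if (nrow(got) == nrow(fx$peaks)) {
      # refined reconstruction meets the generator's own 3% criterion
      refined <- peakTable(refinePeaks(picked, sp))
      expect_lt(max(abs(reconOf(refined) - intensities(sp))),
                0.03 * max(intensities(sp)))
    }
  }
})
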