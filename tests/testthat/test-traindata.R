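cfgP <- generatorConfig(seed = 1)

test_that("sampled peak pairs respect the configured ranges", {
  set.seed(31)
  pairs <- replicate(2000, samplePeakPair(cfgP), simplify = FALSE)
  f <- unlist(lapply(pairs, `[[`, "fwhh"))
  e <- unlist(lapply(pairs, `[[`, "eta"))
  a2 <- vapply(pairs, function(p) p$amplitude[2], 0)
  sep <- vapply(pairs, function(p) abs(diff(p$center)) / mean(p$fwhh), 0)
  expect_true(all(f >= 6 & f <= 20))
  expect_true(all(e >= 0 & e <= 1))
  expect_true(all(a2 >= 0.05 & a2 <= 1))
  expect_true(all(sep >= 0.2 & sep <= 3))

  set.seed(77); p1 <- samplePeakPair(cfgP)
  set.seed(77); p2 <- samplePeakPair(cfgP)
  expect_identical(p1, p2)
})

test_that("fitKPeaks recovers exact model-class profiles", {
  prof <- evalPeak(voigtPeaks(60, 1.3, 9, 0.4), 120)
  fit <- fitKPeaks(prof, 1, seed = 5)
  expect_true(fit$converged)
  expect_lt(fit$maxAbsErrorFraction, 1e-6)
  expect_equal(fit$peaks$center, 60, tolerance = 1e-4)
  expect_equal(fit$peaks$eta, 0.4, tolerance = 1e-3)
  expect_true(fit$robust)

  two <- synthSpectrum1D(voigtPeaks(c(50, 80), c(1, 0.8), c(10, 10),
                                    c(0.5, 0.5)), 130)
  fit2 <- fitKPeaks(intensities(two), 2, seed = 5)
  expect_lt(fit2$maxAbsErrorFraction, 1e-5)
})

test_that("single-peak fit errors cross the labeling thresholds as expected", {
  mkPair <- function(sep) voigtPeaks(c(0, sep * 10), c(1, 0.8), c(10, 10),
                                     c(0.5, 0.5))
  # strongly overlapped: representable by one peak
  close <- labelPair(mkPair(0.3), cfgP, seed = 2)
  expect_identical(close$decision, "ONE_PEAK")
  expect_lt(close$error, 0.02)
  expect_equal(nrow(close$truth), 1)
  # well separated: far beyond the 3% exclusion threshold
  far <- labelPair(mkPair(2), cfgP, seed = 2)
  expect_identical(far$decision, "TWO_PEAKS")
  expect_gt(far$error, 0.03)
  expect_equal(nrow(far$truth), 2)
  # coincident equal-width peaks are exactly one peak of doubled height
  co <- labelPair(voigtPeaks(c(40, 40), c(1, 1), c(10, 10), c(0.3, 0.3)),
                  cfgP, seed = 2)
  expect_identical(co$decision, "ONE_PEAK")
  expect_equal(co$truth$amplitude, 2, tolerance = 1e-3)
})

test_that("the discard band between 2% and 3% exists and is labeled DISCARD", {
  mkPair <- function(sep) voigtPeaks(c(0, sep * 10), c(1, 0.8), c(10, 10),
                                     c(0.5, 0.5))
  err <- function(sep) labelPair(mkPair(sep), cfgP, seed = 2)$error
  lo <- 0.2; hi <- 1.2
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (err(mid) < 0.025) lo <- mid else hi <- mid
  }
  lab <- labelPair(mkPair((lo + hi) / 2), cfgP, seed = 2)
  expect_identical(lab$decision, "DISCARD")
  expect_gt(lab$error, 0.02)
  expect_lt(lab$error, 0.03)
})

test_that("width-ratio rule blocks merging of dissimilar peaks", {
  # nearly coincident but very different widths: fits well yet must not
  # be relabeled as a single peak
  pair <- voigtPeaks(c(50, 50.5), c(1, 0.1), c(10, 18), c(0.5, 0.5))
  lab <- labelPair(pair, cfgP, seed = 3)
  if (lab$error < cfgP$mergeThreshold)
    expect_identical(lab$decision, "DISCARD")
  else succeed("pair not in the mergeable error regime")
})

test_that("class assignment follows the domination rule", {
  # isolated peak
  expect_identical(assignClasses(voigtPeaks(50, 1, 10, 0.5)), 2L)
  # shoulder 0.6 FWHH from a 5x larger equal-width peak is dominated
  sh <- voigtPeaks(c(50, 56), c(5, 1), c(10, 10), c(0.5, 0.5))
  expect_identical(assignClasses(sh), c(2L, 1L))
  # equal overlapping peaks: neither strictly dominates
  eq <- voigtPeaks(c(50, 56), c(1, 1), c(10, 10), c(0.5, 0.5))
  expect_identical(assignClasses(eq), c(2L, 2L))
  # domination requires both larger amplitude and larger volume
  mixed <- voigtPeaks(c(50, 55), c(1, 0.9), c(8, 18), c(0.5, 0.5))
  vol <- VoigtPicker:::.peakVolume(mixed)
  expect_gt(vol[2], vol[1])   # wider peak has larger volume
  expect_identical(assignClasses(mixed), c(2L, 2L))
})

test_that("composed segments never gain peaks and reduce only robustly", {
  set.seed(9)
  db <- buildPairDatabase(generatorConfig(pairDbSize = 40, seed = 1))
  set.seed(10)
  for (i in 1:30) {
    seg <- composeMultipeak(cfgP, db)
    if (is.null(seg)) next
    expect_lte(nrow(seg$truth), 5)
    expect_gte(nrow(seg$truth), 2)
    if (seg$relabeled) {
      # reduced truth must explain the original profile
      win <- VoigtPicker:::.pairWindow(seg$truth, pad = 3)
      expect_true(all(seg$truth$fwhh > 0))
    }
  }
  # three peaks two FWHH apart cannot be explained by two
  wide <- voigtPeaks(c(30, 50, 70), c(1, 1, 1), c(10, 10, 10), 0.5)
  prof <- intensities(synthSpectrum1D(wide, 100))
  red <- fitKPeaks(prof, 2, seed = 4)
  expect_gt(red$maxAbsErrorFraction, cfgP$exclusionThreshold)
})

test_that("assembled examples carry 3-point labels with bounded offsets", {
  set.seed(21)
  units <- list(voigtPeaks(0, 1, 10, 0.5),
                voigtPeaks(c(0, 7), c(1, 0.3), c(9, 9), c(0.2, 0.8)))
  ex <- assembleExample(units, cfgP)
  expect_length(ex$intensities, 300)
  expect_equal(max(ex$intensities), 1)
  expect_equal(sum(ex$classLabels > 0), 3 * nrow(ex$truth))
  expect_identical(which(ex$mask), which(ex$classLabels > 0))
  offs <- ex$targets[ex$mask, "offset"]
  expect_true(all(abs(offs) <= 1.5))
  # labels are contiguous triplets around each rounded center
  for (i in seq_len(nrow(ex$truth))) {
    r <- round(ex$truth$center[i])
    expect_true(all(ex$classLabels[(r:(r + 2)) - 1 + 1] > 0))
  }
})

test_that("small corpora meet the structural contracts deterministically", {
  corpus <- tinyCorpus()
  cfg <- corpus@config
  expect_length(corpus@train, 20)
  expect_length(corpus@val, 5)
  for (ex in c(corpus@train, corpus@val)) {
    expect_length(ex$intensities, 300)
    expect_true(nrow(ex$truth) >= 3 && nrow(ex$truth) <= 9)
    expect_true(all(ex$truth$center >= 5 & ex$truth$center <= 294))
    expect_true(all(ex$classLabels[!ex$mask] == 0))
  }
  counts <- topologyCounts(corpus)
  expect_lte(max(counts), 2 * min(counts))

  again <- buildCorpus(generatorConfig(nTrain = 20, nVal = 5,
                                       pairDbSize = 40,
                                       composedPoolSize = 15, seed = 2))
  expect_identical(serialize(corpus, NULL, version = 2),
                   serialize(again, NULL, version = 2))
})

test_that("corpus archives round-trip byte-exactly with their config", {
  corpus <- tinyCorpus()
  path <- tempfile(fileext = ".rds")
  writeCorpus(corpus, path)
  back <- readCorpus(path)
  expect_identical(back@config, corpus@config)
  expect_identical(back@train, corpus@train)
  suppressWarnings(expect_error(readCorpus(tempfile()),
                                "cannot open|No such file"))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(readCorpus(bad), "not a VoigtPicker corpus")
})
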