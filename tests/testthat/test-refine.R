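test_that("overlap clustering forms connected components", {
  pk <- data.frame(position = c(20, 120, 128, 136, 260),
                   amplitude = 1, fwhh = 8, eta = 0.5)
  cl <- clusterPeaks(pk)
  expect_length(cl, 3)
  expect_identical(cl[[2]], 2:4)       # chained A-B, B-C overlap
  expect_identical(clusterPeaks(pk[0, ]), list())

  # 10 FWHH apart: singletons
  far <- data.frame(position = c(50, 130), amplitude = 1, fwhh = 8,
                    eta = 0.5)
  expect_length(clusterPeaks(far), 2)
})

test_that("cluster fits recover truth from perturbed seeds", {
  truth <- voigtPeaks(c(140, 148), c(1, 0.7), c(9, 8), c(0.4, 0.6))
  sp <- synthSpectrum1D(truth, 300)
  seed <- data.frame(position = truth$center + c(0.5, -0.5),
                     amplitude = truth$amplitude * c(1.1, 0.9),
                     fwhh = truth$fwhh, eta = truth$eta)
  res <- fitCluster(seed, sp)
  expect_true(res$converged)
  expect_lt(max(abs(res$peaks$position - truth$center)), 0.05)
  expect_lt(max(abs(res$peaks$amplitude - truth$amplitude) /
                  truth$amplitude), 0.01)

  # singleton noise-free peak: residual at solver tolerance
  single <- voigtPeaks(100, 1, 10, 0.3)
  sp1 <- synthSpectrum1D(single, 200)
  seed1 <- data.frame(position = 100.4, amplitude = 0.9, fwhh = 11,
                      eta = 0.5)
  res1 <- fitCluster(seed1, sp1)
  expect_lt(res1$residualFraction, 1e-6)

  # seeding with the truth is a stationary point
  seedT <- data.frame(position = 100, amplitude = 1, fwhh = 10, eta = 0.3)
  resT <- fitCluster(seedT, sp1)
  expect_equal(resT$peaks$position, 100, tolerance = 1e-6)
  expect_equal(resT$peaks$amplitude, 1, tolerance = 1e-6)
})

test_that("2D separable cluster fits recover truth", {
  truth <- crossPeaks(c(40, 47), c(40, 46), c(1, 0.6), c(8, 9), c(8, 7),
                      c(0.3, 0.7), c(0.5, 0.5))
  sp <- synthSpectrum2D(truth, c(90, 90))
  seed <- data.frame(posRow = truth$rowCenter + c(0.5, -0.4),
                     posCol = truth$colCenter + c(-0.5, 0.4),
                     fwhhRow = truth$rowFwhh, fwhhCol = truth$colFwhh,
                     etaRow = truth$rowEta, etaCol = truth$colEta,
                     amplitude = truth$amplitude * c(0.9, 1.1))
  res <- fitCluster(seed, sp)
  expect_true(res$converged)
  expect_lt(max(abs(res$peaks$posRow - truth$rowCenter)), 0.05)
  expect_lt(max(abs(res$peaks$posCol - truth$colCenter)), 0.05)
  expect_lt(max(abs(res$peaks$amplitude - truth$amplitude) /
                  truth$amplitude), 0.01)
})

test_that("refinement preserves peak count and never raises the residual", {
  truth <- voigtPeaks(c(80, 150, 157, 240), c(1, 0.9, 0.5, 0.3),
                      c(10, 9, 9, 8), 0.5)
  sp <- synthSpectrum1D(truth, 300)
  seeds <- new("PeakSet", kind = "1d", peaks = data.frame(
    position = truth$center + c(0.3, -0.3, 0.4, 0.2),
    amplitude = truth$amplitude * c(1.05, 0.95, 1.1, 0.9),
    fwhh = truth$fwhh * c(1.1, 1, 0.9, 1), eta = truth$eta,
    class = 2L, confidence = 1, origin = "picked"))
  ref <- refinePeaks(seeds, sp)
  expect_identical(nPeaks(ref), nPeaks(seeds))
  expect_true(all(peakTable(ref)$origin == "refined"))
  expect_lt(max(abs(peakTable(ref)$position - truth$center)), 0.05)

  # per-cluster seeded SSQ never increases
  y <- intensities(sp)
  ssqOf <- function(pk) {
    model <- Reduce(`+`, lapply(seq_len(nrow(pk)), function(j)
      pseudoVoigt(0:299, pk$position[j], pk$amplitude[j], pk$fwhh[j],
                  pk$eta[j])))
    sum((model - y)^2)
  }
  expect_lte(ssqOf(peakTable(ref)), ssqOf(peakTable(seeds)))

  # amplitude-only mode keeps shapes fixed
  refA <- refinePeaks(seeds, sp, amplitudeOnly = TRUE)
  expect_identical(peakTable(refA)$position, peakTable(seeds)$position)
  expect_identical(peakTable(refA)$fwhh, peakTable(seeds)$fwhh)
  expect_false(identical(peakTable(refA)$amplitude,
                         peakTable(seeds)$amplitude))
})
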