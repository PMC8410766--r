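# hand-built section picks / lines for the geometric operations
mkPick <- function(position, class = 2L, confidence = 1, amplitude = 1,
                   fwhh = 8, eta = 0.5) {
  if (!length(position)) return(VoigtPicker:::.emptyPeaks1D())
  data.frame(position = position, amplitude = amplitude, fwhh = fwhh,
             eta = eta, class = class, confidence = confidence)
}

mkLine <- function(sections, positions, class = 2L, confidence = 1,
                   orientation = "column_line") {
  l <- data.frame(section = sections, position = positions,
                  class = class, confidence = confidence,
                  amplitude = 1, fwhh = 8, eta = 0.5)
  attr(l, "orientation") <- orientation
  l
}

test_that("line building chains adjacent picks and drops short lines", {
  picks <- rep(list(mkPick(numeric(0))[0, ]), 12)
  for (s in 3:9) picks[[s]] <- mkPick(40 + 0.1 * s)
  picks[[6]] <- rbind(picks[[6]], mkPick(70))   # isolated single pick
  lines <- buildLines(picks, "column_line", linkTol = 2, minLineLength = 3)
  expect_length(lines, 1)
  expect_identical(lines[[1]]$section, 2:8)
  expect_true(all(diff(lines[[1]]$section) == 1))

  # two far-apart chains give two lines
  for (s in 3:9) picks[[s]] <- rbind(mkPick(40 + 0.1 * s), mkPick(70))
  lines2 <- buildLines(picks, "column_line")
  expect_length(lines2, 2)

  # a gap larger than the tolerance breaks the chain
  picks3 <- rep(list(mkPick(numeric(0))[0, ]), 12)
  for (s in 1:4) picks3[[s]] <- mkPick(40)
  for (s in 5:8) picks3[[s]] <- mkPick(49)
  lines3 <- buildLines(picks3, "column_line", linkTol = 2)
  expect_length(lines3, 2)
})

test_that("line intersection finds matched node pairs within tolerance", {
  # two vertical column lines at columns 36..52 holding rows 40 and 48,
  # two horizontal row lines likewise: classic crossed geometry in which
  # every line passes both crossing columns/rows, giving 4 intersections
  colL <- list(mkLine(36:52, rep(40, 17)), mkLine(36:52, rep(48, 17)))
  rowL <- list(mkLine(36:52, rep(40, 17)), mkLine(36:52, rep(48, 17)))
  cand <- intersectLines(colL, rowL, matchTol = 1.5)
  expect_identical(nrow(cand), 4L)
  got <- sort(paste(round(cand$posRow), round(cand$posCol)))
  expect_identical(got, sort(c("40 40", "40 48", "48 40", "48 48")))

  none <- intersectLines(list(mkLine(0:5, rep(10, 6))),
                         list(mkLine(30:35, rep(30, 6))))
  expect_identical(nrow(none), 0L)
})

test_that("only Class-1-in-both intersections are removed", {
  cand <- data.frame(posRow = c(40, 40, 48, 48), posCol = c(40, 48, 40, 48),
                     classRow = c(2L, 1L, 1L, 2L),
                     classCol = c(2L, 1L, 1L, 1L))
  flt <- removeFalseIntersections(cand)
  expect_identical(nrow(flt$removed), 2L)
  expect_identical(flt$kept$posCol, c(40, 48))   # 2/2 kept, 2/1 kept
})

test_that("tilt angles follow the arctangent closed forms", {
  expect_equal(maxTiltAngle(mkLine(0:8, rep(40, 9)))$angle, 0)
  expect_equal(maxTiltAngle(mkLine(0:8, 40 + 0:8))$angle, 45)
  expect_equal(maxTiltAngle(mkLine(0:8, 40 + 0.25 * 0:8))$angle,
               atan(0.25) * 180 / pi, tolerance = 1e-9)
  # the most tilted 3-node segment of a mixed line is found
  mixed <- mkLine(0:6, c(40, 40, 40, 41, 42, 42, 42))
  tl <- maxTiltAngle(mixed, window = 3)
  expect_equal(tl$angle, 45)
})

test_that("tilted intersections split into midpoint peaks only when both tilt", {
  cand <- data.frame(posRow = 44, posCol = 44, fwhhRow = 8, fwhhCol = 8,
                     etaRow = 0.5, etaCol = 0.5, amplitude = 1,
                     confidence = 0.9, classRow = 2L, classCol = 2L)
  straightC <- mkLine(40:48, rep(44, 9))
  straightR <- mkLine(40:48, rep(44, 9), orientation = "row_line")
  # both straight: unchanged
  out <- splitTilted(cand, straightC, straightR)
  expect_identical(nrow(out), 1L)
  expect_identical(out$origin, "picked")
  # only one tilted: unchanged (the rule is AND)
  tiltedC <- mkLine(40:48, 40:48)
  out1 <- splitTilted(cand, tiltedC, straightR)
  expect_identical(nrow(out1), 1L)
  # both tilted beyond 14 degrees: two peaks at segment midpoints
  tiltedR <- mkLine(40:48, 40:48, orientation = "row_line")
  out2 <- splitTilted(cand, tiltedC, tiltedR)
  expect_identical(nrow(out2), 2L)
  expect_identical(out2$origin, c("split", "split"))
  expect_equal(sort(out2$posRow), sort(out2$posCol))
})

test_that("cross-peak assembly mixes the two 1D predictions correctly", {
  colNode <- mkPick(40.2, class = 2L, confidence = 0.95, amplitude = 0.8,
                    fwhh = 9, eta = 0.3)
  rowNode <- mkPick(48.1, class = 1L, confidence = 0.7, amplitude = 0.6,
                    fwhh = 7, eta = 0.8)
  cp <- assembleCrossPeak(colNode, rowNode)
  expect_equal(cp$amplitude, 0.7)
  expect_equal(cp$confidence, 0.7)
  expect_equal(cp$posRow, 40.2)
  expect_equal(cp$posCol, 48.1)
  expect_equal(cp$fwhhRow, 9)
  expect_equal(cp$fwhhCol, 7)
})

test_that("section picking honours separability and transposition", {
  net <- trainedNet()
  sp <- synthSpectrum2D(crossPeaks(45, 60, 1, 8, 8), c(100, 120),
                        noiseSigma = 0.01, seed = 9)
  sec <- pickSections(sp, net)
  # the peak's column sees a 1D peak near the row center and vice versa
  expect_true(any(abs(sec$colPicks[[61]]$position - 45) < 2))
  expect_true(any(abs(sec$rowPicks[[46]]$position - 60) < 2))

  secT <- pickSections(t(intensities(sp)), net)
  expect_equal(secT$colPicks[[46]]$position, sec$rowPicks[[46]]$position,
               tolerance = 1e-10)

  pure <- synthSpectrum2D(crossPeaks(numeric(0), numeric(0)), c(100, 100),
                          noiseSigma = 1, seed = 10)
  secN <- pickSections(pure, net)
  expect_true(all(vapply(secN$colPicks, nrow, 0L) == 0))
})

test_that("the 2D pipeline resolves the crossed two-peak geometry", {
  net <- trainedNet()
  sp <- synthSpectrum2D(crossPeaks(c(40, 48), c(40, 48), 1, 8, 8),
                        c(90, 90))
  got <- pickPeaks2D(sp, net)
  pk <- peakTable(got)
  expect_identical(nrow(pk), 2L)
  err <- vapply(seq_len(2), function(i)
    min(abs(pk$posRow - c(40, 48)[i]) + abs(pk$posCol - c(40, 48)[i])), 0)
  expect_lt(max(err), 2)
  # the two crossed intersections were generated, then removed
  rm <- got@metadata$removed
  expect_identical(nrow(rm), 2L)
})

test_that("2D picking is transpose symmetric", {
  net <- trainedNet()
  fx <- simulateRecovery2D(700)
  m <- intensities(fx$spectrum)
  a <- peakTable(pickPeaks2D(m, net))
  b <- peakTable(pickPeaks2D(t(m), net))
  expect_identical(nrow(a), nrow(b))
  ka <- a[order(a$posRow, a$posCol), c("posRow", "posCol")]
  kb <- b[order(b$posCol, b$posRow), c("posCol", "posRow")]
  expect_equal(unname(as.matrix(ka)), unname(as.matrix(kb)),
               tolerance = 1e-10)
})

test_that("masked columns are excluded from picking", {
  net <- trainedNet()
  sp <- synthSpectrum2D(crossPeaks(c(40, 70), c(30, 80), 1, 8, 8),
                        c(100, 110), noiseSigma = 0.01, seed = 12)
  all2 <- peakTable(pickPeaks2D(sp, net))
  expect_identical(nrow(all2), 2L)
  masked <- peakTable(pickPeaks2D(sp, net,
                                  pickConfig(maskCols = 10:50)))
  expect_identical(nrow(masked), 1L)
  expect_lt(abs(masked$posCol - 80), 2)
})
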