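#' Picking configuration
#'
#' @param kNoise Amplitude cutoff multiplier: peaks below
#'   \code{kNoise * sigma} (original intensity units) are dropped.
#' @param fwhhFloor Minimum decoded FWHH in points.
#' @param linkTol Maximum position difference (points) for chaining 1D
#'   picks across adjacent rows/columns of a 2D spectrum.
#' @param minLineLength Minimum number of chained sections for a peak
#'   line.
#' @param matchTol Maximum row/column mismatch (points) for a line
#'   intersection to define a cross-peak candidate.
#' @param angleCutoff Tilt angle (degrees) above which (in both
#'   orientations) an intersection peak is split in two.
#' @param tiltWindow Node window for the most-tilted-segment search.
#' @param mergeReducible Apply the training set's single-peak decision
#'   boundary to the picked peaks: an overlapping cluster of picks that a
#'   fit with one peak fewer explains within
#'   \code{reducibleThreshold} of the local maximum is iteratively
#'   reduced.  This removes the characteristic failure mode of splitting
#'   one wide peak into several narrow picks, using the same
#'   nonlinear-fit criterion that defined the ground-truth labels.
#' @param reducibleThreshold Maximum absolute residual (fraction of the
#'   local maximum) below which a reduced fit replaces a pick cluster;
#'   matches the generator's exclusion threshold.
#' @param minShoulderConfidence Confidence floor for Class-1 (shoulder)
#'   picks in 1D spectra.  A 2D cross-peak must be confirmed by both its
#'   row and its column, which suppresses spurious shoulder predictions;
#'   a 1D spectrum has no such orthogonal check, so low-confidence
#'   shoulder picks are dropped instead.  Not applied to the per-section
#'   picks of 2D spectra.
#' @param maskCols Optional integer vector of 0-based column indices to
#'   zero before 2D picking (water / t1-noise bands).
#' @return Validated list.
#' @export
pickConfig <- function(kNoise = 5, fwhhFloor = 0.5, linkTol = 2,
                       minLineLength = 3, matchTol = 1.5, angleCutoff = 14,
                       tiltWindow = 3, mergeReducible = TRUE,
                       reducibleThreshold = 0.03,
                       minShoulderConfidence = 0.8,
                       maskCols = NULL) {
  stopifnot(kNoise >= 0, fwhhFloor > 0, linkTol > 0, minLineLength >= 1,
            matchTol > 0, angleCutoff > 0, tiltWindow >= 2,
            reducibleThreshold > 0, reducibleThreshold < 1,
            minShoulderConfidence >= 0, minShoulderConfidence <= 1)
  list(kNoise = kNoise, fwhhFloor = fwhhFloor, linkTol = linkTol,
       minLineLength = as.integer(minLineLength), matchTol = matchTol,
       angleCutoff = angleCutoff, tiltWindow = as.integer(tiltWindow),
       mergeReducible = isTRUE(mergeReducible),
       reducibleThreshold = reducibleThreshold,
       minShoulderConfidence = minShoulderConfidence,
       maskCols = maskCols)
}

#' Smooth class scores with a 3-point moving average
#'
#' Per-channel 3-point moving average (edge points use the available
#' neighbours) followed by per-point renormalization to unit row sums.
#'
#' @param scores N x 3 matrix of class scores.
#' @return Smoothed N x 3 matrix with rows summing to 1.
#' @export
smoothScores <- function(scores) {
  n <- nrow(scores)
  stopifnot(n >= 3)
  sm <- scores
  sm[2:(n - 1), ] <- (scores[1:(n - 2), ] + scores[2:(n - 1), ] + scores[3:n, ]) / 3
  sm[1, ] <- (scores[1, ] + scores[2, ]) / 2
  sm[n, ] <- (scores[n - 1, ] + scores[n, ]) / 2
  sm / rowSums(sm)
}

#' Classify points and compute confidences
#'
#' Per-point argmax class (ties resolved toward the higher class, i.e. a
#' peak rather than a non-peak); confidence is the summed Class 1 +
#' Class 2 score.
#'
#' @param smoothed N x 3 matrix of normalized scores (columns = Class 0,
#'   1, 2).
#' @return List with integer \code{classes} and numeric
#'   \code{confidence}.
#' @export
classifyPoints <- function(smoothed) {
  cls <- apply(smoothed, 1, function(r) max(which(r == max(r))) - 1L)
  list(classes = as.integer(cls),
       confidence = smoothed[, 2] + smoothed[, 3])
}

#' Non-maximum suppression over contiguous peak-class runs
#'
#' Points with class 1 or 2 are partitioned into maximal contiguous runs;
#' in each run only the index of maximal confidence survives (leftmost on
#' ties).
#'
#' @param classes Integer vector over {0, 1, 2}.
#' @param confidence Numeric vector of the same length.
#' @return Integer vector of selected 0-based indices.
#' @export
nmsSelect <- function(classes, confidence) {
  stopifnot(length(classes) == length(confidence))
  isPeak <- classes > 0
  if (!any(isPeak)) return(integer())
  r <- rle(isPeak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- integer()
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    keep <- c(keep, idx[which.max(confidence[idx])])
  }
  keep - 1L
}

#' Decode the regressor output at a selected index
#'
#' Reads the 4-channel regressor block matching the point's class
#' (Class 2 block first) and converts it to a peak: position = index +
#' sub-pixel offset, amplitude, FWHH (floored), Lorentzian fraction
#' (clamped to [0, 1]).
#'
#' @param index 0-based selected index.
#' @param classes Integer class vector.
#' @param regressor N x 8 regressor matrix.
#' @param confidence Numeric confidence vector.
#' @param fwhhFloor Minimum reported FWHH.
#' @return One-row data.frame (position, amplitude, fwhh, eta, class,
#'   confidence).
#' @export
decodePeak <- function(index, classes, regressor, confidence = NULL,
                       fwhhFloor = 0.5) {
  cls <- classes[index + 1]
  stopifnot(cls %in% c(1L, 2L))
  block <- if (cls == 2L) 1:4 else 5:8
  v <- regressor[index + 1, block]
  data.frame(position = index + v[1],
             amplitude = v[2],
             fwhh = max(v[3], fwhhFloor),
             eta = min(max(v[4], 0), 1),
             class = as.integer(cls),
             confidence = if (is.null(confidence)) NA_real_
                          else confidence[index + 1])
}

#' Robust global noise level estimate
#'
#' Scaled median-absolute-deviation about the median, iterated twice
#' after excluding points more than 3 sigma from the median, so that a
#' sparse population of genuine peaks does not inflate the estimate.
#' The amplitude cutoff is \code{kNoise * sigma}.
#'
#' @param spectrum An \linkS4class{NMRSpectrum1D},
#'   \linkS4class{NMRSpectrum2D} or numeric vector/matrix.
#' @param kNoise Cutoff multiplier.
#' @return List with \code{sigma} and \code{cutoff}.
#' @export
estimateNoise <- function(spectrum, kNoise = 5) {
  x <- if (is(spectrum, "NMRSpectrum1D") || is(spectrum, "NMRSpectrum2D"))
    as.numeric(intensities(spectrum)) else as.numeric(spectrum)
  stopifnot(length(x) >= 64)
  med <- median(x)
  sigma <- 1.4826 * median(abs(x - med))
  for (it in 1:2) {
    if (sigma <= 0) break
    keep <- abs(x - med) <= 3 * sigma
    med <- median(x[keep])
    sigma <- 1.4826 * median(abs(x[keep] - med))
  }
  list(sigma = sigma, cutoff = kNoise * sigma)
}

# core picker on a plain numeric vector given network outputs; intensities
# are max-normalized before the forward pass (training convention) and
# decoded amplitudes are restored to original units
.pickVector <- function(x, net, config, cutoff, sigma = 0, forward = NULL) {
  scale <- max(x)
  if (scale <= 0) return(.emptyPeaks1D())
  if (is.null(forward)) forward <- forwardNetwork(net, x / scale)
  sm <- smoothScores(forward$classScores)
  cl <- classifyPoints(sm)
  sel <- nmsSelect(cl$classes, cl$confidence)
  if (!length(sel)) return(.emptyPeaks1D())
  rows <- lapply(sel, decodePeak, classes = cl$classes,
                 regressor = forward$regressor, confidence = cl$confidence,
                 fwhhFloor = config$fwhhFloor)
  pk <- do.call(rbind, rows)
  pk$amplitude <- pk$amplitude * scale
  # cutoff on both the decoded height and the observed intensity at the
  # picked point: a genuine peak (even a shoulder) rides on a data value
  # at least as large as its own height, so a sub-cutoff data value
  # unmasks hallucinated amplitudes over the baseline
  obs <- x[pmin(pmax(round(pk$position), 0), length(x) - 1) + 1]
  pk <- pk[pk$amplitude >= cutoff & obs >= cutoff & pk$position >= 0 &
             pk$position <= length(x) - 1, , drop = FALSE]
  pk <- pk[order(pk$position), , drop = FALSE]
  rownames(pk) <- NULL
  if (isTRUE(config$mergeReducible) && nrow(pk) > 1)
    pk <- .mergeReduciblePicks(pk, x, config$reducibleThreshold, sigma)
  pk
}

# apply the corpus decision boundary to one cluster of overlapping
# picks: while a bounded fit with one peak fewer explains the cluster's
# data region within `threshold` of the local maximum, merge the two
# most-overlapped picks and adopt the fitted parameters
.reduceCluster <- function(pk, x, threshold, sigma = 0) {
  n <- length(x)
  repeat {
    k <- nrow(pk)
    if (k < 2) return(pk)
    # screen: only clusters containing a strongly overlapped pair can be
    # reducible (the boundary sits near 0.4 of the mean FWHH, measured
    # against the true width, which the candidate widths underestimate)
    gaps <- abs(outer(pk$position, pk$position, "-")) /
      outer(pk$fwhh, pk$fwhh, "+")
    diag(gaps) <- Inf
    if (min(gaps) > 0.6) return(pk)
    pad <- 2 * max(pk$fwhh)
    lo <- max(0, floor(min(pk$position) - pad))
    hi <- min(n - 1, ceiling(max(pk$position) + pad))
    region <- x[(lo:hi) + 1]
    # seed: merge the two most-overlapped picks into one
    ij <- which(gaps == min(gaps), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    wsum <- pk$amplitude[i] + pk$amplitude[j]
    merged <- data.frame(
      position = (pk$position[i] * pk$amplitude[i] +
                    pk$position[j] * pk$amplitude[j]) / wsum,
      amplitude = max(pk$amplitude[i], pk$amplitude[j]),
      fwhh = max(pk$fwhh[i], pk$fwhh[j]) +
        abs(pk$position[i] - pk$position[j]) / 2,
      eta = (pk$eta[i] + pk$eta[j]) / 2,
      class = pk$class[[which.max(pk$amplitude[c(i, j)])[1]]],
      confidence = max(pk$confidence[i], pk$confidence[j]))
    cand <- rbind(pk[-c(i, j), names(merged), drop = FALSE], merged)
    par0 <- as.numeric(t(cand[, c("position", "amplitude", "fwhh", "eta")]))
    kk <- nrow(cand)
    lower <- as.numeric(t(cbind(cand$position - 3, 1e-12,
                                cand$fwhh * 0.3, 0)))
    upper <- as.numeric(t(cbind(cand$position + 3, Inf, cand$fwhh * 3, 1)))
    resid <- function(par) .pv_profile(par, lo:hi) - region
    jac <- function(par) .pv_jacobian(par, lo:hi)
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid, jac = jac,
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) return(pk)
    # noise allowance: even the correct model leaves ~sigma-scale
    # residuals, so the noise-free training criterion gets a 4-sigma
    # headroom on top of the fractional threshold
    if (max(abs(fit$fvec)) >= threshold * max(region) + 4 * sigma)
      return(pk)
    pm <- matrix(fit$par, ncol = 4, byrow = TRUE)
    cand$position <- pm[, 1]; cand$amplitude <- pm[, 2]
    cand$fwhh <- pm[, 3]; cand$eta <- pmin(pmax(pm[, 4], 0), 1)
    pk <- cand[order(cand$position), , drop = FALSE]
  }
}

.mergeReduciblePicks <- function(pk, x, threshold, sigma = 0) {
  if (nrow(pk) < 2) return(pk)
  clusters <- clusterPeaks(pk)
  out <- NULL
  for (cl in clusters)
    out <- rbind(out, .reduceCluster(pk[cl, , drop = FALSE], x, threshold,
                                     sigma))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyPeaks1D <- function() {
  data.frame(position = numeric(), amplitude = numeric(), fwhh = numeric(),
             eta = numeric(), class = integer(), confidence = numeric())
}

#' Pick peaks in a 1D spectrum
#'
#' Full 1D pipeline: forward pass on the max-normalized spectrum, 3-point
#' score smoothing, per-point classification, non-maximum suppression,
#' regressor decoding, and removal of peaks below the automatic noise
#' amplitude cutoff.
#'
#' @param spectrum An \linkS4class{NMRSpectrum1D} or numeric vector.
#' @param net A trained \linkS4class{PickerNet}.
#' @param config A \code{\link{pickConfig}}.
#' @return A \linkS4class{PeakSet} (kind "1d"), peaks sorted by position;
#'   amplitudes are in the spectrum's original intensity units.
#' @export
pickPeaks1D <- function(spectrum, net, config = pickConfig()) {
  x <- if (is(spectrum, "NMRSpectrum1D")) intensities(spectrum)
       else as.numeric(spectrum)
  noise <- estimateNoise(x, config$kNoise)
  pk <- .pickVector(x, net, config, noise$cutoff, noise$sigma)
  pk <- pk[pk$class == 2L |
             pk$confidence >= config$minShoulderConfidence, , drop = FALSE]
  rownames(pk) <- NULL
  pk$origin <- rep("picked", nrow(pk))
  new("PeakSet", peaks = pk, kind = "1d",
      metadata = list(noise = noise, config = config))
}
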