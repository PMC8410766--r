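#' Generator configuration
#'
#' Settings of the synthetic 1D training-set generator.  Peak widths are
#' drawn uniformly from \code{pppRange} (points per peak = FWHH in grid
#' points), the Lorentzian fraction uniformly from [0, 1], pair amplitude
#' ratios log-uniformly from [0.05, 1] and pair separations uniformly
#' from [0.2, 3] times the mean FWHH of the pair, so that all three
#' labeling outcomes (two peaks / merged single peak / discard) occur
#' with substantial frequency.
#'
#' @param pppRegime "protein" (FWHH 6-20 points) or "metabolomics"
#'   (FWHH 4-12 points); ignored if \code{pppRange} is given.
#' @param pppRange Numeric length-2, FWHH range in points.
#' @param nPointsPerExample Points per training spectrum.
#' @param peaksPerExample Integer length-2, min/max peaks per spectrum.
#' @param nTrain,nVal Corpus sizes.
#' @param exclusionThreshold Single-peak fit error (fraction of the
#'   profile maximum) below which a pair cannot be used as a two-peak
#'   example.
#' @param mergeThreshold Fit error below which (given a moderate width
#'   ratio) a strongly overlapped pair is intentionally relabeled as one
#'   peak.
#' @param widthRatioMax Maximum FWHH ratio for the merge relabeling.
#' @param fitRestarts Multi-start count for the nonlinear-fit oracle.
#' @param pairDbSize,composedPoolSize Sizes of the reusable pair database
#'   and composed-segment pool.
#' @param edgeMargin Minimum distance (points) of any truth peak from the
#'   spectrum edge.
#' @param reducibleAction "relabel" keeps a reducible multi-peak segment
#'   with the reduced truth when the reduced fit is robust; "remove"
#'   drops reducible segments entirely.
#' @param noiseSigma Additive noise in training spectra (0 = noise-free
#'   default; robustness comes from the merge labeling rule).
#' @param overlapFactor Two peaks are overlapping neighbours when their
#'   center distance is below \code{overlapFactor * (fwhh_a + fwhh_b)}.
#'   The default 0.75 makes the Class-1 label track the visual shoulder
#'   regime: a weak neighbour up to about 1.5 FWHH away generally lacks
#'   its own local maximum.
#' @param seed Integer master seed.
#' @return A validated config list.
#' @export
generatorConfig <- function(pppRegime = c("protein", "metabolomics"),
                            pppRange = NULL,
                            nPointsPerExample = 300,
                            peaksPerExample = c(3, 9),
                            nTrain = 5000, nVal = 500,
                            exclusionThreshold = 0.03,
                            mergeThreshold = 0.02,
                            widthRatioMax = 1.5,
                            fitRestarts = 8,
                            pairDbSize = 400,
                            composedPoolSize = 200,
                            edgeMargin = 6,
                            reducibleAction = c("relabel", "remove"),
                            noiseSigma = 0,
                            overlapFactor = 0.75,
                            seed = 1L) {
  pppRegime <- match.arg(pppRegime)
  if (is.null(pppRange))
    pppRange <- if (pppRegime == "protein") c(6, 20) else c(4, 12)
  stopifnot(pppRange[1] < pppRange[2],
            0 < mergeThreshold, mergeThreshold < exclusionThreshold,
            exclusionThreshold < 1, widthRatioMax > 1,
            peaksPerExample[1] >= 1, peaksPerExample[1] <= peaksPerExample[2],
            nPointsPerExample >= 64, edgeMargin >= 5)
  list(pppRegime = pppRegime, pppRange = pppRange,
       nPointsPerExample = as.integer(nPointsPerExample),
       peaksPerExample = as.integer(peaksPerExample),
       nTrain = as.integer(nTrain), nVal = as.integer(nVal),
       exclusionThreshold = exclusionThreshold,
       mergeThreshold = mergeThreshold,
       widthRatioMax = widthRatioMax,
       fitRestarts = as.integer(fitRestarts),
       pairDbSize = as.integer(pairDbSize),
       composedPoolSize = as.integer(composedPoolSize),
       edgeMargin = as.integer(edgeMargin),
       reducibleAction = match.arg(reducibleAction),
       noiseSigma = noiseSigma,
       overlapFactor = overlapFactor,
       seed = as.integer(seed))
}

#' Draw one random peak pair
#'
#' Uses the current RNG state (callers wrap it in their own seeded
#' stream).  The first peak sits at center 0 with amplitude 1; the second
#' at a random separation with a log-uniform amplitude ratio, randomly on
#' either side.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @return A two-row peak table.
#' @export
samplePeakPair <- function(config) {
  f <- runif(2, config$pppRange[1], config$pppRange[2])
  eta <- runif(2)
  ratio <- exp(runif(1, log(0.05), log(1)))
  sep <- runif(1, 0.2, 3) * mean(f)
  side <- sample(c(-1, 1), 1)
  voigtPeaks(center = c(0, side * sep), amplitude = c(1, ratio),
             fwhh = f, eta = eta)
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Multi-start bounded fit of k pseudo-Voigt peaks
#'
#' Best-of-\code{nStarts} bounded Levenberg-Marquardt least squares of
#' \code{k} pseudo-Voigt peaks against a profile.  The reported error
#' metric is the maximum pointwise absolute residual as a fraction of the
#' profile maximum.  The fit is "robust" when the two best restarts agree
#' on all centers within 0.5 points and all amplitudes within 5%.
#'
#' @param profile Numeric vector with positive maximum.
#' @param k Number of peaks (>= 1).
#' @param nStarts Number of random restarts.
#' @param seed Optional seed for the restart jitter.
#' @return List with \code{peaks} (fitted peak table),
#'   \code{maxAbsErrorFraction}, \code{converged}, \code{robust} and
#'   \code{ssq}.
#' @export
fitKPeaks <- function(profile, k, nStarts = 8, seed = NULL) {
  stopifnot(k >= 1, max(profile) > 0)
  n <- length(profile)
  pmax <- max(profile)
  x <- seq_len(n) - 1
  lower <- rep(c(0, 1e-6 * pmax, 0.8, 0), k)
  upper <- rep(c(n - 1, 3 * pmax, 2 * n, 1), k)

  model <- function(par) .pv_profile(par, x)
  resid <- function(par) model(par) - profile
  jac <- function(par) .pv_jacobian(par, x)

  # moment-ish base start: highest local maxima, spread fallback
  lm <- .localMaxima(profile)
  lm <- lm[order(profile[lm], decreasing = TRUE)]
  centers0 <- (lm - 1)[seq_len(min(k, length(lm)))]
  if (length(centers0) < k) {
    extra <- seq(0.2, 0.8, length.out = k - length(centers0)) * (n - 1)
    centers0 <- c(centers0, extra)
  }
  w0 <- tryCatch(measureFWHH(profile), error = function(e) n / 6) / max(1, sqrt(k))

  fits <- .withSeed(seed, {
    lapply(seq_len(nStarts), function(s) {
      par <- numeric(4 * k)
      for (j in seq_len(k)) {
        cj <- centers0[j]
        if (s > 1) cj <- cj + runif(1, -w0, w0)
        cj <- min(max(cj, 0), n - 1)
        aj <- max(profile[round(cj) + 1], 0.05 * pmax)
        if (s > 1) aj <- aj * runif(1, 0.5, 1.5)
        wj <- if (s > 1) w0 * runif(1, 0.5, 2) else w0
        ej <- if (s > 1) runif(1) else 0.5
        par[(4 * j - 4) + 1:4] <- c(cj, min(aj, upper[2]), min(max(wj, 1), 2 * n), ej)
      }
      out <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                             fn = resid, jac = jac,
                             control = minpack.lm::nls.lm.control(maxiter = 120))),
        error = function(e) NULL)
      if (is.null(out)) return(NULL)
      list(par = out$par, ssq = sum(out$fvec^2), info = out$info)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    return(list(peaks = NULL, maxAbsErrorFraction = Inf, converged = FALSE,
                robust = FALSE, ssq = Inf))
  ord <- order(vapply(fits, `[[`, 0, "ssq"))
  best <- fits[[ord[1]]]
  pk <- as.data.frame(matrix(best$par, ncol = 4, byrow = TRUE))
  names(pk) <- c("center", "amplitude", "fwhh", "eta")
  pk <- pk[order(pk$center), , drop = FALSE]
  rownames(pk) <- NULL
  robust <- FALSE
  if (length(ord) >= 2) {
    second <- fits[[ord[2]]]
    p2 <- matrix(second$par, ncol = 4, byrow = TRUE)
    p2 <- p2[order(p2[, 1]), , drop = FALSE]
    robust <- all(abs(p2[, 1] - pk$center) <= 0.5) &&
      all(abs(p2[, 2] - pk$amplitude) <= 0.05 * pmax)
  }
  list(peaks = pk,
       maxAbsErrorFraction = max(abs(model(best$par) - profile)) / pmax,
       converged = best$info %in% 1:4,
       robust = robust,
       ssq = best$ssq)
}

.pairWindow <- function(peaks, pad = 4) {
  lo <- floor(min(peaks$center) - pad * max(peaks$fwhh))
  hi <- ceiling(max(peaks$center) + pad * max(peaks$fwhh))
  list(offset = lo, n = hi - lo + 1)
}

#' Label a peak pair by the single-peak fit decision boundary
#'
#' Fits one pseudo-Voigt peak to the pair sum.  If the maximal absolute
#' residual is at least \code{exclusionThreshold} (3%) of the profile
#' maximum, the pair is a genuine two-peak example; if it is below
#' \code{mergeThreshold} (2%) and the two widths differ by at most
#' \code{widthRatioMax} (1.5), the pair is intentionally relabeled as the
#' fitted single peak; everything in between is discarded (it is neither
#' distinguishable nor safely mergeable).
#'
#' @param pair Two-row peak table.
#' @param config A \code{\link{generatorConfig}}.
#' @param seed Optional seed for the fit restarts.
#' @return List with \code{decision} ("TWO_PEAKS", "ONE_PEAK" or
#'   "DISCARD"), \code{truth} (labeled peak table, NULL on discard) and
#'   \code{error} (single-peak fit error fraction).
#' @export
labelPair <- function(pair, config = generatorConfig(), seed = NULL) {
  stopifnot(nrow(pair) == 2)
  win <- .pairWindow(pair)
  shifted <- pair
  shifted$center <- shifted$center - win$offset
  profile <- .sumPeaks(shifted, win$n)
  fit <- fitKPeaks(profile, 1, nStarts = config$fitRestarts, seed = seed)
  err <- fit$maxAbsErrorFraction
  wr <- max(pair$fwhh) / min(pair$fwhh)
  if (!fit$converged && !is.finite(err))
    return(list(decision = "DISCARD", truth = NULL, error = err))
  if (err >= config$exclusionThreshold) {
    truth <- pair[order(pair$center), , drop = FALSE]
    rownames(truth) <- NULL
    return(list(decision = "TWO_PEAKS", truth = truth, error = err))
  }
  if (err < config$mergeThreshold && wr <= config$widthRatioMax) {
    truth <- fit$peaks
    truth$center <- truth$center + win$offset
    return(list(decision = "ONE_PEAK", truth = truth, error = err))
  }
  list(decision = "DISCARD", truth = NULL, error = err)
}

# overlap topology of each truth peak: S (standalone), L/R (overlapping
# neighbour on that side), B (both sides)
.peakTopo <- function(peaks, overlapFactor = 0.75) {
  n <- nrow(peaks)
  if (n == 0) return(character())
  hasL <- hasR <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- peaks$center[j] - peaks$center[i]
    if (abs(d) < overlapFactor * (peaks$fwhh[i] + peaks$fwhh[j])) {
      if (d < 0) hasL[i] <- TRUE else hasR[i] <- TRUE
    }
  }
  ifelse(hasL & hasR, "B", ifelse(hasL, "L", ifelse(hasR, "R", "S")))
}

# analytic pseudo-Voigt volume (area): unit-height Lorentzian area is
# pi*f/2, unit-height Gaussian area is f/2*sqrt(pi/log(2))
.peakVolume <- function(peaks) {
  peaks$amplitude * peaks$fwhh *
    (peaks$eta * pi / 2 + (1 - peaks$eta) * sqrt(pi / log(2)) / 2)
}

#' Assign Class 1 / Class 2 to truth peaks
#'
#' Two peaks are overlapping neighbours when their center distance is
#' below \code{overlapFactor} times the sum of their FWHHs.  A peak is
#' Class 1 (a dominated, typically shoulder peak) when some overlapping
#' neighbour exceeds it in both amplitude and volume; otherwise Class 2.
#'
#' @param peaks Peak table sorted by center.
#' @param overlapFactor Overlap threshold factor (see
#'   \code{\link{generatorConfig}}).
#' @return Integer vector of classes (1 or 2).
#' @export
assignClasses <- function(peaks, overlapFactor = 0.75) {
  n <- nrow(peaks)
  if (n == 0) return(integer())
  vol <- .peakVolume(peaks)
  cls <- rep(2L, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- abs(peaks$center[j] - peaks$center[i])
    if (d < overlapFactor * (peaks$fwhh[i] + peaks$fwhh[j]) &&
        peaks$amplitude[j] > peaks$amplitude[i] && vol[j] > vol[i]) {
      cls[i] <- 1L
      break
    }
  }
  cls
}

#' Build the reusable pair database
#'
#' Repeatedly samples and labels peak pairs until \code{config$pairDbSize}
#' non-discarded entries are collected.  Entries store the labeled truth
#' in coordinates relative to the leftmost center.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @param size Number of entries (default \code{config$pairDbSize}).
#' @return List of entries, each with \code{truth}, \code{decision} and
#'   \code{topo}.
#' @export
buildPairDatabase <- function(config = generatorConfig(), size = NULL) {
  if (is.null(size)) size <- config$pairDbSize
  db <- vector("list", size)
  got <- 0L
  tries <- 0L
  while (got < size) {
    tries <- tries + 1L
    if (tries > 60L * size)
      stop("pair database starvation: too many discarded pairs (",
           got, " of ", size, " after ", tries, " draws)")
    pair <- samplePeakPair(config)
    lab <- labelPair(pair, config)
    if (lab$decision == "DISCARD") next
    truth <- lab$truth
    truth$center <- truth$center - min(truth$center)
    got <- got + 1L
    db[[got]] <- list(truth = truth, decision = lab$decision,
                      topo = .peakTopo(truth, config$overlapFactor))
  }
  db
}

#' Compose a multi-peak segment with reduced-fit relabeling
#'
#' Draws singles and pairs from the database until the segment holds 3-5
#' peaks, placed with random inter-unit gaps, then asks whether the
#' summed profile can be explained robustly by one peak fewer (within the
#' 3% exclusion threshold).  If so, the truth is relabeled to the reduced
#' fitted set (or, with \code{reducibleAction = "remove"}, the segment is
#' dropped); a reducible but non-robust fit always drops the segment.  A
#' cheap geometric screen skips the expensive reduced fit when every pair
#' of peaks is separated by more than 1.2 times the overlap distance, a
#' regime in which the reduced fit cannot reach the threshold.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @param pairDB Database from \code{\link{buildPairDatabase}}.
#' @param k Number of generating peaks (default random in 3-5).
#' @return List with \code{truth} (possibly relabeled) and
#'   \code{relabeled}, or NULL when the segment is rejected.
#' @export
composeMultipeak <- function(config, pairDB, k = NULL,
                             gapRange = c(0.4, 1.1)) {
  if (is.null(k)) k <- sample(3:5, 1)
  stopifnot(k >= 2, length(pairDB) >= 1)
  peaks <- NULL
  total <- 0L
  while (total < k) {
    if (total == k - 1L || runif(1) < 0.35) {
      f <- runif(1, config$pppRange[1], config$pppRange[2])
      unit <- voigtPeaks(0, exp(runif(1, log(0.1), log(1))), f, runif(1))
    } else {
      e <- pairDB[[sample(length(pairDB), 1)]]
      unit <- e$truth
      unit$amplitude <- unit$amplitude * exp(runif(1, log(0.1), log(1)))
      if (runif(1) < 0.5) {  # mirror for left/right symmetry
        unit$center <- max(unit$center) - unit$center
        unit <- unit[order(unit$center), , drop = FALSE]
      }
    }
    if (is.null(peaks)) {
      peaks <- unit
    } else {
      gap <- runif(1, gapRange[1], gapRange[2]) *
        mean(c(max(peaks$fwhh), max(unit$fwhh)))
      unit$center <- unit$center + max(peaks$center) + gap
      peaks <- rbind(peaks, unit)
    }
    total <- nrow(peaks)
  }
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL

  # geometric screen: reduced fit can only merge strongly overlapped peaks
  dmat <- abs(outer(peaks$center, peaks$center, "-")) /
    outer(peaks$fwhh, peaks$fwhh, "+")
  diag(dmat) <- Inf
  if (min(dmat) > 1.2 * config$overlapFactor)
    return(list(truth = peaks, relabeled = FALSE))

  win <- .pairWindow(peaks, pad = 3)
  shifted <- peaks
  shifted$center <- shifted$center - win$offset
  profile <- .sumPeaks(shifted, win$n)
  fit <- fitKPeaks(profile, nrow(peaks) - 1L, nStarts = config$fitRestarts)
  if (is.finite(fit$maxAbsErrorFraction) &&
      fit$maxAbsErrorFraction < config$exclusionThreshold) {
    if (!fit$robust || config$reducibleAction == "remove") return(NULL)
    truth <- fit$peaks
    truth$center <- truth$center + win$offset
    return(list(truth = truth, relabeled = TRUE))
  }
  list(truth = peaks, relabeled = FALSE)
}

# ---- example assembly -------------------------------------------------

# write 3-point labels and masked regressor targets for one normalized
# example; ties at contested points go to the higher-amplitude peak
.labelExample <- function(truth, n, overlapFactor) {
  cls <- assignClasses(truth, overlapFactor)
  labels <- integer(n)
  mask <- logical(n)
  targets <- matrix(0, n, 4,
                    dimnames = list(NULL, c("offset", "amplitude", "fwhh", "eta")))
  for (i in order(truth$amplitude, decreasing = TRUE)) {
    r <- round(truth$center[i])
    for (p in (r - 1L):(r + 1L)) {
      if (p < 0 || p >= n || mask[p + 1]) next
      mask[p + 1] <- TRUE
      labels[p + 1] <- cls[i]
      targets[p + 1, ] <- c(truth$center[i] - p, truth$amplitude[i],
                            truth$fwhh[i], truth$eta[i])
    }
  }
  list(classLabels = labels, mask = mask, targets = targets, classes = cls)
}

#' Assemble a training example from truth segments
#'
#' Places segments at non-clashing random offsets on the example grid
#' (cross-segment center distances at least 1.2 times the sum of the two
#' FWHHs, peaks at least \code{edgeMargin} points from the edges),
#' normalizes the spectrum to unit maximum and writes 3-point class
#' labels plus masked regressor targets (sub-pixel offset, amplitude,
#' FWHH, Lorentzian fraction) at the three grid points nearest each truth
#' center.
#'
#' @param units List of truth peak tables in segment-local coordinates.
#' @param config A \code{\link{generatorConfig}}.
#' @param maxTries Placement retries before giving up.
#' @return A training example (list with \code{intensities},
#'   \code{classLabels}, \code{targets}, \code{mask}, \code{truth},
#'   \code{scale}) or NULL if placement failed.
#' @export
assembleExample <- function(units, config, maxTries = 40) {
  n <- config$nPointsPerExample
  margin <- config$edgeMargin
  placed <- NULL
  for (u in units) {
    span <- max(u$center) - min(u$center)
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      off <- runif(1, margin, n - 1 - margin - span) - min(u$center)
      cand <- u
      cand$center <- cand$center + off
      if (!is.null(placed)) {
        d <- abs(outer(cand$center, placed$center, "-"))
        lim <- 1.2 * outer(cand$fwhh, placed$fwhh, "+")
        if (any(d < lim)) next
      }
      placed <- rbind(placed, cand)
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  truth <- placed[order(placed$center), , drop = FALSE]
  rownames(truth) <- NULL
  y <- .sumPeaks(truth, n)
  if (config$noiseSigma > 0)
    y <- y + rnorm(n, sd = config$noiseSigma)
  scale <- max(y)
  y <- y / scale
  truth$amplitude <- truth$amplitude / scale
  lab <- .labelExample(truth, n, config$overlapFactor)
  truth$class <- lab$classes
  list(intensities = y, classLabels = lab$classLabels,
       targets = lab$targets, mask = lab$mask, truth = truth, scale = scale)
}

# choose the next unit for an example, biased toward the overlap-topology
# categories (S / L / R / B) currently least represented
.drawUnit <- function(config, pairDB, pool, counts, remaining) {
  wS <- 1 / (1 + counts["S"])
  wLR <- 1 / (1 + min(counts["L"], counts["R"]))
  wB <- 1 / (1 + counts["B"])
  types <- c("single")
  w <- c(wS)
  if (remaining >= 2) { types <- c(types, "pair"); w <- c(w, 2 * wLR) }
  if (remaining >= 3 && length(pool)) { types <- c(types, "composed"); w <- c(w, 3 * wB) }
  type <- sample(types, 1, prob = w / sum(w))
  if (type == "single") {
    f <- runif(1, config$pppRange[1], config$pppRange[2])
    return(voigtPeaks(0, 1, f, runif(1)))
  }
  if (type == "pair") {
    idx <- seq_along(pairDB)
    if (min(counts["L"], counts["R"]) <= min(counts)) {
      ov <- which(vapply(pairDB, function(e) any(e$topo %in% c("L", "R")), TRUE))
      if (length(ov)) idx <- ov
    }
    u <- pairDB[[idx[sample(length(idx), 1)]]]$truth
  } else {
    idx <- seq_along(pool)
    fits <- which(vapply(pool, function(e) nrow(e$truth) <= remaining, TRUE))
    if (!length(fits)) {
      u <- pairDB[[sample(length(pairDB), 1)]]$truth
    } else {
      if (counts["B"] <= min(counts)) {
        wb <- intersect(fits, which(vapply(pool, function(e)
          any(e$topo == "B"), TRUE)))
        if (length(wb)) fits <- wb
      }
      u <- pool[[fits[sample(length(fits), 1)]]]$truth
    }
  }
  u$amplitude <- u$amplitude * exp(runif(1, log(0.2), log(1)))
  if (runif(1) < 0.5) {
    u$center <- max(u$center) - u$center
    u <- u[order(u$center), , drop = FALSE]
    rownames(u) <- NULL
  }
  u
}

.exampleTopoCounts <- function(ex, overlapFactor) {
  topo <- .peakTopo(ex$truth, overlapFactor)
  tab <- c(S = 0, L = 0, R = 0, B = 0)
  t2 <- table(topo)
  tab[names(t2)] <- as.numeric(t2)
  tab
}

.generateOneExample <- function(config, pairDB, pool, counts) {
  for (attempt in 1:25) {
    target <- sample(config$peaksPerExample[1]:config$peaksPerExample[2], 1)
    units <- list()
    total <- 0L
    while (total < target) {
      u <- .drawUnit(config, pairDB, pool, counts, target - total)
      if (nrow(u) > target - total) next
      units[[length(units) + 1L]] <- u
      total <- total + nrow(u)
    }
    ex <- assembleExample(units, config)
    if (!is.null(ex)) return(ex)
  }
  stop("example generation starvation: could not place peaks within the ",
       "edge margins after repeated attempts")
}

#' Build the training and validation corpora
#'
#' Generates exactly \code{nTrain} and \code{nVal} class-balanced
#' examples.  The pair database and composed-segment pool are built
#' first; training and validation examples are then generated from
#' disjoint seeded RNG streams.  Unit selection is continuously biased
#' toward the overlap-topology category (standalone / left-shoulder /
#' right-shoulder / double-shoulder) currently least represented, and a
#' final trim-and-replace pass enforces that no category exceeds twice
#' the smallest.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @param verbose Print progress.
#' @return A \linkS4class{TrainingCorpus}.
#' @export
buildCorpus <- function(config = generatorConfig(), verbose = FALSE) {
  seeds <- .withSeed(config$seed, sample.int(.Machine$integer.max - 1, 4))
  if (verbose) message("building pair database (", config$pairDbSize, " entries)")
  pairDB <- .withSeed(seeds[1], buildPairDatabase(config))
  if (verbose) message("building composed-segment pool (",
                       config$composedPoolSize, " entries)")
  pool <- .withSeed(seeds[2], {
    out <- list()
    tries <- 0L
    while (length(out) < config$composedPoolSize) {
      tries <- tries + 1L
      if (tries > 40L * config$composedPoolSize)
        stop("composed-segment pool starvation")
      # half the pool uses tight gaps to supply double-shoulder topologies
      gaps <- if (length(out) %% 2 == 0) c(0.3, 0.65) else c(0.4, 1.1)
      seg <- composeMultipeak(config, pairDB, gapRange = gaps)
      if (is.null(seg)) next
      seg$topo <- .peakTopo(seg$truth, config$overlapFactor)
      out[[length(out) + 1L]] <- seg
    }
    out
  })
  counts <- c(S = 0, L = 0, R = 0, B = 0)
  gen <- function(nEx) {
    out <- vector("list", nEx)
    for (i in seq_len(nEx)) {
      ex <- .generateOneExample(config, pairDB, pool, counts)
      counts <<- counts + .exampleTopoCounts(ex, config$overlapFactor)
      out[[i]] <- ex
      if (verbose && i %% 500 == 0) message("  ", i, " / ", nEx)
    }
    out
  }
  train <- .withSeed(seeds[3], gen(config$nTrain))
  val <- .withSeed(seeds[4], gen(config$nVal))

  # trim-and-replace pass: replace examples dominated by the largest
  # category until balance (max <= 2 * min) holds
  rebalance <- .withSeed(seeds[4] %% 1000000L + 7L, {
    budget <- 200L
    while (max(counts) > 2 * min(counts) && budget > 0L) {
      budget <- budget - 1L
      big <- names(which.max(counts))
      contrib <- vapply(train, function(ex)
        .exampleTopoCounts(ex, config$overlapFactor)[big], 0)
      idx <- which.max(contrib)
      counts <- counts - .exampleTopoCounts(train[[idx]], config$overlapFactor)
      repl <- .generateOneExample(config, pairDB, pool, counts)
      counts <- counts + .exampleTopoCounts(repl, config$overlapFactor)
      train[[idx]] <- repl
    }
    if (max(counts) > 2 * min(counts))
      stop("could not balance overlap-topology categories: ",
           paste(names(counts), counts, sep = "=", collapse = ", "))
    invisible(NULL)
  })
  new("TrainingCorpus", train = train, val = val,
      config = c(config, list(topoCounts = counts)))
}

#' Overlap-topology category counts of a corpus
#'
#' @param corpus A \linkS4class{TrainingCorpus}.
#' @return Named numeric vector (S, L, R, B).
#' @export
topologyCounts <- function(corpus) {
  counts <- c(S = 0, L = 0, R = 0, B = 0)
  for (ex in c(corpus@train, corpus@val))
    counts <- counts + .exampleTopoCounts(ex, corpus@config$overlapFactor)
  counts
}

#' Serialize / load a corpus archive
#'
#' Single-file archive embedding the full generator configuration; the
#' round trip is byte-exact.
#'
#' @param corpus A \linkS4class{TrainingCorpus}.
#' @param path File path.
#' @return \code{readCorpus} returns the \linkS4class{TrainingCorpus}.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "TrainingCorpus"))
  saveRDS(list(format = "VoigtPicker-corpus-1", config = corpus@config,
               train = corpus@train, val = corpus@val),
          path, version = 2)
  invisible(path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "VoigtPicker-corpus-1"))
    stop("not a VoigtPicker corpus archive: ", path)
  new("TrainingCorpus", train = obj$train, val = obj$val, config = obj$config)
}

# stack a list of examples into the dense arrays the trainer consumes
.corpusTensors <- function(examples) {
  B <- length(examples)
  n <- length(examples[[1]]$intensities)
  X <- matrix(0, n, B)
  lab <- matrix(0L, n, B)
  targ <- matrix(0, 4L * n, B)
  for (b in seq_len(B)) {
    ex <- examples[[b]]
    X[, b] <- ex$intensities
    lab[, b] <- ex$classLabels
    targ[, b] <- as.numeric(ex$targets)   # column-major: 4 blocks of n
  }
  list(X = X, labels = lab, targets = targ)
}
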