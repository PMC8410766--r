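#' Pseudo-Voigt profile
#'
#' Unit-parameterized pseudo-Voigt lineshape: a convex combination
#' \eqn{V(x) = A [\eta L(x) + (1-\eta) G(x)]} of a unit-height Lorentzian
#' and a unit-height Gaussian that share the same full width at half
#' height (FWHH).  \code{eta} is the Lorentzian fraction: 0 gives a pure
#' Gaussian, 1 a pure Lorentzian.  Because both components have unit
#' height, the profile height at \code{center} is exactly
#' \code{amplitude} for every \code{eta}, and the mixture has FWHH equal
#' to \code{fwhh} exactly.
#'
#' @param x Numeric vector of grid coordinates (may be sub-pixel).
#' @param center Peak center in grid-point units (real-valued).
#' @param amplitude Peak height (> 0).
#' @param fwhh Full width at half height in grid-point units (> 0).
#' @param eta Lorentzian fraction in [0, 1].
#' @return Numeric vector of profile values at \code{x}.
#' @export
pseudoVoigt <- function(x, center, amplitude, fwhh, eta) {
  u <- (x - center) / fwhh
  lor <- 1 / (1 + 4 * u^2)
  gau <- exp(-4 * log(2) * u^2)
  amplitude * (eta * lor + (1 - eta) * gau)
}

.checkPeaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "amplitude", "fwhh", "eta") %in% names(peaks)))
  with(peaks, {
    if (!all(is.finite(center)) || !all(is.finite(amplitude)) ||
        !all(is.finite(fwhh)) || !all(is.finite(eta)))
      stop("peak parameters must be finite")
    if (any(amplitude <= 0)) stop("amplitude must be > 0")
    if (any(fwhh <= 0)) stop("fwhh must be > 0")
    if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]")
  })
  invisible(peaks)
}

#' Construct a table of Voigt peaks
#'
#' Peaks are plain data.frames with columns \code{center, amplitude,
#' fwhh, eta} (grid-point units; amplitude is height, not volume).
#'
#' @param center,amplitude,fwhh,eta Numeric vectors, recycled to common
#'   length.
#' @return A validated data.frame, one peak per row.
#' @export
voigtPeaks <- function(center, amplitude = 1, fwhh = 10, eta = 0.5) {
  if (length(center) == 0)
    return(data.frame(center = numeric(), amplitude = numeric(),
                      fwhh = numeric(), eta = numeric()))
  df <- data.frame(center = center, amplitude = amplitude,
                   fwhh = fwhh, eta = eta)
  .checkPeaks(df)
}

#' Evaluate one peak on an integer grid
#'
#' @param peak One-row peak table (see \code{\link{voigtPeaks}}).
#' @param nPoints Grid length (>= 2); the grid is 0 .. nPoints-1.
#' @return Numeric vector of length \code{nPoints}.
#' @export
evalPeak <- function(peak, nPoints) {
  stopifnot(nPoints >= 2)
  .checkPeaks(peak)
  pseudoVoigt(seq_len(nPoints) - 1, peak$center[1], peak$amplitude[1],
              peak$fwhh[1], peak$eta[1])
}

.sumPeaks <- function(peaks, nPoints) {
  x <- seq_len(nPoints) - 1
  y <- numeric(nPoints)
  for (i in seq_len(nrow(peaks)))
    y <- y + pseudoVoigt(x, peaks$center[i], peaks$amplitude[i],
                         peaks$fwhh[i], peaks$eta[i])
  y
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthesize a 1D spectrum with known ground truth
#'
#' Sum of pseudo-Voigt peaks plus i.i.d. Gaussian noise.  With a fixed
#' \code{seed} the output is bitwise reproducible; the caller's RNG state
#' is left untouched.
#'
#' @param peaks Peak table (possibly empty if \code{noiseSigma > 0}).
#' @param nPoints Spectrum length.
#' @param noiseSigma Standard deviation of additive Gaussian noise.
#' @param seed Optional integer seed for the noise.
#' @param axis Optional axis calibration.
#' @return An \linkS4class{NMRSpectrum1D}.
#' @export
synthSpectrum1D <- function(peaks, nPoints, noiseSigma = 0, seed = NULL,
                            axis = list()) {
  stopifnot(nPoints >= 2)
  if (nrow(peaks) == 0 && noiseSigma <= 0)
    stop("need at least one peak or noiseSigma > 0")
  if (nrow(peaks)) .checkPeaks(peaks)
  y <- .sumPeaks(peaks, nPoints)
  if (noiseSigma > 0)
    y <- y + .withSeed(seed, rnorm(nPoints, sd = noiseSigma))
  nmrSpectrum1D(y, axis)
}

#' Construct a table of separable 2D cross-peaks
#'
#' Each cross-peak is the outer product of a unit-height row profile and a
#' unit-height column profile, scaled by \code{amplitude}.
#'
#' @param rowCenter,colCenter Centers in grid points (row = indirect dim).
#' @param amplitude Cross-peak height.
#' @param rowFwhh,colFwhh Per-dimension FWHH in points.
#' @param rowEta,colEta Per-dimension Lorentzian fractions.
#' @return A data.frame, one cross-peak per row.
#' @export
crossPeaks <- function(rowCenter, colCenter, amplitude = 1,
                       rowFwhh = 8, colFwhh = 8, rowEta = 0.5, colEta = 0.5) {
  if (length(rowCenter) == 0)
    return(data.frame(rowCenter = numeric(), colCenter = numeric(),
                      amplitude = numeric(), rowFwhh = numeric(),
                      colFwhh = numeric(), rowEta = numeric(),
                      colEta = numeric()))
  df <- data.frame(rowCenter = rowCenter, colCenter = colCenter,
                   amplitude = amplitude, rowFwhh = rowFwhh,
                   colFwhh = colFwhh, rowEta = rowEta, colEta = colEta)
  if (any(df$amplitude <= 0) || any(df$rowFwhh <= 0) || any(df$colFwhh <= 0) ||
      any(df$rowEta < 0 | df$rowEta > 1) || any(df$colEta < 0 | df$colEta > 1))
    stop("invalid cross-peak parameters")
  df
}

#' Synthesize a separable 2D spectrum
#'
#' @param peaks Cross-peak table from \code{\link{crossPeaks}} (possibly
#'   empty when \code{noiseSigma > 0}).
#' @param dim Integer vector \code{c(rows, cols)}, both >= 8.
#' @param noiseSigma Additive Gaussian noise standard deviation.
#' @param seed Optional integer seed.
#' @param axes Optional axis calibrations.
#' @return An \linkS4class{NMRSpectrum2D}.
#' @export
synthSpectrum2D <- function(peaks, dim, noiseSigma = 0, seed = NULL,
                            axes = list()) {
  stopifnot(length(dim) == 2, all(dim >= 8))
  if (nrow(peaks) == 0 && noiseSigma <= 0)
    stop("need at least one cross-peak or noiseSigma > 0")
  m <- matrix(0, dim[1], dim[2])
  r <- seq_len(dim[1]) - 1
  cc <- seq_len(dim[2]) - 1
  for (i in seq_len(nrow(peaks))) {
    pr <- pseudoVoigt(r, peaks$rowCenter[i], 1, peaks$rowFwhh[i], peaks$rowEta[i])
    pc <- pseudoVoigt(cc, peaks$colCenter[i], 1, peaks$colFwhh[i], peaks$colEta[i])
    m <- m + peaks$amplitude[i] * outer(pr, pc)
  }
  if (noiseSigma > 0)
    m <- m + .withSeed(seed, matrix(rnorm(length(m), sd = noiseSigma),
                                    dim[1], dim[2]))
  nmrSpectrum2D(m, axes)
}

#' Measure the full width at half maximum of a profile
#'
#' Linear interpolation of the two half-maximum crossings around the
#' profile maximum, in grid-point units.
#'
#' @param profile Numeric vector with a maximum above half its range.
#' @return Interpolated FWHH (numeric scalar).
#' @export
measureFWHH <- function(profile) {
  n <- length(profile)
  imax <- which.max(profile)
  half <- profile[imax] / 2
  left <- NA_real_
  if (imax > 1) for (i in imax:2) {
    if (profile[i - 1] <= half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  if (imax < n) for (i in imax:(n - 1)) {
    if (profile[i + 1] <= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("no half-height crossings found on both sides of the maximum")
  right - left
}

#' True Voigt profile by numerical convolution (cross-check oracle)
#'
#' Evaluates the genuine Voigt profile -- the convolution of a Lorentzian
#' of FWHH \code{fwhhLorentz} with a Gaussian of FWHH \code{fwhhGauss} --
#' on a fine auxiliary grid via FFT, normalized to unit height, then
#' interpolated at \code{x}.  This is deliberately independent of
#' \code{\link{pseudoVoigt}} and is used as a numerical oracle; the
#' picker itself works entirely in the pseudo-Voigt approximation because
#' its single Lorentzian-fraction parameter maps one-to-one onto a
#' regressor channel.
#'
#' @param x Evaluation coordinates (grid points).
#' @param center Peak center.
#' @param amplitude Peak height.
#' @param fwhhGauss,fwhhLorentz Component FWHHs (points).
#' @param oversample Fine-grid oversampling factor.
#' @return Profile values at \code{x}.
#' @export
voigtConvolution <- function(x, center, amplitude, fwhhGauss, fwhhLorentz,
                             oversample = 50) {
  span <- 40 * max(fwhhGauss, fwhhLorentz)
  h <- 1 / oversample
  g <- seq(-span, span, by = h)
  lor <- 1 / (1 + 4 * (g / fwhhLorentz)^2)
  gau <- exp(-4 * log(2) * (g / fwhhGauss)^2)
  n <- length(g)
  # linear convolution via zero-padded FFT
  m <- stats::nextn(2 * n - 1)
  v <- Re(stats::fft(stats::fft(c(lor, numeric(m - n))) *
                     stats::fft(c(gau, numeric(m - n))), inverse = TRUE)) / m
  v <- v[seq_len(2 * n - 1)]
  mid <- which.max(v)
  v <- v / v[mid]
  xg <- (seq_along(v) - mid) * h
  amplitude * stats::approx(xg, v, xout = x - center, rule = 2)$y
}
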