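#' Group picked peaks into overlap clusters
#'
#' Two peaks overlap when their center distance is below 1.5 times the
#' sum of their half-FWHHs in every dimension; clusters are the
#' connected components of this relation (singletons allowed).
#'
#' @param peaks A \linkS4class{PeakSet} or peak table (1d or 2d columns).
#' @return List of integer index vectors, one per cluster, in order of
#'   first member.
#' @export
clusterPeaks <- function(peaks) {
  pk <- if (is(peaks, "PeakSet")) peaks@peaks else peaks
  n <- nrow(pk)
  if (n == 0) return(list())
  is2d <- "posRow" %in% names(pk)
  ov <- function(i, j) {
    if (is2d) {
      abs(pk$posRow[i] - pk$posRow[j]) <
        1.5 * (pk$fwhhRow[i] + pk$fwhhRow[j]) / 2 &&
      abs(pk$posCol[i] - pk$posCol[j]) <
        1.5 * (pk$fwhhCol[i] + pk$fwhhCol[j]) / 2
    } else {
      abs(pk$position[i] - pk$position[j]) <
        1.5 * (pk$fwhh[i] + pk$fwhh[j]) / 2
    }
  }
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (j in seq_len(n)) {
        if (!is.na(comp[j]) || !ov(cur, j)) next
        comp[j] <- nc
        queue <- c(queue, j)
      }
    }
  }
  lapply(seq_len(nc), function(k) which(comp == k))
}

.clusterRegion1D <- function(pk, n) {
  pad <- 2 * max(pk$fwhh)
  lo <- max(0, floor(min(pk$position) - pad))
  hi <- min(n - 1, ceiling(max(pk$position) + pad))
  c(lo, hi)
}

#' Simultaneously refine all peaks of one cluster
#'
#' Bounded Levenberg-Marquardt least squares over all cluster peaks'
#' parameters jointly against the spectrum region spanning the cluster
#' (cluster extent padded by twice the maximal FWHH).  Bounds: position
#' within 2 points of the seed, FWHH within [0.5x, 2x] of the seed,
#' Lorentzian fraction in [0, 1], amplitude positive.  For 2D peaks the
#' model is a sum of separable pseudo-Voigt products.  If the fit does
#' not reduce the seeded sum of squared residuals, the seeds are
#' returned unchanged with \code{converged = FALSE}.
#'
#' @param pk Peak table of the cluster members.
#' @param spectrum The spectrum the peaks were picked from.
#' @param amplitudeOnly Refit amplitudes only, keeping shapes fixed.
#' @param others Peak table of picked peaks outside the cluster; their
#'   modeled profiles are subtracted from the fit region so that
#'   far-reaching (Lorentzian) tails of neighbouring peaks do not bias
#'   the cluster's parameters.
#' @return List with \code{peaks} (refined table),
#'   \code{residualFraction} (max |residual| / max region amplitude) and
#'   \code{converged}.
#' @export
fitCluster <- function(pk, spectrum, amplitudeOnly = FALSE, others = NULL) {
  is2d <- "posRow" %in% names(pk)
  if (is2d) .fitCluster2D(pk, spectrum, amplitudeOnly, others)
  else .fitCluster1D(pk, spectrum, amplitudeOnly, others)
}

.runClusterFit <- function(par0, lower, upper, residFn) {
  ssq0 <- sum(residFn(par0)^2)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = residFn,
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit) || sum(fit$fvec^2) > ssq0)
    return(list(par = par0, ok = FALSE, resid = residFn(par0)))
  list(par = fit$par, ok = TRUE, resid = fit$fvec)
}

.fitCluster1D <- function(pk, spectrum, amplitudeOnly, others = NULL) {
  y <- if (is(spectrum, "NMRSpectrum1D")) intensities(spectrum)
       else as.numeric(spectrum)
  reg <- .clusterRegion1D(pk, length(y))
  idx <- (reg[1]:reg[2]) + 1
  yr <- y[idx]
  x <- reg[1]:reg[2]
  if (!is.null(others) && nrow(others))
    for (j in seq_len(nrow(others)))
      yr <- yr - pseudoVoigt(x, others$position[j], others$amplitude[j],
                             others$fwhh[j], others$eta[j])
  k <- nrow(pk)
  if (amplitudeOnly) {
    par0 <- pk$amplitude
    lower <- rep(1e-12, k)
    upper <- rep(Inf, k)
    shape <- lapply(seq_len(k), function(j)
      pseudoVoigt(x, pk$position[j], 1, pk$fwhh[j], pk$eta[j]))
    residFn <- function(par) {
      Reduce(`+`, Map(`*`, shape, as.list(par))) - yr
    }
  } else {
    par0 <- as.numeric(t(pk[, c("position", "amplitude", "fwhh", "eta")]))
    lower <- as.numeric(t(cbind(pk$position - 2, 1e-12, pk$fwhh * 0.5, 0)))
    upper <- as.numeric(t(cbind(pk$position + 2, Inf, pk$fwhh * 2, 1)))
    residFn <- function(par) {
      m <- numeric(length(x))
      for (j in seq_len(k)) {
        p <- par[(4 * j - 4) + 1:4]
        m <- m + pseudoVoigt(x, p[1], p[2], p[3], p[4])
      }
      m - yr
    }
  }
  out <- .runClusterFit(par0, lower, upper, residFn)
  ref <- pk
  if (amplitudeOnly) {
    ref$amplitude <- out$par
  } else {
    pm <- matrix(out$par, ncol = 4, byrow = TRUE)
    ref$position <- pm[, 1]; ref$amplitude <- pm[, 2]
    ref$fwhh <- pm[, 3]; ref$eta <- pm[, 4]
  }
  list(peaks = ref, residualFraction = max(abs(out$resid)) / max(abs(yr)),
       converged = out$ok)
}

.fitCluster2D <- function(pk, spectrum, amplitudeOnly, others = NULL) {
  m <- if (is(spectrum, "NMRSpectrum2D")) intensities(spectrum)
       else as.matrix(spectrum)
  padR <- 2 * max(pk$fwhhRow); padC <- 2 * max(pk$fwhhCol)
  r0 <- max(0, floor(min(pk$posRow) - padR))
  r1 <- min(nrow(m) - 1, ceiling(max(pk$posRow) + padR))
  c0 <- max(0, floor(min(pk$posCol) - padC))
  c1 <- min(ncol(m) - 1, ceiling(max(pk$posCol) + padC))
  mr <- m[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
  rr <- r0:r1
  cc <- c0:c1
  if (!is.null(others) && nrow(others))
    for (j in seq_len(nrow(others)))
      mr <- mr - others$amplitude[j] *
        outer(pseudoVoigt(rr, others$posRow[j], 1, others$fwhhRow[j],
                          others$etaRow[j]),
              pseudoVoigt(cc, others$posCol[j], 1, others$fwhhCol[j],
                          others$etaCol[j]))
  k <- nrow(pk)
  if (amplitudeOnly) {
    par0 <- pk$amplitude
    lower <- rep(1e-12, k); upper <- rep(Inf, k)
    shapes <- lapply(seq_len(k), function(j)
      outer(pseudoVoigt(rr, pk$posRow[j], 1, pk$fwhhRow[j], pk$etaRow[j]),
            pseudoVoigt(cc, pk$posCol[j], 1, pk$fwhhCol[j], pk$etaCol[j])))
    residFn <- function(par)
      as.numeric(Reduce(`+`, Map(`*`, shapes, as.list(par))) - mr)
  } else {
    cols <- c("posRow", "posCol", "amplitude", "fwhhRow", "fwhhCol",
              "etaRow", "etaCol")
    par0 <- as.numeric(t(pk[, cols]))
    lower <- as.numeric(t(cbind(pk$posRow - 2, pk$posCol - 2, 1e-12,
                                pk$fwhhRow * 0.5, pk$fwhhCol * 0.5, 0, 0)))
    upper <- as.numeric(t(cbind(pk$posRow + 2, pk$posCol + 2, Inf,
                                pk$fwhhRow * 2, pk$fwhhCol * 2, 1, 1)))
    residFn <- function(par) {
      mm <- matrix(0, length(rr), length(cc))
      for (j in seq_len(k)) {
        p <- par[(7 * j - 7) + 1:7]
        mm <- mm + p[3] * outer(pseudoVoigt(rr, p[1], 1, p[4], p[6]),
                                pseudoVoigt(cc, p[2], 1, p[5], p[7]))
      }
      as.numeric(mm - mr)
    }
  }
  out <- .runClusterFit(par0, lower, upper, residFn)
  ref <- pk
  if (amplitudeOnly) {
    ref$amplitude <- out$par
  } else {
    pm <- matrix(out$par, ncol = 7, byrow = TRUE)
    ref$posRow <- pm[, 1]; ref$posCol <- pm[, 2]; ref$amplitude <- pm[, 3]
    ref$fwhhRow <- pm[, 4]; ref$fwhhCol <- pm[, 5]
    ref$etaRow <- pm[, 6]; ref$etaCol <- pm[, 7]
  }
  list(peaks = ref, residualFraction = max(abs(out$resid)) / max(abs(mr)),
       converged = out$ok)
}

#' Refine all picked peaks by simultaneous cluster fits
#'
#' Clusters the peaks by overlap, then refines each cluster
#' independently with \code{\link{fitCluster}}, seeding the fit with the
#' picker's estimates.  The number of peaks, their identities and
#' classes are preserved; only parameters move (within bounds).
#'
#' @param peaks A \linkS4class{PeakSet} from \code{\link{pickPeaks1D}} or
#'   \code{\link{pickPeaks2D}}.
#' @param spectrum The spectrum the peaks were picked from.
#' @param amplitudeOnly Refit amplitudes only.
#' @return A \linkS4class{PeakSet} with refined parameters; metadata
#'   records per-cluster convergence and residuals.
#' @export
refinePeaks <- function(peaks, spectrum, amplitudeOnly = FALSE) {
  stopifnot(is(peaks, "PeakSet"))
  pk <- peaks@peaks
  if (!nrow(pk)) return(peaks)
  clusters <- clusterPeaks(pk)
  info <- list()
  # two sequential passes: the second re-fits each cluster against the
  # data minus the other clusters' updated models, so neighbouring tails
  # settle
  for (pass in 1:2) {
    info <- list()
    for (cl in clusters) {
      res <- fitCluster(pk[cl, , drop = FALSE], spectrum, amplitudeOnly,
                        others = pk[-cl, , drop = FALSE])
      pk[cl, names(res$peaks)] <- res$peaks
      info[[length(info) + 1L]] <- list(members = cl,
                                        converged = res$converged,
                                        residualFraction = res$residualFraction)
    }
  }
  pk$origin <- rep("refined", nrow(pk))
  new("PeakSet", peaks = pk, kind = peaks@kind,
      metadata = c(peaks@metadata, list(refinement = info)))
}
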