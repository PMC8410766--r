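# NMRPipe header word indices (0-based positions in the 512-float header)
.FD <- list(MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
            F1QUADFLAG = 55L, F2QUADFLAG = 56L, SIZE = 99L, F2SW = 100L,
            F2ORIG = 101L, QUADFLAG = 106L, F2OBS = 119L, F1OBS = 218L,
            SPECNUM = 219L, F2FTFLAG = 220L, TRANSPOSED = 221L,
            F1FTFLAG = 222L, F1SW = 229L, F1ORIG = 249L)

.axisFromHeader <- function(sw, obs, orig, size) {
  if (obs == 0 || sw == 0) return(list())
  step <- sw / size
  list(refPpm = (orig + (size - 1) * step) / obs,
       ppmPerPoint = -step / obs, obsMHz = obs)
}

#' Convert between grid points and ppm
#'
#' Affine conversions using an axis calibration list (\code{refPpm},
#' \code{ppmPerPoint}); exact inverses of each other.
#'
#' @param points,ppm Numeric vectors (points are 0-based grid
#'   coordinates, possibly sub-pixel).
#' @param axis Axis calibration list.
#' @return Converted numeric vector.
#' @export
pointsToPpm <- function(points, axis) {
  stopifnot(all(c("refPpm", "ppmPerPoint") %in% names(axis)))
  axis$refPpm + points * axis$ppmPerPoint
}

#' @rdname pointsToPpm
#' @export
ppmToPoints <- function(ppm, axis) {
  stopifnot(all(c("refPpm", "ppmPerPoint") %in% names(axis)))
  (ppm - axis$refPpm) / axis$ppmPerPoint
}

#' Read a frequency-domain spectrum
#'
#' Supports NMRPipe files (512-float header followed by real float32
#' intensities; frequency-domain, real data only) and plain-text
#' matrices (whitespace- or comma-separated rows, with an optional
#' JSON axis sidecar \code{<path>.axis.json}).
#'
#' @param path File path.
#' @param format "nmrpipe" or "text_matrix".
#' @return An \linkS4class{NMRSpectrum1D} or \linkS4class{NMRSpectrum2D}.
#' @export
readSpectrum <- function(path, format = c("nmrpipe", "text_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nmrpipe") .readNMRPipe(path) else .readTextMatrix(path)
}

.readNMRPipe <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "numeric", n = 512, size = 4, endian = "little")
  if (length(hdr) < 512) stop("truncated NMRPipe file (header): ", path)
  endian <- "little"
  if (abs(hdr[.FD$FLTORDER + 1] - 2.345) > 1e-4) {
    seek(con, 0)
    hdr <- readBin(con, "numeric", n = 512, size = 4, endian = "big")
    endian <- "big"
    if (abs(hdr[.FD$FLTORDER + 1] - 2.345) > 1e-4)
      stop("not an NMRPipe file (bad byte-order word): ", path)
  }
  h <- function(k) hdr[.FD[[k]] + 1]
  dimCount <- round(h("DIMCOUNT"))
  size <- round(h("SIZE"))
  specnum <- max(1, round(h("SPECNUM")))
  if (h("QUADFLAG") != 1 || h("F2QUADFLAG") != 1)
    stop("complex NMRPipe data are not supported; extract the real part ",
         "during processing (e.g. with the -di flag)")
  if (h("F2FTFLAG") != 1)
    stop("time-domain NMRPipe data are not supported; Fourier transform ",
         "the data first")
  want <- size * specnum
  dat <- readBin(con, "numeric", n = want, size = 4, endian = endian)
  if (length(dat) < want)
    stop("truncated NMRPipe file: expected ", want, " points, got ",
         length(dat), ": ", path)
  axF2 <- .axisFromHeader(h("F2SW"), h("F2OBS"), h("F2ORIG"), size)
  if (dimCount <= 1 || specnum == 1)
    return(nmrSpectrum1D(dat, axF2))
  if (h("F1QUADFLAG") != 1 || h("F1FTFLAG") != 1)
    stop("indirect dimension must be real frequency-domain data")
  axF1 <- .axisFromHeader(h("F1SW"), h("F1OBS"), h("F1ORIG"), specnum)
  nmrSpectrum2D(matrix(dat, nrow = specnum, ncol = size, byrow = TRUE),
                axes = list(row = axF1, col = axF2))
}

#' Write a spectrum as an NMRPipe file
#'
#' Real float32 frequency-domain data with a minimal 512-float header
#' (little-endian).  Used to generate round-trip fixtures and to export
#' synthetic spectra.
#'
#' @param spectrum An \linkS4class{NMRSpectrum1D} or
#'   \linkS4class{NMRSpectrum2D}.
#' @param path Output path.
#' @param sw,obs,orig Direct-dimension spectral width (Hz), observe
#'   frequency (MHz) and origin (Hz) when the spectrum has no axis
#'   calibration.
#' @param sw1,obs1,orig1 Indirect-dimension equivalents (2D only).
#' @return The path, invisibly.
#' @export
writeNMRPipe <- function(spectrum, path, sw = 6000, obs = 600, orig = 0,
                         sw1 = 2000, obs1 = 60, orig1 = 0) {
  is2d <- is(spectrum, "NMRSpectrum2D")
  m <- intensities(spectrum)
  size <- if (is2d) ncol(m) else length(m)
  specnum <- if (is2d) nrow(m) else 1L
  ax <- spectrumAxis(spectrum)
  axCol <- if (is2d) ax$col else ax
  if (length(axCol)) {
    step <- -axCol$ppmPerPoint * axCol$obsMHz
    sw <- step * size
    obs <- axCol$obsMHz
    orig <- axCol$refPpm * obs - (size - 1) * step
  }
  if (is2d && length(ax$row)) {
    step1 <- -ax$row$ppmPerPoint * ax$row$obsMHz
    sw1 <- step1 * specnum
    obs1 <- ax$row$obsMHz
    orig1 <- ax$row$refPpm * obs1 - (specnum - 1) * step1
  }
  hdr <- numeric(512)
  set <- function(k, v) hdr[.FD[[k]] + 1] <<- v
  set("FLTFORMAT", 4008636160)  # conventional float-format magic
  set("FLTORDER", 2.345)
  set("DIMCOUNT", if (is2d) 2 else 1)
  set("SIZE", size)
  set("SPECNUM", specnum)
  set("QUADFLAG", 1); set("F2QUADFLAG", 1); set("F1QUADFLAG", 1)
  set("F2FTFLAG", 1); set("F1FTFLAG", 1)
  set("F2SW", sw); set("F2OBS", obs); set("F2ORIG", orig)
  set("F1SW", sw1); set("F1OBS", obs1); set("F1ORIG", orig1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4, endian = "little")
  dat <- if (is2d) as.numeric(t(m)) else as.numeric(m)
  writeBin(dat, con, size = 4, endian = "little")
  invisible(path)
}

.readTextMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty text matrix: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "[,[:space:]]+")[[1]]))
    if (anyNA(v)) stop("parse error in ", path, " at line ", i)
    v
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("ragged rows in ", path, " (line ", which(lens != lens[1])[1], ")")
  axPath <- paste0(path, ".axis.json")
  axes <- if (file.exists(axPath)) jsonlite::read_json(axPath,
                                                       simplifyVector = TRUE)
          else list()
  if (length(rows) == 1)
    nmrSpectrum1D(rows[[1]], if (length(axes)) axes else list())
  else
    nmrSpectrum2D(do.call(rbind, rows), if (length(axes)) axes else list())
}

#' Write a spectrum as a plain-text matrix
#'
#' One spectrum row per line (a single line for 1D), whitespace
#' separated, full double precision; the axis calibration (if any) goes
#' to a JSON sidecar \code{<path>.axis.json}.
#'
#' @param spectrum A spectrum object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeSpectrumText <- function(spectrum, path) {
  m <- intensities(spectrum)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  ax <- spectrumAxis(spectrum)
  if (length(ax))
    jsonlite::write_json(ax, paste0(path, ".axis.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

.peakPpmColumns <- function(pk, kind, axes) {
  if (kind == "1d") {
    if (length(axes)) pk$ppm <- pointsToPpm(pk$position, axes)
  } else {
    if (length(axes$row)) pk$ppmRow <- pointsToPpm(pk$posRow, axes$row)
    if (length(axes$col)) pk$ppmCol <- pointsToPpm(pk$posCol, axes$col)
  }
  pk
}

#' Write a peak list
#'
#' \code{tsv} writes the full peak table (plus ppm columns when an axis
#' calibration is supplied) with an index column.  \code{sparky} writes
#' a Sparky-style list (\code{Assignment w1 w2 Height}, positions in
#' ppm; requires calibration).
#'
#' @param peaks A \linkS4class{PeakSet}.
#' @param path Output path.
#' @param format "tsv" or "sparky".
#' @param axes Axis calibration: for 1d a single axis list, for 2d a
#'   list with \code{row} and \code{col}.
#' @return The path, invisibly.
#' @export
writePeaks <- function(peaks, path, format = c("tsv", "sparky"),
                       axes = list()) {
  format <- match.arg(format)
  stopifnot(is(peaks, "PeakSet"))
  pk <- peaks@peaks
  if (format == "tsv") {
    out <- cbind(index = seq_len(nrow(pk)),
                 .peakPpmColumns(pk, peaks@kind, axes))
    if (nrow(pk) == 0) out <- cbind(index = integer(),
                                    .peakPpmColumns(pk, peaks@kind, axes))
    write.table(format(out, digits = 10, scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  # sparky list
  if (peaks@kind == "2d") {
    if (!length(axes$row) || !length(axes$col))
      stop("sparky output requires row and col axis calibrations (ppm)")
    w1 <- pointsToPpm(pk$posRow, axes$row)
    w2 <- pointsToPpm(pk$posCol, axes$col)
    lines <- c(sprintf("%17s %10s %10s %14s", "Assignment", "w1", "w2",
                       "Height"),
               sprintf("%17s %10.4f %10.4f %14.6g", "?-?", w1, w2,
                       pk$amplitude))
  } else {
    if (!length(axes))
      stop("sparky output requires an axis calibration (ppm)")
    w1 <- pointsToPpm(pk$position, axes)
    lines <- c(sprintf("%17s %10s %14s", "Assignment", "w1", "Height"),
               sprintf("%17s %10.4f %14.6g", "?", w1, pk$amplitude))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV peak list written by \code{\link{writePeaks}}
#'
#' @param path TSV path.
#' @return A \linkS4class{PeakSet}.
#' @export
readPeaksTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  kind <- if ("posRow" %in% names(df)) "2d" else "1d"
  df$index <- NULL
  new("PeakSet", peaks = df, kind = kind, metadata = list(source = path))
}

#' Compare predicted against true peak positions
#'
#' One-to-one greedy matching by increasing distance: the closest
#' remaining prediction-truth pair is matched while every coordinate
#' difference is within \code{matchTol} points.  Unmatched predictions
#' are false positives, unmatched truths false negatives.
#'
#' @param predicted,truth \linkS4class{PeakSet}s, peak tables, numeric
#'   position vectors (1d) or two-column matrices (2d: row, col).
#' @param matchTol Matching tolerance in points (per coordinate).
#' @return A \code{MatchReport} list: nTruth, nPred, truePositives,
#'   falsePositives, falseNegatives, precision, recall, positionRMSE
#'   (points, over matched pairs).
#' @export
evaluatePicks <- function(predicted, truth, matchTol = 2) {
  stopifnot(matchTol > 0)
  pos <- function(x) {
    if (is(x, "PeakSet")) x <- x@peaks
    if (is.data.frame(x)) {
      if ("posRow" %in% names(x)) return(cbind(x$posRow, x$posCol))
      if ("position" %in% names(x)) return(cbind(x$position))
      if ("rowCenter" %in% names(x)) return(cbind(x$rowCenter, x$colCenter))
      if ("center" %in% names(x)) return(cbind(x$center))
      stop("cannot extract positions")
    }
    if (is.null(dim(x))) cbind(as.numeric(x)) else as.matrix(x)
  }
  P <- pos(predicted)
  Tm <- pos(truth)
  if (ncol(P) != ncol(Tm) && nrow(P) && nrow(Tm))
    stop("predicted and truth dimensionality differ")
  nP <- nrow(P); nT <- nrow(Tm)
  pairs <- NULL
  if (nP && nT) {
    cand <- expand.grid(p = seq_len(nP), t = seq_len(nT))
    dd <- abs(P[cand$p, , drop = FALSE] - Tm[cand$t, , drop = FALSE])
    ok <- rowSums(dd > matchTol) == 0
    cand <- cand[ok, , drop = FALSE]
    cand$d <- sqrt(rowSums(dd[ok, , drop = FALSE]^2))
    cand <- cand[order(cand$d), , drop = FALSE]
    usedP <- logical(nP); usedT <- logical(nT)
    for (i in seq_len(nrow(cand))) {
      if (usedP[cand$p[i]] || usedT[cand$t[i]]) next
      usedP[cand$p[i]] <- TRUE; usedT[cand$t[i]] <- TRUE
      pairs <- rbind(pairs, cand[i, ])
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  out <- list(nTruth = nT, nPred = nP, truePositives = tp,
              falsePositives = nP - tp, falseNegatives = nT - tp,
              precision = if (nP > 0) tp / nP else NA_real_,
              recall = if (nT > 0) tp / nT else NA_real_,
              positionRMSE = if (tp > 0) sqrt(mean(pairs$d^2)) else NA_real_)
  class(out) <- "MatchReport"
  out
}

#' @export
print.MatchReport <- function(x, ...) {
  cat(sprintf(
    "MatchReport: %d truth, %d predicted | TP %d FP %d FN %d | precision %.3f recall %.3f RMSE %.3f pts\n",
    x$nTruth, x$nPred, x$truePositives, x$falsePositives, x$falseNegatives,
    x$precision, x$recall, x$positionRMSE))
  invisible(x)
}
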