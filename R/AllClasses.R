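#' @import methods
#' @importFrom stats median optim rnorm runif sd setNames
#' @importFrom utils modifyList read.table write.table head tail
#' @useDynLib VoigtPicker, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' One-dimensional frequency-domain NMR spectrum
#'
#' Container for a phased, baseline-corrected absorption-mode 1D spectrum.
#' Intensities live on an integer grid (0-based internally); an optional
#' axis calibration maps grid points to ppm for reporting.
#'
#' @slot intensities Numeric vector of point intensities (length >= 2,
#'   all finite).
#' @slot axis Either an empty list (no calibration) or a list with elements
#'   \code{refPpm} (ppm of grid point 0), \code{ppmPerPoint} (negative for
#'   conventional NMR axes is allowed) and optionally \code{obsMHz}.
#' @exportClass NMRSpectrum1D
setClass("NMRSpectrum1D",
  representation(intensities = "numeric", axis = "list"),
  prototype(intensities = numeric(), axis = list()))

setValidity("NMRSpectrum1D", function(object) {
  if (length(object@intensities) < 2) return("need at least 2 data points")
  if (!all(is.finite(object@intensities))) return("intensities must be finite")
  ax <- object@axis
  if (length(ax) && !all(c("refPpm", "ppmPerPoint") %in% names(ax)))
    return("axis needs refPpm and ppmPerPoint")
  TRUE
})

#' Two-dimensional frequency-domain NMR spectrum
#'
#' Row index is the indirect dimension (omega-1), column index the direct
#' dimension (omega-2), so \code{intensities[r, c]} is the point at row
#' coordinate r, column coordinate c (both 0-based in grid units).
#'
#' @slot intensities Numeric matrix, both dimensions >= 2, finite.
#' @slot axes List with optional per-dimension calibrations \code{row} and
#'   \code{col}, each as in \linkS4class{NMRSpectrum1D}.
#' @exportClass NMRSpectrum2D
setClass("NMRSpectrum2D",
  representation(intensities = "matrix", axes = "list"),
  prototype(intensities = matrix(0, 2, 2), axes = list()))

setValidity("NMRSpectrum2D", function(object) {
  d <- dim(object@intensities)
  if (any(d < 2)) return("both dimensions must be >= 2")
  if (!all(is.finite(object@intensities))) return("intensities must be finite")
  TRUE
})

#' Set of picked or simulated peaks
#'
#' Thin S4 wrapper around a peak table.  For \code{kind = "1d"} the table
#' has columns \code{position, amplitude, fwhh, eta, class, confidence,
#' origin}; for \code{kind = "2d"} per-dimension columns
#' \code{posRow, posCol, fwhhRow, fwhhCol, etaRow, etaCol} plus
#' \code{amplitude, confidence, classRow, classCol, origin}.
#'
#' @slot peaks data.frame of peak parameters.
#' @slot kind "1d" or "2d".
#' @slot metadata Free-form list (noise estimate, config echo, ...).
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", kind = "character", metadata = "list"),
  prototype(peaks = data.frame(), kind = "1d", metadata = list()))

setValidity("PeakSet", function(object) {
  if (!object@kind %in% c("1d", "2d")) return("kind must be '1d' or '2d'")
  need <- if (object@kind == "1d") c("position", "amplitude", "fwhh", "eta")
          else c("posRow", "posCol", "fwhhRow", "fwhhCol", "amplitude")
  if (nrow(object@peaks) && !all(need %in% names(object@peaks)))
    return(paste("peak table must contain:", paste(need, collapse = ", ")))
  TRUE
})

#' Convolutional peak-picking network
#'
#' @slot arch Architecture description (depths, kernels, layer kinds,
#'   head channel counts); see \code{\link{archConfig}}.
#' @slot weights List of layer weight matrices plus classifier and
#'   regressor heads.
#' @slot trained Logical; TRUE after \code{\link{trainNetwork}}.
#' @slot history Training history (losses per epoch) or empty list.
#' @slot provenance Seeds and config hashes recorded at build/train time.
#' @exportClass PickerNet
setClass("PickerNet",
  representation(arch = "list", weights = "list", trained = "logical",
                 history = "list", provenance = "list"),
  prototype(trained = FALSE, history = list(), provenance = list()))

#' Synthetic training corpus
#'
#' @slot train List of training examples (see \code{\link{assembleExample}}).
#' @slot val List of validation examples.
#' @slot config The \code{\link{generatorConfig}} used.
#' @exportClass TrainingCorpus
setClass("TrainingCorpus",
  representation(train = "list", val = "list", config = "list"))

setMethod("show", "NMRSpectrum1D", function(object) {
  cat(sprintf("NMRSpectrum1D with %d points%s\n", length(object@intensities),
              if (length(object@axis)) " (ppm-calibrated)" else ""))
})

setMethod("show", "NMRSpectrum2D", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("NMRSpectrum2D %d x %d (rows = indirect, cols = direct)\n",
              d[1], d[2]))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet (%s) with %d peaks\n", object@kind, nrow(object@peaks)))
  if (nrow(object@peaks)) print(head(object@peaks, 10))
  if (nrow(object@peaks) > 10) cat("...\n")
})

setMethod("show", "PickerNet", function(object) {
  cat(sprintf("PickerNet: %d hidden layers, %d trainable parameters, %s\n",
              length(object@arch$depths), countParameters(object),
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "TrainingCorpus", function(object) {
  cat(sprintf("TrainingCorpus: %d training / %d validation examples of %d points\n",
              length(object@train), length(object@val),
              object@config$nPointsPerExample))
})

#' Accessors
#'
#' @param object,x A VoigtPicker S4 object.
#' @param ... Unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "NMRSpectrum1D", function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("intensities", "NMRSpectrum2D", function(object) object@intensities)

#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setMethod("peakTable", "PeakSet", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("as.data.frame", "PeakSet", function(x, ...) x@peaks)

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname accessors
#' @export
setMethod("nPeaks", "PeakSet", function(object) nrow(object@peaks))

#' @rdname accessors
#' @export
setGeneric("spectrumAxis", function(object) standardGeneric("spectrumAxis"))
#' @rdname accessors
#' @export
setMethod("spectrumAxis", "NMRSpectrum1D", function(object) object@axis)
#' @rdname accessors
#' @export
setMethod("spectrumAxis", "NMRSpectrum2D", function(object) object@axes)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "PickerNet", function(object) object@history)

#' Construct a 1D spectrum object
#'
#' @param intensities Numeric vector.
#' @param axis Optional axis calibration list.
#' @return An \linkS4class{NMRSpectrum1D}.
#' @export
nmrSpectrum1D <- function(intensities, axis = list()) {
  new("NMRSpectrum1D", intensities = as.numeric(intensities), axis = axis)
}

#' Construct a 2D spectrum object
#'
#' @param intensities Numeric matrix (rows = indirect dimension).
#' @param axes Optional per-dimension calibration list.
#' @return An \linkS4class{NMRSpectrum2D}.
#' @export
nmrSpectrum2D <- function(intensities, axes = list()) {
  new("NMRSpectrum2D", intensities = as.matrix(intensities), axes = axes)
}
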