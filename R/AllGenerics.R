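# Accessor generics, user-facing constructors and show methods.

#' Extract densities of a discrete PDF
#'
#' For a [PlanarPDF-class] the matrix is returned; treat a detection event as
#' a linear (column-major) index into it.
#'
#' @param x A [RadialPDF-class] or [PlanarPDF-class].
#' @return Numeric vector or matrix of densities summing to 1.
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @rdname densities
#' @export
setMethod("densities", "RadialPDF", function(x) x@densities)

#' @rdname densities
#' @export
setMethod("densities", "PlanarPDF", function(x) x@densities)

#' Extract hypothesis probabilities
#'
#' @param x A [ProbabilityVector-class] or [PosteriorTrace-class].
#' @return Named numeric vector (probability vector) or matrix with one row
#'   per processed detection, starting at the prior (trace).
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname probs
#' @export
setMethod("probs", "ProbabilityVector", function(x) {
  stats::setNames(x@probs, x@labels)
})

#' @rdname probs
#' @export
setMethod("probs", "PosteriorTrace", function(x) {
  p <- x@probs
  colnames(p) <- x@labels
  p
})

#' Hypothesis labels
#'
#' @param x A [ProbabilityVector-class] or [PosteriorTrace-class].
#' @return Character vector of hypothesis identifiers.
#' @export
setGeneric("hypLabels", function(x) standardGeneric("hypLabels"))

#' @rdname hypLabels
#' @export
setMethod("hypLabels", "ProbabilityVector", function(x) x@labels)

#' @rdname hypLabels
#' @export
setMethod("hypLabels", "PosteriorTrace", function(x) x@labels)

#' Extract grid values
#'
#' @param x An [IntensityImage-class], [DiffractionPattern-class],
#'   [RadialProfile-class] or [WaveField-class].
#' @return The underlying numeric (or complex, for waves) data.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "IntensityImage", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "DiffractionPattern", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "RadialProfile", function(x) x@totals)

#' @rdname values
#' @export
setMethod("values", "WaveField", function(x) x@amplitudes)

#' Reciprocal-space pitch
#'
#' @param x A pattern, profile or PDF carrying a `dq` calibration.
#' @return Reciprocal-space pitch per pixel/bin (1/length), possibly `NA`.
#' @export
setGeneric("reciprocalPitch", function(x) standardGeneric("reciprocalPitch"))

#' @rdname reciprocalPitch
#' @export
setMethod("reciprocalPitch", "DiffractionPattern", function(x) x@dq)

#' @rdname reciprocalPitch
#' @export
setMethod("reciprocalPitch", "RadialProfile", function(x) x@dq)

#' @rdname reciprocalPitch
#' @export
setMethod("reciprocalPitch", "RadialPDF", function(x) x@dq)

#' Atom table of a structure
#'
#' @param x An [AtomicStructure-class].
#' @return `data.frame` with columns `element`, `x`, `y`, `z` (Angstrom).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "AtomicStructure", function(x) x@atoms)

## ---- constructors -----------------------------------------------------------

#' Construct an intensity image
#'
#' @param values Nonnegative numeric matrix (row = y, col = x).
#' @param pixelPitch Length per pixel.
#' @return An [IntensityImage-class].
#' @export
IntensityImage <- function(values, pixelPitch = 1) {
  new("IntensityImage", values = as.matrix(values),
      pixelPitch = as.numeric(pixelPitch))
}

#' Construct a diffraction pattern
#'
#' @param values Numeric matrix of intensities.
#' @param center 1-based (row, col) of zero frequency; default the centered
#'   FFT convention `floor(N/2) + 1`.
#' @param dq Reciprocal-space pitch per pixel, `NA` if uncalibrated.
#' @return A [DiffractionPattern-class].
#' @export
DiffractionPattern <- function(values, center = NULL, dq = NA_real_) {
  values <- as.matrix(values)
  if (is.null(center))
    center <- c(gridCenter(nrow(values)), gridCenter(ncol(values)))
  new("DiffractionPattern", values = values, center = as.numeric(center),
      dq = as.numeric(dq))
}

#' Construct a radial profile
#'
#' @param totals Numeric vector, entry `k` for integer pixel radius `k`.
#' @param dq Reciprocal-space pitch per bin.
#' @return A [RadialProfile-class].
#' @export
RadialProfile <- function(totals, dq = NA_real_) {
  new("RadialProfile", totals = as.numeric(totals), dq = as.numeric(dq))
}

#' Construct an atomic structure
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param label Optional name.
#' @return An [AtomicStructure-class].
#' @export
AtomicStructure <- function(element, x, y, z, label = "") {
  new("AtomicStructure",
      atoms = data.frame(element = toupper(as.character(element)),
                         x = as.numeric(x), y = as.numeric(y),
                         z = as.numeric(z), stringsAsFactors = FALSE),
      label = as.character(label))
}

#' Construct a probability vector
#'
#' @param probs Probabilities (will not be renormalized).
#' @param labels Hypothesis identifiers; defaults to `H1..HM` or existing names.
#' @return A [ProbabilityVector-class].
#' @export
ProbabilityVector <- function(probs, labels = NULL) {
  if (is.null(labels))
    labels <- if (!is.null(names(probs))) names(probs)
              else paste0("H", seq_along(probs))
  new("ProbabilityVector", probs = as.numeric(probs),
      labels = as.character(labels))
}

#' Construct a noise model
#'
#' @param kind `"constant"` (sigma = S/snr per value) or `"qdependent"`
#'   (SNR(q) = 1/(c q), q in 1/Angstrom).
#' @param snr Constant signal-to-noise ratio.
#' @param coefficient Coefficient c of the q-dependent model (default 30).
#' @return A [NoiseModel-class].
#' @export
NoiseModel <- function(kind = c("constant", "qdependent"), snr = 2,
                       coefficient = 30) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, snr = as.numeric(snr),
      coefficient = as.numeric(coefficient))
}

## ---- show methods -----------------------------------------------------------

setMethod("show", "RadialPDF", function(object) {
  cat(sprintf("RadialPDF: %d bins, dq = %s\n", length(object@densities),
              format(object@dq)))
})

setMethod("show", "PlanarPDF", function(object) {
  cat(sprintf("PlanarPDF: %d x %d pixels, center (%g, %g)\n",
              nrow(object@densities), ncol(object@densities),
              object@center[1], object@center[2]))
})

setMethod("show", "ProbabilityVector", function(object) {
  cat(sprintf("ProbabilityVector over %d hypotheses\n", length(object@probs)))
  print(round(probs(object), 4))
})

setMethod("show", "PosteriorTrace", function(object) {
  n <- nrow(object@probs) - 1L
  cat(sprintf("PosteriorTrace: %d detections, %d hypotheses\n",
              n, ncol(object@probs)))
  cat("final: ")
  print(round(object@probs[nrow(object@probs), , drop = TRUE], 4))
})

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage: %d x %d, pixel pitch %g\n",
              nrow(object@values), ncol(object@values), object@pixelPitch))
})

setMethod("show", "DiffractionPattern", function(object) {
  cat(sprintf("DiffractionPattern: %d x %d, center (%g, %g), dq = %s\n",
              nrow(object@values), ncol(object@values),
              object@center[1], object@center[2], format(object@dq)))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: q = 1..%d px, dq = %s\n",
              length(object@totals), format(object@dq)))
})

setMethod("show", "AtomicStructure", function(object) {
  tab <- table(object@atoms$element)
  cat(sprintf("AtomicStructure%s: %d atoms (%s)\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              nrow(object@atoms),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = " ")))
})

setMethod("show", "WaveField", function(object) {
  cat(sprintf("WaveField: %d x %d, pitch %g A, lambda %g A, z = %g A\n",
              nrow(object@amplitudes), ncol(object@amplitudes),
              object@pixelPitch, object@wavelength, object@z))
})

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf(
    "DetectorGeometry: %d px, pitch %.4g A, distance %.4g A, lambda %g A\n",
    object@nPixels, object@pixelPitch, object@distance, object@wavelength))
})

setMethod("show", "NoiseModel", function(object) {
  if (object@kind == "constant")
    cat(sprintf("NoiseModel: constant SNR = %g\n", object@snr))
  else
    cat(sprintf("NoiseModel: SNR(q) = 1/(%g q)\n", object@coefficient))
})
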