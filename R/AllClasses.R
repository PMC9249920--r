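#' @import methods
NULL

TOL_SUM <- 1e-12

#' Discrete radial probability density function
#'
#' Normalized probability of detecting a scattered particle in each integer
#' radial bin of a diffraction pattern. Bin `k` covers pixel radius `k`;
#' physical momentum transfer is `k * dq` when the reciprocal-space pitch
#' `dq` is known.
#'
#' @slot densities Nonnegative numeric vector summing to 1.
#' @slot dq Reciprocal-space pitch per radial bin (1/length), or `NA`.
#' @export
setClass("RadialPDF", representation(densities = "numeric", dq = "numeric"))

setValidity("RadialPDF", function(object) {
  d <- object@densities
  if (length(d) < 1L) return("at least one bin required")
  if (any(!is.finite(d))) return("densities must be finite")
  if (any(d < 0)) return("densities must be nonnegative")
  if (abs(sum(d) - 1) > TOL_SUM) return("densities must sum to 1")
  TRUE
})

#' Two-dimensional detector-pixel probability density function
#'
#' Normalized probability of detection per detector pixel (q_x, q_y).
#'
#' @slot densities Nonnegative matrix summing to 1.
#' @slot center 1-based (row, col) of the zero-frequency pixel.
#' @slot dq Reciprocal-space pitch per pixel, or `NA`.
#' @export
setClass("PlanarPDF",
         representation(densities = "matrix", center = "numeric", dq = "numeric"))

setValidity("PlanarPDF", function(object) {
  d <- object@densities
  if (any(!is.finite(d))) return("densities must be finite")
  if (any(d < 0)) return("densities must be nonnegative")
  if (abs(sum(d) - 1) > TOL_SUM) return("densities must sum to 1")
  ctr <- object@center
  if (length(ctr) != 2L || any(ctr < 1) || ctr[1] > nrow(d) || ctr[2] > ncol(d))
    return("center must lie inside the grid")
  TRUE
})

# Virtual union: anything the Bayes machinery accepts as a likelihood model.
setClassUnion("DetectionPDF", c("RadialPDF", "PlanarPDF"))

#' Probabilities over a hypothesis set
#'
#' Prior or posterior probabilities for M structural hypotheses.
#'
#' @slot probs Numeric vector in \[0, 1\] summing to 1.
#' @slot labels Hypothesis identifiers (unique, same length as `probs`).
#' @export
setClass("ProbabilityVector",
         representation(probs = "numeric", labels = "character"))

setValidity("ProbabilityVector", function(object) {
  p <- object@probs
  if (length(p) < 1L) return("at least one hypothesis required")
  if (length(object@labels) != length(p)) return("labels/probs length mismatch")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > TOL_SUM) return("probabilities must sum to 1")
  TRUE
})

#' Posterior evolution over a detection stream
#'
#' Row `k + 1` holds the hypothesis probabilities after `k` detections; row 1
#' is the prior.
#'
#' @slot probs Numeric matrix, one row per state, one column per hypothesis.
#' @slot labels Hypothesis identifiers (column order).
#' @export
setClass("PosteriorTrace",
         representation(probs = "matrix", labels = "character"))

setValidity("PosteriorTrace", function(object) {
  p <- object@probs
  if (nrow(p) < 1L) return("trace must contain at least the prior")
  if (ncol(p) != length(object@labels)) return("labels/columns mismatch")
  if (any(!is.finite(p)) || any(p < 0)) return("probabilities must be nonnegative")
  if (any(abs(rowSums(p) - 1) > TOL_SUM)) return("every row must sum to 1")
  TRUE
})

#' Real-space intensity image (an object hypothesis)
#'
#' @slot values Nonnegative matrix (row = y, col = x).
#' @slot pixelPitch Length per pixel (arbitrary units or Angstrom).
#' @export
setClass("IntensityImage",
         representation(values = "matrix", pixelPitch = "numeric"))

setValidity("IntensityImage", function(object) {
  v <- object@values
  if (nrow(v) < 2L || ncol(v) < 2L) return("image must be at least 2 x 2")
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be nonnegative")
  if (object@pixelPitch <= 0) return("pixelPitch must be positive")
  TRUE
})

#' Far-field diffraction pattern
#'
#' @slot values Nonnegative matrix of intensities or counts.
#' @slot center 1-based (row, col) of zero spatial frequency.
#' @slot dq Reciprocal-space pitch per pixel (1/length), or `NA`.
#' @export
setClass("DiffractionPattern",
         representation(values = "matrix", center = "numeric", dq = "numeric"))

setValidity("DiffractionPattern", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("values must be finite")
  ctr <- object@center
  if (length(ctr) != 2L || any(ctr < 1) || ctr[1] > nrow(v) || ctr[2] > ncol(v))
    return("center must lie inside the grid")
  TRUE
})

#' Azimuthally-averaged radial intensity profile
#'
#' `totals[k]` is the ring-weighted azimuthal sum of the pattern at integer
#' pixel radius `k`. Noise may make entries negative; they are clipped when
#' the profile is normalized into a [RadialPDF-class].
#'
#' @slot totals Numeric vector, one entry per integer radius 1..q_max.
#' @slot dq Reciprocal-space pitch per radial bin, or `NA`.
#' @export
setClass("RadialProfile", representation(totals = "numeric", dq = "numeric"))

setValidity("RadialProfile", function(object) {
  if (length(object@totals) < 1L) return("profile must have at least one bin")
  if (any(!is.finite(object@totals))) return("totals must be finite")
  TRUE
})

#' Atomic structure
#'
#' @slot atoms `data.frame` with columns `element`, `x`, `y`, `z` (Angstrom).
#' @slot label Optional structure name.
#' @export
setClass("AtomicStructure",
         representation(atoms = "data.frame", label = "character"))

setValidity("AtomicStructure", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(a))) return("atoms needs element, x, y, z columns")
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  TRUE
})

#' Complex scalar wave on a square grid
#'
#' Carrier of the multi-slice electron wave state.
#'
#' @slot amplitudes Complex matrix.
#' @slot pixelPitch Sampling pitch (Angstrom).
#' @slot wavelength Wavelength (Angstrom).
#' @slot z Axial position of the plane (Angstrom).
#' @export
setClass("WaveField",
         representation(amplitudes = "matrix", pixelPitch = "numeric",
                        wavelength = "numeric", z = "numeric"))

setValidity("WaveField", function(object) {
  a <- object@amplitudes
  if (nrow(a) < 2L || ncol(a) < 2L) return("wave grid must be at least 2 x 2")
  if (!is.complex(a)) return("amplitudes must be complex")
  if (any(!is.finite(Re(a))) || any(!is.finite(Im(a))))
    return("amplitudes must be finite")
  if (object@pixelPitch <= 0 || object@wavelength <= 0)
    return("pixelPitch and wavelength must be positive")
  TRUE
})

#' Detector geometry for X-ray scattering
#'
#' @slot nPixels Pixels per detector side.
#' @slot pixelPitch Detector pixel size (Angstrom).
#' @slot distance Sample-to-detector distance (Angstrom).
#' @slot wavelength Radiation wavelength (Angstrom).
#' @export
setClass("DetectorGeometry",
         representation(nPixels = "integer", pixelPitch = "numeric",
                        distance = "numeric", wavelength = "numeric"))

setValidity("DetectorGeometry", function(object) {
  if (object@nPixels < 2L) return("nPixels must be >= 2")
  if (object@pixelPitch <= 0 || object@distance <= 0 || object@wavelength <= 0)
    return("pixelPitch, distance and wavelength must be positive")
  TRUE
})

#' Gaussian noise model
#'
#' Either a constant signal-to-noise ratio (per-value sigma = S/snr) or the
#' q-dependent electron recipe SNR(q) = 1/(c q) with q in 1/Angstrom.
#'
#' @slot kind `"constant"` or `"qdependent"`.
#' @slot snr Constant SNR (constant kind).
#' @slot coefficient Coefficient c of SNR(q) = 1/(c q) (q-dependent kind).
#' @export
setClass("NoiseModel",
         representation(kind = "character", snr = "numeric",
                        coefficient = "numeric"))

setValidity("NoiseModel", function(object) {
  if (!object@kind %in% c("constant", "qdependent"))
    return("kind must be 'constant' or 'qdependent'")
  if (object@kind == "constant" && !(is.finite(object@snr) && object@snr > 0))
    return("constant kind requires snr > 0")
  if (object@kind == "qdependent" &&
      !(is.finite(object@coefficient) && object@coefficient > 0))
    return("q-dependent kind requires coefficient > 0")
  TRUE
})
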