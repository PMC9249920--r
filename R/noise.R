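# Gaussian noise recipes (constant SNR and q-dependent SNR) and seeded
# Monte-Carlo sampling of particle detections from discrete PDFs.

#' Add Gaussian noise at constant signal-to-noise ratio
#'
#' Each value S is replaced by `S + g` with `g ~ Normal(0, S/snr)`, drawn
#' independently per value. Zero-signal entries keep sigma = 0 and stay
#' exactly zero. The result may contain negative values; normalize through
#' [radialPdf()], which clips.
#'
#' @param values Nonnegative numeric vector/matrix, or a
#'   [RadialProfile-class].
#' @param snr Signal-to-noise ratio, `> 0`.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Same shape/class as the input, with noise added.
#' @export
addNoiseConstantSnr <- function(values, snr, seed = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop("snr must be a positive number", call. = FALSE)
  prof <- NULL
  if (is(values, "RadialProfile")) {
    prof <- values
    values <- values@totals
  }
  stopIfNotFinite(values, "values")
  if (any(values < 0)) stop("values must be nonnegative", call. = FALSE)
  noisy <- withSeed(seed, values + stats::rnorm(length(values)) * values / snr)
  if (is.matrix(values)) noisy <- matrix(noisy, nrow(values), ncol(values))
  if (!is.null(prof)) RadialProfile(noisy, dq = prof@dq) else noisy
}

#' q-dependent signal-to-noise ratio
#'
#' The electron-diffraction noise model `SNR(q) = 1/(c q)` with q in
#' 1/Angstrom; the default coefficient c = 30 approximates reported
#' experimental noise levels (SNR = 0.33 at q = 0.1, 0.11 at q = 0.3).
#'
#' @param q Spatial frequency, 1/Angstrom, `> 0`.
#' @param coefficient Coefficient c (default 30).
#' @return SNR value(s).
#' @examples
#' snrAtQ(0.1)   # 0.333...
#' @export
snrAtQ <- function(q, coefficient = 30) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop("q must be positive (1/Angstrom)", call. = FALSE)
  if (coefficient <= 0) stop("coefficient must be positive", call. = FALSE)
  1 / (coefficient * q)
}

#' Add q-dependent Gaussian noise to a diffraction pattern
#'
#' Per pixel, noise with `sigma = S / SNR(q) = S * c * q` is added, with q
#' the pixel's physical spatial frequency from the pattern's center and
#' `dq` calibration. At the central pixel q = 0 and sigma is taken as 0
#' (the model leaves the DC pixel untouched).
#'
#' @param pattern A [DiffractionPattern-class] with a finite `dq`.
#' @param model A q-dependent [NoiseModel-class] (or a coefficient c).
#' @param seed Optional integer seed.
#' @return The noisy [DiffractionPattern-class] (values may go negative).
#' @export
addNoiseQDependent <- function(pattern, model = NoiseModel("qdependent"),
                               seed = NULL) {
  stopifnot(is(pattern, "DiffractionPattern"))
  if (is.numeric(model)) model <- NoiseModel("qdependent", coefficient = model)
  stopifnot(is(model, "NoiseModel"))
  if (model@kind != "qdependent")
    stop("model must be of the q-dependent kind", call. = FALSE)
  if (!is.finite(pattern@dq))
    stop("pattern has no dq calibration; q-dependent noise needs one",
         call. = FALSE)
  v <- pattern@values
  nr <- nrow(v); nc <- ncol(v)
  rows <- matrix(seq_len(nr), nr, nc) - pattern@center[1L]
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - pattern@center[2L]
  qmag <- sqrt(rows^2 + cols^2) * pattern@dq
  sigma <- v * model@coefficient * qmag      # = S / SNR(q); 0 at q = 0
  noisy <- withSeed(seed, v + stats::rnorm(length(v)) * as.numeric(sigma))
  DiffractionPattern(matrix(noisy, nr, nc), center = pattern@center,
                     dq = pattern@dq)
}

#' Sample particle detections from a discrete PDF
#'
#' Draws n independent detections by inverse-CDF lookup on the cumulative
#' bin probabilities: each uniform variate is mapped to the first bin whose
#' cumulative probability exceeds it.
#'
#' @param pdf A [RadialPDF-class] or [PlanarPDF-class].
#' @param n Number of detections, `>= 0`.
#' @param seed Optional integer seed.
#' @return Integer vector of detected bins (linear indices for planar
#'   PDFs), in arrival order.
#' @export
sampleDetections <- function(pdf, n, seed = NULL) {
  stopifnot(is(pdf, "RadialPDF") || is(pdf, "PlanarPDF"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0)
    stop("n must be a nonnegative count", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  d <- as.numeric(densities(pdf))
  cdf <- cumsum(d)
  cdf[length(cdf)] <- 1  # guard the last edge against rounding
  u <- withSeed(seed, stats::runif(n))
  findInterval(u, cdf, left.open = TRUE) + 1L
}
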