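# Shift-invariant Fraunhofer diffraction of 2D objects and reduction of 2D
# patterns to rotation-invariant 1D radial profiles.

#' Fraunhofer diffraction pattern of an intensity image
#'
#' The far-field pattern is the centered squared modulus of the 2D discrete
#' Fourier transform of the object distribution. Because a lateral shift of
#' the object only adds a phase to its transform, the pattern is independent
#' of object position. The unnormalized DFT is used, so the pattern total
#' equals `N^2 * sum(image^2)` (Parseval).
#'
#' @param image An [IntensityImage-class] or nonnegative numeric matrix.
#' @param pixelPitch Pixel pitch when `image` is a bare matrix.
#' @return A [DiffractionPattern-class] with `dq = 1/(N * pixelPitch)` and
#'   zero frequency at `floor(N/2) + 1` (1-based).
#' @export
fraunhofer <- function(image, pixelPitch = 1) {
  if (is(image, "IntensityImage")) {
    pixelPitch <- image@pixelPitch
    image <- image@values
  }
  image <- as.matrix(image)
  stopIfNotFinite(image, "image")
  ft <- stats::fft(image)
  vals <- fftshift2(Mod(ft)^2)
  DiffractionPattern(vals, dq = 1 / (nrow(image) * pixelPitch))
}

#' Rotate a diffraction pattern about its center
#'
#' Bilinear-interpolated in-plane rotation; samples falling outside the grid
#' are set to 0. Used to exercise the rotation invariance of radial PDFs (an
#' in-plane object rotation rotates its diffraction pattern by the same
#' angle).
#'
#' @param pattern A [DiffractionPattern-class].
#' @param angle Rotation angle in radians (counter-clockwise in (x, y) with
#'   row = y).
#' @return The rotated [DiffractionPattern-class] (same center, same `dq`).
#' @export
rotatePattern <- function(pattern, angle) {
  stopifnot(is(pattern, "DiffractionPattern"))
  if (!is.finite(angle)) stop("angle must be finite", call. = FALSE)
  v <- pattern@values
  nr <- nrow(v); nc <- ncol(v)
  ctr <- pattern@center
  # rotate sampling grid by -angle around the center (inverse mapping)
  rows <- matrix(seq_len(nr), nr, nc) - ctr[1L]
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[2L]
  ca <- cos(angle); sa <- sin(angle)
  srow <- ca * rows - sa * cols + ctr[1L]
  scol <- sa * rows + ca * cols + ctr[2L]
  out <- matrix(bilinearSample(v, as.numeric(srow), as.numeric(scol)), nr, nc)
  DiffractionPattern(out, center = ctr, dq = pattern@dq)
}

#' Azimuthally average a diffraction pattern
#'
#' For each integer pixel radius q the pattern is sampled by bilinear
#' interpolation at N = 2*pi/dtheta points around the ring and summed with
#' the ring weight 2*pi*q/N, giving the total intensity landing at radius q.
#' The DC pixel (q = 0) carries zero ring weight and is excluded; rings are
#' kept up to the largest radius fully contained in the grid.
#'
#' @param pattern A [DiffractionPattern-class].
#' @param dtheta Azimuthal step in radians, or `NULL` (default) for an arc
#'   step of at most one pixel on the outermost ring (`1/q_max`).
#' @return A [RadialProfile-class] with entries for q = 1..q_max.
#' @export
azimuthalAverage <- function(pattern, dtheta = NULL) {
  stopifnot(is(pattern, "DiffractionPattern"))
  v <- pattern@values
  ctr <- pattern@center
  qmax <- floor(min(ctr[1L] - 1, nrow(v) - ctr[1L],
                    ctr[2L] - 1, ncol(v) - ctr[2L]))
  if (qmax < 1L)
    stop("pattern too small: no fully contained ring", call. = FALSE)
  if (is.null(dtheta)) dtheta <- 1 / qmax
  if (!is.finite(dtheta) || dtheta <= 0 || dtheta > pi)
    stop("dtheta must lie in (0, pi]", call. = FALSE)
  nSteps <- max(4L, as.integer(round(2 * pi / dtheta)))
  theta <- (seq_len(nSteps) - 1L) * (2 * pi / nSteps)
  ct <- cos(theta); st <- sin(theta)
  totals <- numeric(qmax)
  for (q in seq_len(qmax)) {
    s <- bilinearSample(v, ctr[1L] + q * st, ctr[2L] + q * ct)
    totals[q] <- (2 * pi * q / nSteps) * sum(s)
  }
  RadialProfile(totals, dq = pattern@dq)
}

#' Radial PDF from a radial profile
#'
#' Negative entries (possible after noise addition) are clipped to zero, then
#' the profile is normalized to a discrete probability density over radial
#' bins.
#'
#' @param profile A [RadialProfile-class] or numeric vector.
#' @param dq Reciprocal-space pitch override.
#' @return A [RadialPDF-class].
#' @examples
#' densities(radialPdf(c(2, -1, 3)))   # 0.4 0.0 0.6
#' @export
radialPdf <- function(profile, dq = NA_real_) {
  if (is(profile, "RadialProfile")) {
    if (is.na(dq)) dq <- profile@dq
    profile <- profile@totals
  }
  profile <- pmax(as.numeric(profile), 0)
  if (sum(profile) <= 0)
    stop("normalization impossible: no positive totals", call. = FALSE)
  normalizePdf(profile, dq = dq)
}
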