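# Coherent X-ray scattering from an atomic structure: Cromer-Mann atomic
# form factors and the far-field detector intensity from a spherical-wave
# sum over atoms.

# Cromer-Mann 4-Gaussian + constant parameters (International Tables for
# Crystallography vol. C) for the elements of biological macromolecules.
# f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c, q = |k_f - k_i| in 1/Angstrom.
CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305, Z = 1),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600, Z = 6),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290, Z = 7),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800, Z = 8),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490, Z = 15),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900, Z = 16)
)

formFactorEntry <- function(element, table = NULL) {
  element <- toupper(element)
  tab <- CROMER_MANN
  if (!is.null(table)) tab[names(table)] <- table
  entry <- tab[[element]]
  if (is.null(entry))
    stop("no form-factor parameters for element '", element,
         "'; supported: ", paste(names(tab), collapse = ", "), call. = FALSE)
  entry
}

#' Atomic X-ray form factor
#'
#' Evaluates the Cromer-Mann parameterization
#' `f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c` (four Gaussians plus a
#' constant), with q the scattering-vector magnitude in 1/Angstrom. At q = 0
#' the form factor equals the number of electrons of the atom to within the
#' fit accuracy.
#'
#' @param element Chemical symbol; H, C, N, O, P and S are built in.
#' @param q Scattering-vector magnitude(s), 1/Angstrom, `>= 0`.
#' @param table Optional named list of additional/overriding parameter sets,
#'   each `list(a = ..., b = ..., c = ..., Z = ...)`.
#' @return Form factor in electrons, vectorized over `q`.
#' @examples
#' formFactor("C", 0)   # ~ 6
#' @export
formFactor <- function(element, q, table = NULL) {
  entry <- formFactorEntry(element, table)
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0))
    stop("q must be finite and nonnegative", call. = FALSE)
  s2 <- (q / (4 * pi))^2
  f <- rep(entry$c, length(q))
  for (i in seq_along(entry$a))
    f <- f + entry$a[i] * exp(-entry$b[i] * s2)
  f
}

#' Detector geometry for far-field X-ray scattering
#'
#' When `pixelPitch` is omitted it is chosen so that the detector rim (half
#' the detector side away from the axis) corresponds to the requested
#' resolution `d = 2*pi/q_rim`; the default, 2.2 Angstrom at the rim of a
#' 1024-pixel detector with 1 Angstrom photons, reproduces the benchmark
#' single-molecule imaging geometry.
#'
#' @param nPixels Pixels per detector side (default 1024).
#' @param wavelength Photon wavelength in Angstrom (default 1).
#' @param distance Sample-detector distance in Angstrom (default 5e8, i.e.
#'   5 cm).
#' @param pixelPitch Detector pixel size in Angstrom; computed from
#'   `resolutionAtRim` when `NULL`.
#' @param resolutionAtRim Real-space resolution at the detector rim in
#'   Angstrom (default 2.2).
#' @return A [DetectorGeometry-class].
#' @export
detectorGeometry <- function(nPixels = 1024L, wavelength = 1,
                             distance = 5e8, pixelPitch = NULL,
                             resolutionAtRim = 2.2) {
  nPixels <- as.integer(nPixels)
  if (is.null(pixelPitch)) {
    qRim <- 2 * pi / resolutionAtRim
    k <- 2 * pi / wavelength
    ratio <- qRim / (2 * k)
    if (ratio >= 1)
      stop("requested rim resolution unreachable at this wavelength",
           call. = FALSE)
    theta <- 2 * asin(ratio)
    pixelPitch <- distance * tan(theta) / (nPixels / 2)
  }
  new("DetectorGeometry", nPixels = nPixels,
      pixelPitch = as.numeric(pixelPitch), distance = as.numeric(distance),
      wavelength = as.numeric(wavelength))
}

#' Far-field X-ray diffraction pattern of an atomic structure
#'
#' Coherently sums the spherical waves scattered off the individual atoms:
#' each atom contributes `f(q) * exp(ik z) * exp(ik|R - r|)/|R - r|` at
#' detector coordinate R, with the incident beam along +z and q the
#' magnitude of the momentum transfer `k_f - k_i` for that atom/pixel pair.
#' The recorded intensity is the squared modulus of the sum. Phases are
#' computed through the path-difference form `|R - r| - (Z - z)` so that the
#' astronomically large common path drops out before any trigonometry,
#' keeping double precision meaningful.
#'
#' @param structure An [AtomicStructure-class]; all elements must have form
#'   factors (see [formFactor()]).
#' @param geometry A [DetectorGeometry-class]; the detector distance must be
#'   much larger than the structure extent.
#' @param photons Optional total elastic photon count: when given, the
#'   pattern is rescaled so its values sum to `photons` (absolute
#'   cross-sections are out of scope; recognition uses the PDF shape plus a
#'   count budget).
#' @param table Optional form-factor table override, as in [formFactor()].
#' @return A [DiffractionPattern-class] with `dq` set to the mean radial
#'   q-increment per pixel near the axis (1/Angstrom).
#' @export
xrayPattern <- function(structure, geometry, photons = NULL, table = NULL) {
  stopifnot(is(structure, "AtomicStructure"), is(geometry, "DetectorGeometry"))
  at <- structure@atoms
  for (el in unique(at$element)) formFactorEntry(el, table)  # fail early
  n <- geometry@nPixels
  ctr <- gridCenter(n)
  px <- (seq_len(n) - ctr) * geometry@pixelPitch
  X <- matrix(px, n, n, byrow = TRUE)   # col = x
  Y <- matrix(px, n, n)                 # row = y
  Z <- geometry@distance
  k <- 2 * pi / geometry@wavelength
  if (max(abs(c(at$x, at$y, at$z))) > 0.01 * Z)
    stop("detector distance must greatly exceed the structure extent",
         call. = FALSE)
  acc <- matrix(0 + 0i, n, n)
  for (j in seq_len(nrow(at))) {
    dx <- X - at$x[j]; dy <- Y - at$y[j]; dz <- Z - at$z[j]
    rho2 <- dx * dx + dy * dy
    D <- sqrt(rho2 + dz * dz)
    if (min(D) <= 0) stop("atom coincides with the detector plane",
                          call. = FALSE)
    # relative phase k(z + |R - r|) - kZ = k(|R - r| - (Z - z)) = k * path,
    # computed exactly, without catastrophic cancellation:
    path <- rho2 / (D + dz)
    # q = |k_f - k_i|, k_f along (R - r)
    qmag <- k * sqrt(rho2 + (dz - D)^2) / D
    f <- formFactor(at$element[j], as.numeric(qmag), table)
    # global factor exp(ikZ) dropped (common to all atoms)
    acc <- acc + matrix(f, n, n) * exp(1i * k * path) / D
  }
  vals <- Mod(acc)^2
  if (!is.null(photons)) {
    stopifnot(photons >= 0)
    vals <- vals * (photons / sum(vals))
  }
  # radial q-calibration: q per pixel near the axis
  dqPix <- k * geometry@pixelPitch / Z
  DiffractionPattern(vals, center = c(ctr, ctr), dq = dqPix)
}
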