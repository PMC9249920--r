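# Atom-by-atom multi-slice simulation of a high-energy electron wave:
# relativistic interaction parameter, projected atomic potentials,
# angular-spectrum propagation between slices, and the far-field pattern.

# CODATA constants
.PLANCK   <- 6.62607015e-34   # J s
.EMASS    <- 9.1093837015e-31 # kg
.ECHARGE  <- 1.602176634e-19  # C
.CLIGHT   <- 2.99792458e8     # m/s
.KE2      <- 14.3996454784    # e^2/(4 pi eps0), V * Angstrom

#' Relativistic electron wavelength
#'
#' @param energy Accelerating energy in keV.
#' @return Wavelength in Angstrom.
#' @examples
#' electronWavelength(200)   # ~ 0.0251 A
#' @export
electronWavelength <- function(energy) {
  if (!is.numeric(energy) || any(energy <= 0))
    stop("energy must be positive (keV)", call. = FALSE)
  V <- energy * 1e3
  .PLANCK / sqrt(2 * .EMASS * .ECHARGE * V *
                   (1 + .ECHARGE * V / (2 * .EMASS * .CLIGHT^2))) * 1e10
}

#' Relativistic interaction parameter
#'
#' Converts projected electrostatic potential (V Angstrom) into electron
#' phase shift (rad): `sigma = (2 pi / (lambda V)) * (m0 c^2 + eV) /
#' (2 m0 c^2 + eV)` with `lambda` the relativistic electron wavelength.
#'
#' @param energy Accelerating energy in keV.
#' @return Interaction parameter in rad/(V Angstrom).
#' @examples
#' interactionParameter(200)   # ~ 7.29e-4
#' @export
interactionParameter <- function(energy) {
  if (!is.numeric(energy) || any(energy <= 0))
    stop("energy must be positive (keV)", call. = FALSE)
  V <- energy * 1e3
  mc2 <- .EMASS * .CLIGHT^2 / .ECHARGE   # 511 keV in volts
  (2 * pi / (electronWavelength(energy) * V)) * (mc2 + V) / (2 * mc2 + V)
}

#' Projected electrostatic potential of an atom
#'
#' Radially symmetric projected potential derived from the atom's
#' Cromer-Mann X-ray form factor through the Mott-Bethe formula, which gives
#' the closed form `v_z(r) = (e^2/4 pi eps0) * sum_i a_i E1(4 pi^2 r^2 /
#' b_i)` (E1 the exponential integral). The potential diverges
#' logarithmically at r = 0 and is clamped at `rMin` (default half a pixel).
#' A Debye-Waller-style smearing `bFactor` (Angstrom^2) yields the finite,
#' grid-stable variant `sum_i a_i [E1(4 pi^2 r^2/(b_i + B)) - E1(4 pi^2
#' r^2/B)]`.
#'
#' @param element Chemical symbol (see [formFactor()] for the built-in set).
#' @param r Radial distance(s) from the nucleus axis, Angstrom.
#' @param rMin Clamp radius regularizing r -> 0 (ignored when `bFactor > 0`).
#' @param bFactor Isotropic displacement smearing B in Angstrom^2 (default 0).
#' @param table Optional form-factor table override.
#' @return Projected potential in V Angstrom, vectorized over `r`.
#' @export
projectedPotential <- function(element, r, rMin = 0, bFactor = 0,
                               table = NULL) {
  entry <- formFactorEntry(element, table)
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r < 0))
    stop("r must be finite and nonnegative", call. = FALSE)
  out <- numeric(length(r))
  if (bFactor > 0) {
    rr <- pmax(r, 1e-4)
    for (i in seq_along(entry$a))
      out <- out + entry$a[i] *
        (pracma::expint_E1(4 * pi^2 * rr^2 / (entry$b[i] + bFactor)) -
           pracma::expint_E1(4 * pi^2 * rr^2 / bFactor))
  } else {
    rr <- pmax(r, max(rMin, 1e-6))
    for (i in seq_along(entry$a))
      out <- out + entry$a[i] * pracma::expint_E1(4 * pi^2 * rr^2 / entry$b[i])
  }
  .KE2 * out
}

#' Unit-amplitude plane wave
#'
#' @param n Grid size (pixels per side).
#' @param pixelPitch Sampling pitch, Angstrom.
#' @param energy Electron energy in keV (sets the wavelength), or supply
#'   `wavelength` directly.
#' @param wavelength Wavelength in Angstrom (overrides `energy`).
#' @param z Axial position, Angstrom.
#' @return A [WaveField-class] of unit amplitude.
#' @export
planeWave <- function(n, pixelPitch, energy = 200, wavelength = NULL,
                      z = 0) {
  if (is.null(wavelength)) wavelength <- electronWavelength(energy)
  new("WaveField",
      amplitudes = matrix(1 + 0i, n, n), pixelPitch = as.numeric(pixelPitch),
      wavelength = as.numeric(wavelength), z = as.numeric(z))
}

#' Angular-spectrum free-space propagation
#'
#' Multiplies the wave's spatial-frequency spectrum by
#' `exp(i 2 pi dz sqrt(1/lambda^2 - fx^2 - fy^2))`; evanescent components
#' (negative radicand) are set to zero.
#'
#' @param wave A [WaveField-class].
#' @param dz Propagation distance in Angstrom, `>= 0`.
#' @param bandwidthLimit If `TRUE`, zero all frequencies beyond 2/3 of
#'   Nyquist (anti-aliasing rule); off by default.
#' @return The propagated [WaveField-class] (z advanced by `dz`).
#' @export
angularSpectrumPropagate <- function(wave, dz, bandwidthLimit = FALSE) {
  stopifnot(is(wave, "WaveField"))
  if (!is.finite(dz) || dz < 0) stop("dz must be >= 0", call. = FALSE)
  if (dz == 0 && !bandwidthLimit) return(wave)
  a <- wave@amplitudes
  n1 <- nrow(a); n2 <- ncol(a)
  fx <- fftFreq(n2, wave@pixelPitch)
  fy <- fftFreq(n1, wave@pixelPitch)
  f2 <- outer(fy^2, fx^2, `+`)
  rad <- 1 / wave@wavelength^2 - f2
  H <- ifelse(rad > 0, exp(2i * pi * dz * sqrt(pmax(rad, 0))), 0 + 0i)
  if (bandwidthLimit) {
    fmax <- (2 / 3) * (1 / (2 * wave@pixelPitch))
    H[f2 > fmax^2] <- 0 + 0i
  }
  out <- stats::fft(stats::fft(a) * H, inverse = TRUE) / (n1 * n2)
  new("WaveField", amplitudes = out, pixelPitch = wave@pixelPitch,
      wavelength = wave@wavelength, z = wave@z + dz)
}

#' Multi-slice exit wave of an atomic structure
#'
#' Propagates a unit-amplitude plane wave through the structure atom by
#' atom: atoms are stably sorted by increasing z; each atom multiplies the
#' wave by its local transmission function `exp(i sigma v_z)` (a patch
#' evaluated at pixel centers around the atom's exact position), and the
#' wave is then propagated by the z-gap to the next atom with the angular
#' spectrum method. Atoms sharing a z-coordinate are applied consecutively
#' without propagation. The wave after the last atom is the exit wave.
#'
#' @param structure An [AtomicStructure-class]; all atoms must fit inside
#'   the grid.
#' @param energy Electron energy in keV (default 200).
#' @param n Grid size, pixels per side (default 1024).
#' @param pixelPitch Sampling pitch in Angstrom. The default 0.886 spreads
#'   the reference probed area of 8.23e5 Angstrom^2 over a 1024-pixel field.
#' @param patchRadius Transmission patch truncation radius, Angstrom
#'   (default 8: the projected potential is negligible beyond).
#' @param bFactor Optional potential smearing, see [projectedPotential()].
#' @param bandwidthLimit Apply the 2/3 anti-alias rule during propagation.
#' @param table Optional form-factor table override.
#' @return The exit [WaveField-class].
#' @export
multisliceExitWave <- function(structure, energy = 200, n = 1024L,
                               pixelPitch = 0.886, patchRadius = 8,
                               bFactor = 0, bandwidthLimit = FALSE,
                               table = NULL) {
  stopifnot(is(structure, "AtomicStructure"))
  at <- structure@atoms
  for (el in unique(at$element)) formFactorEntry(el, table)
  ord <- order(at$z)              # stable sort by increasing z
  at <- at[ord, , drop = FALSE]
  sigma <- interactionParameter(energy)
  wave <- planeWave(n, pixelPitch, energy = energy, z = at$z[1L])
  a <- wave@amplitudes
  ctr <- gridCenter(n)
  hw <- ceiling(patchRadius / pixelPitch)
  rMin <- pixelPitch / 2
  # pre-computed transmission patches are atom-position dependent (sub-pixel
  # offsets), so each atom gets its own patch
  for (j in seq_len(nrow(at))) {
    rowPos <- at$y[j] / pixelPitch + ctr
    colPos <- at$x[j] / pixelPitch + ctr
    ir <- round(rowPos); ic <- round(colPos)
    if (ir < 1 || ir > n || ic < 1 || ic > n)
      stop(sprintf("atom %d (%s) lies outside the wave grid",
                   ord[j], at$element[j]), call. = FALSE)
    rows <- max(1L, ir - hw):min(n, ir + hw)
    cols <- max(1L, ic - hw):min(n, ic + hw)
    dr <- (rows - rowPos) * pixelPitch
    dc <- (cols - colPos) * pixelPitch
    rr <- sqrt(outer(dr^2, dc^2, `+`))
    vz <- projectedPotential(at$element[j], as.numeric(rr), rMin = rMin,
                             bFactor = bFactor, table = table)
    a[rows, cols] <- a[rows, cols] *
      exp(1i * sigma * matrix(vz, length(rows), length(cols)))
    if (j < nrow(at)) {
      dz <- at$z[j + 1L] - at$z[j]
      if (dz > 0 || bandwidthLimit) {
        wave@amplitudes <- a
        wave <- angularSpectrumPropagate(wave, dz, bandwidthLimit)
        a <- wave@amplitudes
      }
    }
  }
  new("WaveField", amplitudes = a, pixelPitch = pixelPitch,
      wavelength = wave@wavelength, z = at$z[nrow(at)])
}

#' Far-field diffraction pattern of an exit wave
#'
#' The centered squared modulus of the 2D Fourier transform of the complex
#' exit wave.
#'
#' @param exit A [WaveField-class].
#' @param electrons Optional total count normalization, as `photons` in
#'   [xrayPattern()].
#' @return A [DiffractionPattern-class] with `dq = 1/(N * pixelPitch)` in
#'   1/Angstrom (spatial frequency).
#' @export
electronPattern <- function(exit, electrons = NULL) {
  stopifnot(is(exit, "WaveField"))
  vals <- fftshift2(Mod(stats::fft(exit@amplitudes))^2)
  if (!is.null(electrons)) {
    stopifnot(electrons >= 0)
    vals <- vals * (electrons / sum(vals))
  }
  DiffractionPattern(vals, dq = 1 / (nrow(vals) * exit@pixelPitch))
}
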