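---
title: "Methods: sequential Bayesian recognition from low-dose diffraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential Bayesian recognition from low-dose diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffrec)
```

## The model

A recognition experiment assumes M candidate structures are known in
advance. Each candidate's far-field diffraction pattern, normalized to unit
total, is the probability density of detecting a single scattered particle
at each detector position. Detections arrive one at a time; after a
detection in bin $p$, every hypothesis probability is multiplied by its
density at $p$ and the vector is renormalized. The posterior after $k$
detections therefore equals the normalized product of the prior and the $k$
per-event likelihoods — the sequential loop and the batch product are the
same estimator, which `diffrec` exploits by accumulating log-likelihood
sums (`sequentialRecognition()`): a 40 000-event stream would underflow in
linear space but is exact to machine precision in log space.

Two invariances motivate the representation:

* **Shift invariance.** A lateral object shift only adds a phase to the
  object's Fourier transform, so the diffraction pattern (squared modulus)
  is unchanged. Recognition on patterns never needs the object centered.
* **Rotation invariance.** An in-plane rotation rotates the pattern by the
  same angle. Azimuthally averaging the pattern into a 1D radial density
  removes this degree of freedom, at the price of discarding angular
  information.

The assumptions are those of kinematic, coherent, elastic scattering from a
static object: each probing particle interacts once, detections are
independent draws from a fixed density, and out-of-plane orientation is
part of the hypothesis (different 3D orientations are different
hypotheses).

### Decision statistic

`particlesToThreshold()` reports the number of detections at which the true
hypothesis *first* reaches the confidence threshold (default 0.95).
First-crossing is used rather than sustained-crossing; with a finite
hypothesis set the posterior is a supermartingale for the wrong hypotheses,
and empirically re-crossings are rare, but the choice matters for heavy
noise and is stated here once. The threshold 0.95 corresponds, for two
equally-probable hypotheses, to a cumulative log-likelihood ratio of
$\ln 19 \approx 2.94$; Wald's expected-sample-size approximation
$n \approx \ln 19 / K$, with $K$ the mean per-event log-likelihood ratio
under the sampling density, predicts ensemble medians well and is used as
an independent oracle in the test suite.

### Zero likelihoods

Densities are used exactly as given: a hypothesis with zero density at a
detected bin is eliminated permanently, and a detection impossible under
every live hypothesis raises an error naming the event. This is the
literal reading of the update rule. An optional floor `eps` can be added to
all likelihoods for noisy-hypothesis studies; it changes the statistics and
is off by default.

## Azimuthal reduction

`azimuthalAverage()` samples the pattern at $N = 2\pi/\Delta\vartheta$
equally-spaced angles on every integer pixel radius $q$ by bilinear
interpolation and sums with the ring weight $2\pi q/N$:

* **Step size.** Default $\Delta\vartheta = 1/q_{\max}$, i.e. an arc step of
  at most one pixel on the outermost ring — finer steps change profiles
  negligibly while costing linearly.
* **Interpolation.** Angular positions rarely coincide with pixel centers.
  Bilinear interpolation is used because the reduction is written as
  angular sampling; the alternative reading (binning whole pixels into
  integer-radius annuli) is retained as the independent oracle in the test
  suite, and the two agree to total-variation distance below 0.02 on
  detector-scale isotropic patterns. Their residual difference is the
  per-annulus pixel-count fluctuation, which shrinks with grid size.
* **DC pixel.** $q = 0$ carries zero ring weight and is excluded; profiles
  start at $q = 1$.
* **Truncation.** Rings are kept up to the largest radius fully inside the
  grid, so all kept rings are complete.
* **Units.** Radial bins are integer pixel radii. Physical calibration
  rides along as `dq` metadata: the Fraunhofer and electron patterns carry
  spatial frequency $1/(N \cdot \text{pitch})$ per pixel, the X-ray
  pattern carries the momentum-transfer increment $k \cdot
  \text{pitch}/Z$ per pixel (the convention of the form-factor argument).
  Recognition itself uses only relative radial positions.

## Noise models

Two Gaussian recipes (`addNoiseConstantSnr()`, `addNoiseQDependent()`):

* **Constant SNR.** Each value $S$ receives independent
  $\mathcal{N}(0, S/\mathrm{SNR})$ noise; zero signal stays exactly zero.
  SNR = 2 is the default study condition, a pessimistic value compared to
  reported single-particle-imaging noise levels.
* **q-dependent.** $\mathrm{SNR}(q) = 1/(cq)$ with $c = 30$ and $q$ in
  1/Å, so $\sigma = S \cdot c q$ per pixel. The model is undefined at
  $q = 0$; the DC pixel is left untouched ($\sigma = 0$), a documented
  choice.

Noise is applied to the *probed object's* profile only; the hypothesis
densities stay noise-free, mirroring the experimental situation where
hypotheses are simulated and the measurement is noisy. After noise,
negative values are clipped to zero before normalization
(`radialPdf()`) — a density must be nonnegative, and clipping is the
minimal correction. Detection sampling (`sampleDetections()`) is
inverse-CDF lookup on the cumulative bin probabilities.

Every stochastic function takes an integer `seed` and restores the
caller's RNG state; the single generator used package-wide is R's
Mersenne-Twister. Ensembles use `baseSeed + trial` for both the noise
realization and the detection stream of each trial, making every summary
bit-reproducible.

## X-ray simulator

`xrayPattern()` coherently sums, per detector pixel, the spherical waves
scattered by each atom: amplitude $f(q)/|\vec R - \vec r|$ and phase
$k(z + |\vec R - \vec r|)$, with $f(q)$ the Cromer–Mann form factor (four
Gaussians plus a constant; parameters embedded for H, C, N, O, P, S, and
extensible via a user table). Numerical choices:

* **Phase stability.** The common path $kZ$ is millions of radians; the
  phase is computed through the identity
  $z + |\vec R - \vec r| - Z = \rho^2 / (|\vec R - \vec r| + Z - z)$,
  which is exact and cancellation-free in double precision.
* **Geometry default.** 1024×1024 pixels and $\lambda = 1$ Å, with the
  pixel pitch chosen so the detector rim corresponds to 2.2 Å resolution
  (the classic single-molecule benchmark geometry); distance defaults to
  5 cm. All parameters are configurable, and recognition results depend
  only on the pattern shape, not on absolute scale.
* **Counts.** Patterns can be rescaled to a requested total elastic photon
  count; absolute cross sections are out of scope.
* **Limits.** Friedel symmetry holds at small scattering angles and is
  broken at larger ones by the Ewald-sphere curvature phase
  ($\sim \theta^2 k z$), which the tests demonstrate scaling down with
  angle. No Compton scattering, polarization factor, solvent, B-factors or
  lattices.

## Electron simulator

`multisliceExitWave()` implements per-atom slicing: atoms are stably
sorted by increasing $z$; each atom multiplies the wave by its local
transmission $\exp(i\sigma v_z)$ and the wave is propagated to the next
atom's plane by the angular-spectrum method
($\hat H = \exp(i 2\pi \Delta z \sqrt{1/\lambda^2 - f^2})$, evanescent
components zeroed). Atoms at equal $z$ are applied consecutively without
propagation — transmissions commute, so input order cannot matter.

* **Interaction parameter.** The relativistic closed form gives
  $\sigma(200\,\text{keV}) = 7.288 \times 10^{-4}$ rad/(V·Å).
* **Projected potential.** Rather than carrying a second parameter table,
  $v_z$ is derived from the embedded X-ray form factors through the
  Mott–Bethe formula, which yields the closed form
  $v_z(r) = \frac{e^2}{4\pi\varepsilon_0} \sum_i a_i E_1(4\pi^2 r^2/b_i)$
  with $E_1$ the exponential integral. Its plane integral,
  $\frac{e^2}{4\pi\varepsilon_0}\frac{\sum_i a_i b_i}{4\pi}$, is an
  analytic self-check used in the tests (grid refinement reproduces it
  within 2%).
* **Singularity.** The true potential diverges logarithmically at
  $r = 0$; it is clamped at half a pixel. Consequently any *pointwise*
  value at an atom center grows as the grid is refined — integral
  quantities converge, pointwise maxima do not, so reported "maximum
  phase" values are tied to the stated pitch. An optional
  Debye–Waller-style smearing `bFactor` (Å²) replaces the clamp with the
  finite, grid-stable form
  $\sum_i a_i [E_1(4\pi^2 r^2/(b_i+B)) - E_1(4\pi^2 r^2/B)]$ for users
  who need pitch-independent maps.
* **Patch truncation.** Each atom's transmission is applied on a local
  patch (default radius 8 Å, where the potential is negligible), keeping
  per-atom slicing linear in atom count.
* **Defaults.** 1024×1024 grid at 0.886 Å pitch — the reference probed
  area of $8.23 \times 10^5$ Å² spread over a 1024-pixel field — and
  200 keV. No bandwidth limiting by default (available as a flag); no
  inelastic or thermal-diffuse scattering, no lens aberrations.

## Synthetic fixtures

`generateGlyphs()` emulates a set of hand-written characters without
shipping any dataset: each glyph is a random open polyline (3–6 vertices),
augmented half the time by a closed loop, drawn at a random extent between
0.35 and 0.8 of the frame with a stroke half-width of 0.035 of the frame
(about a 2-pixel stroke at 28×28, the typical sampling of digit images).
Loops, stroke count and extent are what make real characters'
radial spectra differ; pairwise radial-PDF total-variation distance is
validated above 0.02, redrawing colliding glyphs. Geometry is generated in
resolution-independent coordinates and validated at a fixed 28-pixel
reference raster, so one seed defines the *same shapes* at any requested
size — the property behind the sampling-invariance experiment (28×28 vs
140×140 medians agreeing within a factor of 1.5).

What the generator does not emulate: stroke-width variation, curvature
continuity of pen strokes, and the class structure of a real digit set.
Passing the recognition tests therefore shows that the machinery
discriminates character-like spectra under the stated noise, not that any
particular OCR benchmark would reach the same particle counts — those
depend on the images, and only order-of-magnitude agreement with reported
digit results is asserted.

`generateStructure()` places atoms uniformly in a box with a 1 Å minimum
separation (rejection sampling) and composition-proportional element
counts — a desk-scale stand-in for a macromolecule wherever the real PDB
coordinates are not available.

## Ensemble reporting

`runEnsemble()` reruns the trial with fresh noise and detections per seed
and reports mean, median, 5th/95th percentiles and the fraction of trials
that never reached the threshold within the particle budget (default
100 × hypotheses × bins). The *median* over reached trials is the headline
"particles needed" statistic; published counts of this kind rarely state
their statistic, so both location measures are always reported. Posterior
evolution curves are available per trial (`runTrial(keepTrace = TRUE)`);
whether published curves are single trials or trial averages is usually
unstated, so both views are left to the user and neither is asserted.

At SNR = 2 with closely-spaced hypotheses a noise realization can pull the
probed density closer to a wrong hypothesis; such trials lock onto that
hypothesis and are counted as not-reached. This is a property of the
experiment, not of the estimator: the posterior correctly tracks the
density the detections were actually drawn from.

## Problem sizes used in the tests

The shipped suite runs entirely on synthetic data: 28–140 pixel images,
64–512 pixel patterns, 8–200 atom clouds, 50–200 trial ensembles with a
5000-particle budget, and $10^5$-draw sampling checks. These sizes were
chosen to exercise every code path at desk scale; the full-scale
macromolecule test (1024² grids, real PDB entries 253L/3J83) runs only when
those coordinate files have been downloaded into `inst/extdata/pdb/`,
since they are third-party data and cannot be redistributed here.

## Known limitations

* Recognition quality is bounded by the hypothesis set: the method ranks
  the given densities and cannot flag "none of the above".
* The radial reduction discards angular information; objects differing
  only in azimuthal structure at equal radial distribution are
  indistinguishable. In-plane rotation *estimation* (via banks of rotated
  2D patterns) is out of scope.
* The electron "maximum phase" is pitch-dependent under the divergent
  atomic potential (see above); compare such values only at matched pitch
  or with `bFactor` smearing.
* Gaussian noise is the only noise model; Poisson shot noise is a natural
  extension but is not the default and not implemented.
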