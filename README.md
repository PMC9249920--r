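# diffrec — low-dose diffraction recognition imaging

`diffrec` answers a simple question at the lowest possible radiation dose:
*which of M known structures am I looking at?* Instead of recording a full
high-resolution image — impossible for a single radiation-sensitive
macromolecule, which is destroyed long before enough scattering is
collected — the sample is probed with individual particles (photons or
electrons), each detected somewhere in the far field, and every detection
updates the probability of each structural hypothesis by Bayes' rule.
A few tens of particles are typically enough to exceed 95% confidence.

The package is aimed at people exploring recognition-based imaging:
single-particle X-ray/electron imaging at minimal dose, optical character
recognition from sparse detections, and conformational discrimination.

## The statistic at its core

Each hypothesis *i* is an intensity distribution *I_i*. Normalizing it
gives the probability of detecting a scattered particle in detector bin
*p*:

    P(p | I_i) = I_i(p) / Σ_p I_i(p)

Starting from equal priors *P_i = 1/M*, a particle detected in bin *p₁*
updates every hypothesis:

    P'_i = P_i · P(p₁ | I_i) / Σ_j P_j · P(p₁ | I_j)

and the posteriors become the priors for the next particle. Working on the
far-field diffraction pattern (the squared Fourier modulus of the object)
makes recognition independent of object shifts; collapsing the 2D pattern
to a 1D radial density by azimuthal averaging,

    I(q) = (2πq/N) Σ_{n=0}^{N−1} I₀(q, nΔϑ),   N = 2π/Δϑ,

adds in-plane rotation invariance. The number of particles needed until
the true hypothesis first reaches a 95% posterior is the headline result
of a recognition experiment.

Forward simulators generate the hypothesis patterns: Fraunhofer optics for
2D images, coherent summation of atomic scattered waves with Cromer–Mann
form factors for X-rays, and an atom-by-atom multi-slice simulation with
angular-spectrum propagation for electrons. Gaussian noise recipes
(constant SNR, or the q-dependent electron model SNR(q) = 1/(30q)) and
seeded Monte-Carlo detection sampling complete the experiment loop.

## Worked example

Ten synthetic character-like glyphs are the hypotheses; glyph G3 is probed
at SNR = 2:

```r
library(diffrec)

glyphs   <- generateGlyphs(M = 10, size = 28, seed = 11)
profiles <- lapply(glyphs@images, function(im) azimuthalAverage(fraunhofer(im)))
pdfs     <- lapply(profiles, radialPdf)
names(pdfs) <- names(profiles) <- glyphs@labels

noisy <- addNoiseConstantSnr(profiles[["G3"]], snr = 2, seed = 1)
runTrial(radialPdf(noisy), pdfs, "G3", seed = 1)
#> TrialResult: true = 'G3', n to 95% = 43 (seed 1)

runEnsemble(profiles[["G3"]], pdfs, "G3", snr = 2,
            nTrials = 200, baseSeed = 100, budget = 5000)
#> EnsembleResult: 200 trials, true = 'G3'
#>   median 82, mean 166.438, 5%-95% [31.05, 625.7], not reached 19.0%
```

In this single trial, 43 detected particles were enough for the correct
glyph to exceed 95% posterior probability; over 200 noise realizations the
median requirement is 82 particles, with 19% of trials failing to reach
the threshold inside the particle budget (at SNR = 2 a noise draw can pull
the probed density closer to a wrong hypothesis). Dose accounting converts
a particle count into particles per unit area:

```r
doseReport(nParticles = 100, probedArea = 30^2, elasticFraction = 0.1)
#> Dose: 100 particles over 900 A^2 -> elastic 0.1111 /A^2, total 1.111 /A^2 (elastic fraction 0.1)
```

A thin command-line front end wraps these functions
(`system.file("scripts", "diffrec.R", package = "diffrec")`) with
`simulate`, `recognize`, `experiment` and `fixtures` subcommands.

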