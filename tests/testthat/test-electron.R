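# Multi-slice electron scattering: interaction parameter, projected
# potentials, angular-spectrum propagation, exit waves and patterns.

test_that("interaction parameter follows the relativistic closed form", {
  # frozen from the closed form with CODATA constants
  expect_equal(interactionParameter(200), 7.2884e-4, tolerance = 1e-4)
  expect_equal(interactionParameter(100), 9.2440e-4, tolerance = 1e-4)
  expect_equal(electronWavelength(200), 0.025079, tolerance = 1e-4)
  sig <- interactionParameter(seq(60, 300, by = 20))
  expect_true(all(diff(sig) < 0))
  expect_error(interactionParameter(-1), "positive")
})

test_that("projected potential is radially symmetric and element-ordered", {
  r <- c(0.3, 0.5, 1, 2)
  expect_equal(projectedPotential("C", r), projectedPotential("C", r))
  # symmetry is inherent (function of r); check via a 2D patch
  x <- seq(-3, 3, by = 0.25)
  patch <- outer(x, x, function(a, b)
    projectedPotential("C", sqrt(a^2 + b^2), rMin = 0.125))
  expect_equal(patch, t(patch), tolerance = 1e-9)
  expect_gt(projectedPotential("C", 0.5), projectedPotential("H", 0.5))
  expect_error(projectedPotential("Q", 1), "supported")
})

test_that("projected-potential integral converges under grid refinement", {
  integral <- function(pitch) {
    n <- round(10 / pitch)
    x <- (seq_len(n) - n / 2 - 0.5) * pitch
    r <- sqrt(outer(x^2, x^2, `+`))
    sum(projectedPotential("C", as.numeric(r), rMin = pitch / 2)) * pitch^2
  }
  i1 <- integral(0.2); i2 <- integral(0.1)
  expect_lt(abs(i1 - i2) / i2, 0.02)
  # analytic plane integral of the Mott-Bethe form: ke2/(4 pi) * sum(a*b)
  cm <- diffrec:::CROMER_MANN$C
  expect_equal(i2, 14.3996 / (4 * pi) * sum(cm$a * cm$b), tolerance = 0.01)
})

test_that("angular-spectrum propagation: identity, plane waves, Gaussian beams", {
  pw <- planeWave(64, 0.5)
  expect_identical(values(angularSpectrumPropagate(pw, 0)), values(pw))
  prop <- angularSpectrumPropagate(pw, 137)
  expect_lt(max(abs(Mod(values(prop))^2 - 1)), 1e-10)
  # Gaussian beam expansion: w(z) = w0 sqrt(1 + (z/zR)^2)
  n <- 256L; pitch <- 1; w0 <- 8; lambda <- 0.05
  ctr <- floor(n / 2) + 1L
  x <- (seq_len(n) - ctr) * pitch
  amp <- exp(-outer(x^2, x^2, `+`) / w0^2)
  wave <- new("WaveField", amplitudes = amp + 0i, pixelPitch = pitch,
              wavelength = lambda, z = 0)
  zR <- pi * w0^2 / lambda
  dz <- 0.5 * zR
  out <- angularSpectrumPropagate(wave, dz)
  I <- Mod(values(out))^2
  # beam width from the intensity second moment: <x^2> = w^2/4
  wMeas <- 2 * sqrt(sum(I * x^2) / sum(I))
  wExpect <- w0 * sqrt(1 + (dz / zR)^2)
  expect_equal(wMeas, wExpect, tolerance = 0.01)
})

test_that("a single atom imprints exactly its transmission phase", {
  st <- AtomicStructure("C", 0, 0, 0)
  pitch <- 0.5
  ew <- multisliceExitWave(st, n = 64L, pixelPitch = pitch)
  expect_lt(max(abs(Mod(values(ew)) - 1)), 1e-12)   # unimodular
  ph <- Arg(values(ew))
  ctr <- 33L
  sigma <- interactionParameter(200)
  expect_equal(ph[ctr, ctr],
               sigma * projectedPotential("C", 0, rMin = pitch / 2),
               tolerance = 1e-9)
  expect_equal(ph[ctr, ctr + 2],
               sigma * projectedPotential("C", 2 * pitch, rMin = pitch / 2),
               tolerance = 1e-9)
})

test_that("exit waves are independent of input atom order", {
  st <- toyStructure(12, seed = 21, extent = 12)
  ref <- values(multisliceExitWave(st, n = 96L, pixelPitch = 0.4))
  a <- st@atoms
  set.seed(4)
  perm <- sample(nrow(a))
  shuffled <- AtomicStructure(a$element[perm], a$x[perm], a$y[perm],
                              a$z[perm])
  out <- values(multisliceExitWave(shuffled, n = 96L, pixelPitch = 0.4))
  expect_lt(max(Mod(ref - out)), 1e-10)
  # two atoms at identical z commute exactly
  za <- AtomicStructure(c("C", "O"), c(-1, 1), c(0, 0), c(0, 0))
  zb <- AtomicStructure(c("O", "C"), c(1, -1), c(0, 0), c(0, 0))
  expect_lt(max(Mod(values(multisliceExitWave(za, n = 64L, pixelPitch = 0.4)) -
                      values(multisliceExitWave(zb, n = 64L, pixelPitch = 0.4)))),
            1e-12)
  outside <- AtomicStructure("C", 1e4, 0, 0)
  expect_error(multisliceExitWave(outside, n = 64L, pixelPitch = 0.4),
               "outside")
})

test_that("electron patterns: plane wave, Parseval, weak-phase scattering", {
  pw <- planeWave(64, 0.5)
  pat <- values(electronPattern(pw))
  ctr <- 33L
  expect_equal(pat[ctr, ctr], 64^4)
  expect_lt(max(pat[-((ctr - 1) * 64 + ctr)]), 1e-12 * pat[ctr, ctr])
  # Parseval for a unimodular exit wave
  st <- toyStructure(8, seed = 9, extent = 8)
  ew <- multisliceExitWave(st, n = 64L, pixelPitch = 0.4)
  expect_equal(sum(values(electronPattern(ew))), 64^2 * sum(Mod(values(ew))^2),
               tolerance = 1e-8)
  # weak phase object: scattered fraction ~ var(phase)
  n <- 128L
  x <- seq_len(n) - 65
  phi <- 0.05 * exp(-outer(x^2, x^2, `+`) / 200)
  wv <- new("WaveField", amplitudes = exp(1i * phi), pixelPitch = 1,
            wavelength = 0.025, z = 0)
  pat2 <- values(electronPattern(wv))
  scattered <- 1 - pat2[65, 65] / sum(pat2)
  expect_equal(scattered, mean(phi^2) - mean(phi)^2, tolerance = 0.1)
  # count normalization
  expect_equal(sum(values(electronPattern(wv, electrons = 4e4))), 4e4)
})
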