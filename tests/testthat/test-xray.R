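# Cromer-Mann form factors and the coherent X-ray scattering sum.

test_that("form factors reach Z at q = 0 and decay monotonically", {
  expect_equal(formFactor("C", 0), 6, tolerance = 0.02)
  expect_equal(formFactor("H", 0), 1, tolerance = 0.05)
  for (el in c("H", "C", "N", "O", "P", "S")) {
    f <- formFactor(el, seq(0, 25, by = 0.1))
    expect_true(all(diff(f) <= 1e-12), label = paste(el, "monotone"))
    expect_true(all(f > 0))
  }
  expect_error(formFactor("XX", 1), "supported")
})

test_that("single- and two-atom patterns match closed forms", {
  geom <- detectorGeometry(nPixels = 64L, resolutionAtRim = 10)
  one <- xrayPattern(AtomicStructure("C", 0, 0, 0), geom)
  # envelope |f(q)|^2 / D^2 at each pixel
  n <- 64L; ctr <- 33L
  px <- (seq_len(n) - ctr) * geom@pixelPitch
  X <- matrix(px, n, n, byrow = TRUE); Y <- matrix(px, n, n)
  D <- sqrt(X^2 + Y^2 + geom@distance^2)
  k <- 2 * pi / geom@wavelength
  qmag <- k * sqrt(X^2 + Y^2 + (geom@distance - D)^2) / D
  envelope <- matrix(formFactor("C", as.numeric(qmag)), n, n)^2 / D^2
  expect_equal(values(one), envelope, tolerance = 1e-10)

  # two identical atoms d apart along x: fringe modulation cos^2(qx d / 2)
  d <- 10
  two <- xrayPattern(AtomicStructure(c("C", "C"), c(-d / 2, d / 2),
                                     c(0, 0), c(0, 0)), geom)
  central <- values(two)[ctr, ]
  qx <- k * px / geom@distance           # small-angle qx per column
  modulation <- central / (4 * envelope[ctr, ])
  # exact two-path interference: cos^2(k (D1 - D2) / 2) on the central row
  D1 <- sqrt((px - d / 2)^2 + geom@distance^2)
  D2 <- sqrt((px + d / 2)^2 + geom@distance^2)
  expect_lt(max(abs(modulation - cos(k * (D1 - D2) / 2)^2)), 1e-3)
  expect_lt(max(abs(modulation - cos(qx * d / 2)^2)), 1e-2)
  # fringe period in qx equals 2 pi / d: first minimum at qx = pi / d,
  # i.e. half a period from the axis, within one pixel
  dqx <- k * geom@pixelPitch / geom@distance
  halfPeriodPx <- pi / d / dqx
  minOffset <- which(diff(modulation[ctr:n]) > 0)[1L] - 1L
  expect_lte(abs(minOffset - halfPeriodPx), 1)
})

test_that("patterns obey Friedel symmetry, positivity and coherent scaling", {
  st <- toyStructure(10, seed = 5)
  # small scattering angles: Ewald curvature (the q_z z phase, ~ theta^2 k z)
  # is what limits Friedel symmetry, so keep the rim angle modest
  geom <- detectorGeometry(nPixels = 64L, resolutionAtRim = 40)
  pat <- values(xrayPattern(st, geom))
  expect_true(all(pat >= 0))
  ctr <- 33L
  idx <- 2:64
  flipped <- pat[rev(idx), rev(idx)]
  expect_lt(max(abs(pat[idx, idx] - flipped) / max(pat)), 0.01)
  # doubling all form factors quadruples every pixel
  tab <- lapply(diffrec:::CROMER_MANN, function(e)
    list(a = 2 * e$a, b = e$b, c = 2 * e$c, Z = e$Z))
  pat2 <- values(xrayPattern(st, geom, table = tab))
  expect_equal(pat2, 4 * pat, tolerance = 1e-10)
})

test_that("a compact cluster scatters coherently as n^2 on axis", {
  geom <- detectorGeometry(nPixels = 32L, resolutionAtRim = 20)
  ctr <- 17L
  one <- values(xrayPattern(AtomicStructure("C", 0, 0, 0), geom))[ctr, ctr]
  nAt <- 5L
  eps <- 0.02   # cluster extent << first fringe
  cl <- AtomicStructure(rep("C", nAt), seq_len(nAt) * eps,
                        rep(0, nAt), rep(0, nAt))
  many <- values(xrayPattern(cl, geom))[ctr, ctr]
  expect_equal(many / one, nAt^2, tolerance = 0.01)
})

test_that("radial PDF of a pattern is unchanged by in-plane shifts", {
  st <- toyStructure(10, seed = 5)
  geom <- detectorGeometry(nPixels = 96L, resolutionAtRim = 10)
  a <- st@atoms
  shifted <- AtomicStructure(a$element, a$x + 2, a$y - 1.5, a$z)
  p0 <- densities(radialPdf(azimuthalAverage(xrayPattern(st, geom))))
  p1 <- densities(radialPdf(azimuthalAverage(xrayPattern(shifted, geom))))
  expect_lt(tvDist(p0, p1), 0.01)
})

test_that("photon budget normalization and geometry guards work", {
  geom <- detectorGeometry(nPixels = 32L, resolutionAtRim = 20)
  pat <- xrayPattern(AtomicStructure("C", 0, 0, 0), geom, photons = 100)
  expect_equal(sum(values(pat)), 100)
  expect_error(detectorGeometry(wavelength = 1, resolutionAtRim = 0.4),
               "unreachable")
  far <- AtomicStructure("C", 0, 0, 0.5 * geom@distance)
  expect_error(xrayPattern(far, geom), "exceed")
})
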