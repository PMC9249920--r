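# Shared fixtures and independent oracles, all built in code.

tvDist <- function(p, q) 0.5 * sum(abs(p - q))

# isotropic Gaussian diffraction pattern exp(-q^2 / (2 sigma^2))
gaussianPattern <- function(n = 128L, sigma = 12) {
  ctr <- floor(n / 2) + 1L
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  DiffractionPattern(exp(-r2 / (2 * sigma^2)))
}

# Oracle for radial PDFs: exact pixel-membership annulus histogram of the
# normalized 2D pattern (bin k = pixels with radius in [k-1/2, k+1/2)).
annulusHistogramPdf <- function(pattern) {
  v <- values(pattern)
  ctr <- pattern@center
  n1 <- nrow(v); n2 <- ncol(v)
  r <- sqrt(outer((seq_len(n1) - ctr[1L])^2, (seq_len(n2) - ctr[2L])^2, `+`))
  qmax <- floor(min(ctr[1L] - 1, n1 - ctr[1L], ctr[2L] - 1, n2 - ctr[2L]))
  bin <- round(r)
  keep <- bin >= 1 & bin <= qmax
  tot <- vapply(seq_len(qmax), function(k) sum(v[keep & bin == k]),
                numeric(1L))
  tot / sum(tot)
}

# family of smooth strictly positive radial PDFs on nbins bins
smoothPdf <- function(center, nbins = 32L, width = 40, floorVal = 0.01) {
  radialPdf(exp(-((seq_len(nbins) - center)^2) / width) + floorVal)
}

# small random structure of protein elements
toyStructure <- function(n = 10L, seed = 5L, extent = 10) {
  generateStructure(n, composition = c(C = 5, N = 2, O = 2, H = 0, S = 1),
                    extent = extent, seed = seed)
}

# hypothesis PDFs + profiles for a glyph set
glyphHypotheses <- function(glyphs) {
  profiles <- lapply(glyphs@images, function(im)
    azimuthalAverage(fraunhofer(im)))
  pdfs <- lapply(profiles, radialPdf)
  names(pdfs) <- names(profiles) <- glyphs@labels
  list(profiles = profiles, pdfs = pdfs)
}
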