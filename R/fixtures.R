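# Synthetic fixtures: binary stroke glyphs (stand-ins for hand-written
# characters) and random atom clouds (desk-scale stand-ins for
# macromolecules). Pure functions of (parameters, seed).

#' A set of binary glyph hypothesis images
#'
#' @slot images List of binary [IntensityImage-class] objects, equal size.
#' @slot labels Glyph identifiers.
#' @slot seed Generator seed.
#' @export
setClass("GlyphSet",
         representation(images = "list", labels = "character",
                        seed = "numeric"))

setMethod("show", "GlyphSet", function(object) {
  sz <- nrow(object@images[[1L]]@values)
  cat(sprintf("GlyphSet: %d glyphs, %d x %d px (seed %g)\n",
              length(object@images), sz, sz, object@seed))
})

# Rasterize a polyline (vertices in the unit square) onto a size x size
# binary grid, with stroke half-width `thickness` (fraction of the image
# side). Resolution-independent: the same geometry rasterized at two sizes
# yields the same shape.
rasterizeStroke <- function(pts, size, thickness = 0.035) {
  img <- matrix(0, size, size)
  halfw <- thickness * size
  xs <- pts[, 1L] * size + 0.5
  ys <- pts[, 2L] * size + 0.5
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  rows <- matrix(seq_len(size), size, size)
  for (i in seq_len(nrow(pts) - 1L)) {
    ax <- xs[i]; ay <- ys[i]; bx <- xs[i + 1L]; by <- ys[i + 1L]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((cols - ax) * vx + (rows - ay) * vy) / len2))
         else 0
    d2 <- (cols - (ax + t * vx))^2 + (rows - (ay + t * vy))^2
    img[d2 <= halfw^2] <- 1
  }
  img
}

# One glyph = an open polyline (3-6 vertices) plus, half the time, a closed
# loop, inside a random extent box -- emulating the variety of hand-written
# characters (stroke count, loops, size) without reproducing any dataset.
glyphGeometry <- function(M, seed) {
  withSeed(seed, lapply(seq_len(M), function(i) {
    ext <- stats::runif(1L, 0.35, 0.8)
    c0 <- 0.5 - ext / 2
    k <- sample(3:6, 1L)
    pts <- cbind(stats::runif(k, c0, c0 + ext), stats::runif(k, c0, c0 + ext))
    circ <- if (stats::runif(1L) < 0.5) {
      cc <- stats::runif(2L, c0 + 0.1 * ext, c0 + 0.9 * ext)
      rr <- stats::runif(1L, 0.15, 0.45) * ext
      th <- seq(0, 2 * pi, length.out = 40L)
      cbind(cc[1L] + rr * cos(th), cc[2L] + rr * sin(th))
    } else NULL
    list(pts = pts, circ = circ)
  }))
}

rasterizeGlyph <- function(geom, size, thickness) {
  img <- rasterizeStroke(geom$pts, size, thickness)
  if (!is.null(geom$circ))
    img <- pmax(img, rasterizeStroke(geom$circ, size, thickness))
  img
}

glyphRadialPdf <- function(img) {
  radialPdf(azimuthalAverage(fraunhofer(img)))
}

tvDistance <- function(p, q) 0.5 * sum(abs(p - q))

#' Generate a set of distinct binary glyphs
#'
#' M random character-like shapes (rasterized polylines, half of them with a
#' closed loop, at varying extents) on a `size x size`
#' grid, validated so that every pair of glyphs has radial-PDF
#' total-variation distance above `minDistance`; colliding glyphs are
#' redrawn up to a retry cap. Validation runs at a fixed 28-pixel reference
#' raster, so the same seed produces the same shapes at any requested
#' `size` (the shapes, not the pixels, are the hypotheses).
#'
#' @param M Number of glyphs, `>= 2` (default 10).
#' @param size Image side in pixels, `>= 8` (default 28).
#' @param seed Integer seed (default 1).
#' @param thickness Stroke half-width as a fraction of the side.
#' @param minDistance Minimum pairwise radial-PDF total-variation distance.
#' @param maxRetry Redraw cap per glyph.
#' @return A [GlyphSet-class].
#' @export
generateGlyphs <- function(M = 10L, size = 28L, seed = 1L,
                           thickness = 0.035, minDistance = 0.02,
                           maxRetry = 50L) {
  M <- as.integer(M); size <- as.integer(size)
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (size < 8L) stop("size must be >= 8", call. = FALSE)
  refSize <- 28L
  geoms <- glyphGeometry(M, seed)
  refPdfs <- vector("list", M)
  accept <- function(i) {
    refPdfs[[i]] <<- glyphRadialPdf(rasterizeGlyph(geoms[[i]], refSize,
                                                   thickness))
  }
  for (i in seq_len(M)) accept(i)
  # redraw any glyph too close (in radial-PDF distance) to an earlier one
  for (i in seq_len(M)) {
    tries <- 0L
    while (i > 1L && any(vapply(seq_len(i - 1L), function(j)
      tvDistance(refPdfs[[i]]@densities, refPdfs[[j]]@densities),
      numeric(1L)) <= minDistance)) {
      tries <- tries + 1L
      if (tries > maxRetry)
        stop("could not generate ", M, " distinct glyphs; try a larger size",
             call. = FALSE)
      geoms[[i]] <- glyphGeometry(1L, seed + 1000L * i + tries)[[1L]]
      accept(i)
    }
  }
  images <- lapply(geoms, function(g)
    IntensityImage(rasterizeGlyph(g, size, thickness)))
  new("GlyphSet", images = images, labels = paste0("G", seq_len(M)),
      seed = as.numeric(seed))
}

#' Generate a random synthetic atom cloud
#'
#' Uniform random positions inside a cubic box with a minimum pairwise
#' separation enforced by rejection sampling; element counts follow the
#' composition proportions (largest-remainder rounding). A desk-scale
#' stand-in for a macromolecular structure.
#'
#' @param nAtoms Number of atoms, `>= 1`.
#' @param composition Named numeric vector of element proportions, e.g.
#'   `c(C = 6, N = 2, O = 2)`.
#' @param extent Box side length in Angstrom (box centered on the origin).
#' @param seed Integer seed (default 1).
#' @param minSeparation Minimum pair distance in Angstrom (default 1).
#' @param maxRetry Placement attempts per atom.
#' @return An [AtomicStructure-class] labelled `"synthetic"`.
#' @export
generateStructure <- function(nAtoms, composition = c(C = 6, N = 2, O = 2),
                              extent = 30, seed = 1L, minSeparation = 1,
                              maxRetry = 200L) {
  nAtoms <- as.integer(nAtoms)
  if (nAtoms < 1L) stop("nAtoms must be >= 1", call. = FALSE)
  if (is.null(names(composition)) || any(composition < 0) ||
      sum(composition) <= 0)
    stop("composition must be a named nonnegative vector", call. = FALSE)
  prop <- composition / sum(composition)
  counts <- floor(nAtoms * prop)
  rem <- nAtoms - sum(counts)
  if (rem > 0) {
    frac <- nAtoms * prop - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  elements <- rep(names(composition), times = counts)
  pos <- withSeed(seed, {
    p <- matrix(NA_real_, nAtoms, 3L)
    for (i in seq_len(nAtoms)) {
      placed <- FALSE
      for (try in seq_len(maxRetry)) {
        cand <- stats::runif(3L, -extent / 2, extent / 2)
        if (i == 1L || min(sqrt(colSums((t(p[seq_len(i - 1L), , drop = FALSE]) -
                                           cand)^2))) >= minSeparation) {
          p[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("packing infeasible: ", nAtoms, " atoms at separation ",
             minSeparation, " A do not fit in a ", extent, " A box",
             call. = FALSE)
    }
    p
  })
  AtomicStructure(elements, pos[, 1L], pos[, 2L], pos[, 3L],
                  label = "synthetic")
}
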