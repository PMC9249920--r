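# Internal numerical helpers shared across modules.

#' Run an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not disturb the global random stream. `seed = NULL` uses the current stream.
#' Mersenne-Twister (R's default) is the single RNG used package-wide.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Centered-origin shift of a matrix (quadrant swap), so that the zero
# spatial frequency of an FFT lands at (floor(N/2)+1, floor(N/2)+1) in
# R's 1-based indexing -- i.e. (N/2, N/2) 0-based for even N.
fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq_len(d[1L])[-seq_len(ceiling(d[1L] / 2))], seq_len(ceiling(d[1L] / 2)))
  j <- c(seq_len(d[2L])[-seq_len(ceiling(d[2L] / 2))], seq_len(ceiling(d[2L] / 2)))
  m[i, j, drop = FALSE]
}

# FFT sample frequencies in cycles per unit length, R's fft ordering.
fftFreq <- function(n, pitch) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * pitch)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) coordinates.
# Coordinates outside [1, nrow] x [1, ncol] return `fill`.
bilinearSample <- function(m, row, col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; cl <- col[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cl), nc - 1L)
  fr <- r - r0; fc <- cl - c0
  i00 <- (c0 - 1) * nr + r0
  v <- m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

# 1-based index of the centered zero-frequency pixel.
gridCenter <- function(n) floor(n / 2) + 1L

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
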