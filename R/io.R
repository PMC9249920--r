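# Text and binary readers/writers for grids, profiles, PDFs, posterior
# traces and detection streams, plus grayscale image input.

#' Write a numeric grid
#'
#' `format = "text"` writes a plain whitespace-delimited matrix. `format =
#' "binary"` writes the documented dump: two little-endian 32-bit integers
#' (nrow, ncol) followed by the values as little-endian doubles in
#' column-major order.
#'
#' @param x Matrix, [IntensityImage-class] or [DiffractionPattern-class].
#' @param path Output path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(x, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (is(x, "IntensityImage") || is(x, "DiffractionPattern")) x <- values(x)
  x <- as.matrix(x)
  if (format == "text") {
    utils::write.table(x, path, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(dim(x)), con, size = 4L, endian = "little")
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a numeric grid written by [writeGrid()]
#'
#' @param path Input path.
#' @param format `"text"` or `"binary"`.
#' @return Numeric matrix.
#' @export
readGrid <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    unname(as.matrix(utils::read.table(path, header = FALSE)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    matrix(readBin(con, "numeric", n = d[1L] * d[2L], size = 8L,
                   endian = "little"), d[1L], d[2L])
  }
}

#' Write a radial profile or radial PDF as two-column text
#'
#' Columns: radial bin coordinate (physical q when `dq` is known, else the
#' integer pixel radius) and the value (intensity total or density).
#'
#' @param x A [RadialProfile-class] or [RadialPDF-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path) {
  if (is(x, "RadialProfile")) {
    v <- x@totals; dq <- x@dq; what <- "totals"
  } else if (is(x, "RadialPDF")) {
    v <- x@densities; dq <- x@dq; what <- "density"
  } else stop("x must be a RadialProfile or RadialPDF", call. = FALSE)
  q <- seq_along(v) * if (is.finite(dq)) dq else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diffrec %s; dq = %s", what, format(dq)), con)
  utils::write.table(data.frame(q = q, value = v), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column profile/PDF file written by [writeProfile()]
#'
#' @param path Input path.
#' @param as `"profile"` or `"pdf"`: class of the returned object (PDF input
#'   is renormalized through [radialPdf()]).
#' @return A [RadialProfile-class] or [RadialPDF-class].
#' @export
readProfile <- function(path, as = c("profile", "pdf")) {
  as <- match.arg(as)
  header <- readLines(path, n = 1L)
  dq <- NA_real_
  if (grepl("dq = ", header, fixed = TRUE))
    dq <- suppressWarnings(as.numeric(sub(".*dq = ", "", header)))
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (as == "profile") RadialProfile(tab[[2L]], dq = dq)
  else radialPdf(tab[[2L]], dq = dq)
}

#' Write a posterior trace as delimited text
#'
#' One row per state (first row = prior), hypothesis labels as header.
#'
#' @param trace A [PosteriorTrace-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "PosteriorTrace"))
  p <- trace@probs
  colnames(p) <- trace@labels
  utils::write.table(p, path, row.names = FALSE, col.names = TRUE,
                     quote = TRUE)
  invisible(path)
}

#' Read a posterior trace written by [writeTrace()]
#'
#' @param path Input path.
#' @return A [PosteriorTrace-class].
#' @export
readTrace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  p <- as.matrix(tab)
  p <- p / rowSums(p)   # absorb text-roundtrip rounding
  new("PosteriorTrace", probs = unname(p), labels = colnames(tab))
}

#' Write/read a detection stream (one bin index per line)
#'
#' @param detections Integer vector of detected bins.
#' @param path File path.
#' @return `writeDetections`: `path`, invisibly. `readDetections`: integer
#'   vector.
#' @export
writeDetections <- function(detections, path) {
  writeLines(as.character(as.integer(detections)), path)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  as.integer(readLines(path))
}

#' Read a grayscale image as an intensity image
#'
#' PNG files (8- or 16-bit; RGB is converted to luminance) and plain
#' whitespace-delimited numeric grids are supported. PNG rows run top-down;
#' they are flipped so that row index increases with y.
#'
#' @param path Path to a `.png` file or a numeric text grid.
#' @param pixelPitch Pixel pitch to attach (default 1).
#' @return An [IntensityImage-class].
#' @export
readImageGrid <- function(path, pixelPitch = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L)
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  } else {
    img <- as.matrix(utils::read.table(path, header = FALSE))
  }
  if (any(img < 0)) stop("image must be nonnegative", call. = FALSE)
  IntensityImage(unname(img), pixelPitch = pixelPitch)
}
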