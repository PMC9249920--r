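# Sequential Bayesian recognition core: PDF construction, priors,
# single-event updates and the recognition loop over a detection stream.

#' Normalize an intensity distribution into a probability density function
#'
#' A diffraction pattern (or any nonnegative intensity distribution) is turned
#' into the probability of detecting a scattered particle per bin or pixel by
#' dividing by the total intensity.
#'
#' @param x Nonnegative numeric vector, matrix, [RadialProfile-class] or
#'   [DiffractionPattern-class]. Negative entries are an error here; profiles
#'   that may have gone negative through noise should pass through
#'   [radialPdf()], which clips first.
#' @param dq Optional reciprocal-space pitch attached to the result; taken
#'   from the input object when available.
#' @return A [RadialPDF-class] (vector/profile input) or [PlanarPDF-class]
#'   (matrix/pattern input).
#' @examples
#' densities(normalizePdf(c(9, 1)))      # 0.9 0.1
#' @export
normalizePdf <- function(x, dq = NA_real_) {
  center <- NULL
  if (is(x, "RadialProfile")) {
    if (is.na(dq)) dq <- x@dq
    x <- x@totals
  } else if (is(x, "DiffractionPattern")) {
    if (is.na(dq)) dq <- x@dq
    center <- x@center
    x <- x@values
  }
  if (!is.numeric(x)) stop("input must be numeric", call. = FALSE)
  stopIfNotFinite(x, "intensity")
  if (any(x < 0))
    stop("negative intensities: clip noise upstream (see radialPdf)",
         call. = FALSE)
  tot <- sum(x)
  if (tot <= 0)
    stop("normalization impossible: all intensities are zero", call. = FALSE)
  d <- x / tot
  d <- d / sum(d)  # kill residual rounding so the validity check is exact
  if (is.matrix(d)) {
    if (is.null(center))
      center <- c(gridCenter(nrow(d)), gridCenter(ncol(d)))
    new("PlanarPDF", densities = d, center = as.numeric(center),
        dq = as.numeric(dq))
  } else {
    new("RadialPDF", densities = as.numeric(d), dq = as.numeric(dq))
  }
}

#' Uniform prior over M hypotheses
#'
#' Before any particle is detected, all M structural hypotheses are equally
#' probable: P_i = 1/M.
#'
#' @param M Number of hypotheses (>= 1), or a character vector of labels.
#' @param labels Optional hypothesis labels when `M` is a count.
#' @return A [ProbabilityVector-class] with all entries 1/M.
#' @examples
#' probs(uniformPrior(10))   # all 0.1
#' @export
uniformPrior <- function(M, labels = NULL) {
  if (is.character(M)) {
    labels <- M
    M <- length(M)
  }
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M < 1)
    stop("M must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  if (is.null(labels)) labels <- paste0("H", seq_len(M))
  ProbabilityVector(rep(1 / M, M), labels)
}

#' Single-event Bayesian update
#'
#' Posterior_i is proportional to prior_i times the probability, under
#' hypothesis i, of detecting a particle where it was detected. A hypothesis
#' assigning zero density to the observed bin is eliminated (posterior 0)
#' unless a likelihood floor `eps` is supplied.
#'
#' @param prior A [ProbabilityVector-class].
#' @param likelihoods Nonnegative numeric vector: each hypothesis's density at
#'   the detected bin, in hypothesis order.
#' @param eps Optional floor added to every likelihood (default 0: densities
#'   are used exactly as given).
#' @return The posterior [ProbabilityVector-class].
#' @examples
#' probs(bayesUpdate(uniformPrior(2, c("A", "B")), c(0.9, 0.4)))  # 0.692 0.308
#' @export
bayesUpdate <- function(prior, likelihoods, eps = 0) {
  stopifnot(is(prior, "ProbabilityVector"))
  lik <- as.numeric(likelihoods) + eps
  if (length(lik) != length(prior@probs))
    stop("one likelihood per hypothesis required", call. = FALSE)
  stopIfNotFinite(lik, "likelihoods")
  if (any(lik < 0)) stop("likelihoods must be nonnegative", call. = FALSE)
  w <- prior@probs * lik
  tot <- sum(w)
  if (tot <= 0)
    stop("inconsistent detection: zero likelihood under every live hypothesis",
         call. = FALSE)
  ProbabilityVector(w / tot, prior@labels)
}

# Likelihood matrix (detections x hypotheses) for a common support.
likelihoodsAt <- function(pdfs, bins) {
  dens <- lapply(pdfs, function(p) as.numeric(densities(p)))
  len <- vapply(dens, length, integer(1L))
  if (length(unique(len)) != 1L)
    stop("hypothesis PDFs must share one support", call. = FALSE)
  bins <- as.integer(bins)
  if (length(bins) && (min(bins) < 1L || max(bins) > len[1L]))
    stop("detection bin outside the PDF support", call. = FALSE)
  vapply(dens, function(d) d[bins], numeric(length(bins)))
}

#' Sequential recognition over a stream of detections
#'
#' Processes detections one at a time: the posterior after each particle
#' becomes the prior for the next. Likelihood products are accumulated in log
#' space, so arbitrarily long streams (tens of thousands of events) do not
#' underflow.
#'
#' @param pdfs List of hypothesis PDFs ([RadialPDF-class] or
#'   [PlanarPDF-class]), all on the same support. Names become hypothesis
#'   labels.
#' @param detections Integer vector of detected bins (linear indices for
#'   planar PDFs), in arrival order.
#' @param prior Optional [ProbabilityVector-class]; defaults to the uniform
#'   prior over the hypotheses.
#' @param eps Optional likelihood floor, as in [bayesUpdate()].
#' @return A [PosteriorTrace-class] with `length(detections) + 1` rows,
#'   beginning with the prior.
#' @examples
#' pdfs <- list(A = normalizePdf(c(9, 1)), B = normalizePdf(c(4, 6)))
#' probs(sequentialRecognition(pdfs, c(1, 1)))  # 0.5 -> 0.692 -> 0.835
#' @export
sequentialRecognition <- function(pdfs, detections, prior = NULL, eps = 0) {
  if (!length(pdfs)) stop("at least one hypothesis required", call. = FALSE)
  labels <- names(pdfs)
  if (is.null(labels)) labels <- paste0("H", seq_along(pdfs))
  if (is.null(prior)) prior <- uniformPrior(length(pdfs), labels)
  stopifnot(is(prior, "ProbabilityVector"))
  if (length(prior@probs) != length(pdfs))
    stop("prior length must match the number of hypotheses", call. = FALSE)
  labels <- prior@labels
  n <- length(detections)
  M <- length(pdfs)
  out <- matrix(0, nrow = n + 1L, ncol = M)
  out[1L, ] <- prior@probs

  if (n) {
    lik <- likelihoodsAt(pdfs, detections) + eps   # n x M
    if (any(lik < 0)) stop("negative likelihood encountered", call. = FALSE)
    # cumulative log-likelihoods; log(0) = -Inf eliminates a hypothesis for good
    logc <- apply(log(lik), 2L, cumsum)
    if (n == 1L) logc <- matrix(logc, nrow = 1L)
    logp0 <- ifelse(prior@probs > 0, log(prior@probs), -Inf)
    lw <- sweep(logc, 2L, logp0, `+`)
    mx <- apply(lw, 1L, max)
    bad <- !is.finite(mx)
    if (any(bad))
      stop(sprintf(
        "inconsistent detection at event %d: zero likelihood under every live hypothesis",
        which(bad)[1L]), call. = FALSE)
    w <- exp(lw - mx)
    out[-1L, ] <- w / rowSums(w)
  }
  new("PosteriorTrace", probs = out, labels = labels)
}

#' Particles required to reach a confidence threshold
#'
#' The number of detected particles after which the posterior probability of
#' the true hypothesis first reaches the threshold (first crossing; the
#' posterior is not required to stay above it).
#'
#' @param trace A [PosteriorTrace-class].
#' @param trueHypothesis Label or column index of the correct hypothesis.
#' @param threshold Confidence level in (0, 1), default 0.95.
#' @return Integer count, or `NA_integer_` when the threshold is never
#'   reached within the trace.
#' @export
particlesToThreshold <- function(trace, trueHypothesis, threshold = 0.95) {
  stopifnot(is(trace, "PosteriorTrace"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  idx <- if (is.character(trueHypothesis)) {
    match(trueHypothesis, trace@labels)
  } else {
    i <- as.integer(trueHypothesis)
    if (is.na(i) || i < 1L || i > ncol(trace@probs)) NA_integer_ else i
  }
  if (is.na(idx))
    stop("unknown true hypothesis: ", trueHypothesis, call. = FALSE)
  p <- trace@probs[, idx]
  hit <- which(p[-1L] >= threshold)   # row k+1 = after k detections; k >= 1
  if (!length(hit)) NA_integer_ else hit[1L]
}
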