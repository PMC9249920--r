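# End-to-end recognition experiments: single trials, trial ensembles,
# particles-to-threshold statistics, dose accounting and the conventional
# cross-correlation baseline.

#' Result of one recognition trial
#'
#' @slot nToThreshold Particles needed for the true hypothesis to first
#'   reach the confidence threshold; `NA` when not reached in budget.
#' @slot trace The [PosteriorTrace-class] (empty matrix when not kept).
#' @slot seed Seed used for the trial's detection stream.
#' @slot trueHypothesis Label of the probed hypothesis.
#' @slot threshold Confidence threshold used.
#' @export
setClass("TrialResult",
         representation(nToThreshold = "integer", trace = "PosteriorTrace",
                        seed = "numeric", trueHypothesis = "character",
                        threshold = "numeric"))

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult: true = '%s', n to %.0f%% = %s (seed %s)\n",
              object@trueHypothesis, 100 * object@threshold,
              ifelse(is.na(object@nToThreshold), "not reached",
                     object@nToThreshold), format(object@seed)))
})

#' Result of a recognition ensemble
#'
#' @slot counts Per-trial particles-to-threshold (`NA` = not reached).
#' @slot summary Named numeric: mean, median, q05, q95, fracNotReached.
#' @slot nTrials Number of trials.
#' @slot baseSeed Base seed; trial i used `baseSeed + i`.
#' @slot threshold Confidence threshold.
#' @slot trueHypothesis Probed hypothesis label.
#' @export
setClass("EnsembleResult",
         representation(counts = "integer", summary = "numeric",
                        nTrials = "integer", baseSeed = "numeric",
                        threshold = "numeric", trueHypothesis = "character"))

setMethod("show", "EnsembleResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "EnsembleResult: %d trials, true = '%s'\n  median %g, mean %g, 5%%-95%% [%g, %g], not reached %.1f%%\n",
    object@nTrials, object@trueHypothesis, s["median"], s["mean"],
    s["q05"], s["q95"], 100 * s["fracNotReached"]))
})

#' Run a single recognition trial
#'
#' Samples detections from the probed (typically noisy) PDF and updates the
#' hypothesis posteriors per particle, stopping when the true hypothesis
#' first reaches the threshold or the particle budget is exhausted. The
#' hypothesis PDFs stay noise-free, per the character-recognition protocol;
#' noise enters only through `truePdf`.
#'
#' @param truePdf [RadialPDF-class]/[PlanarPDF-class] the detections are
#'   drawn from (the probed object, possibly with noise applied upstream).
#' @param pdfs Named list of noise-free hypothesis PDFs on the same support.
#' @param trueHypothesis Label of the probed hypothesis among `names(pdfs)`.
#' @param threshold Confidence threshold (default 0.95).
#' @param budget Maximum detections; default `100 * M * nbins`.
#' @param seed Optional integer seed for the detection stream.
#' @param keepTrace Keep the full posterior trace (default `TRUE`).
#' @param eps Optional likelihood floor, as in [bayesUpdate()].
#' @return A [TrialResult-class].
#' @export
runTrial <- function(truePdf, pdfs, trueHypothesis, threshold = 0.95,
                     budget = NULL, seed = NULL, keepTrace = TRUE,
                     eps = 0) {
  labels <- names(pdfs)
  if (is.null(labels)) labels <- paste0("H", seq_along(pdfs))
  names(pdfs) <- labels
  if (!trueHypothesis %in% labels)
    stop("true hypothesis '", trueHypothesis,
         "' is not among the hypothesis labels", call. = FALSE)
  nbins <- length(as.numeric(densities(pdfs[[1L]])))
  if (is.null(budget)) budget <- 100L * length(pdfs) * nbins
  budget <- as.integer(budget)
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)

  detections <- sampleDetections(truePdf, budget, seed = seed)
  trace <- sequentialRecognition(pdfs, detections, eps = eps)
  n <- particlesToThreshold(trace, trueHypothesis, threshold)
  if (!is.na(n)) {
    # stop at first crossing: truncate the trace there
    trace <- new("PosteriorTrace",
                 probs = trace@probs[seq_len(n + 1L), , drop = FALSE],
                 labels = trace@labels)
  }
  if (!keepTrace)
    trace <- new("PosteriorTrace",
                 probs = trace@probs[nrow(trace@probs), , drop = FALSE],
                 labels = trace@labels)
  new("TrialResult", nToThreshold = n, trace = trace,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      trueHypothesis = trueHypothesis, threshold = as.numeric(threshold))
}

#' Run an ensemble of recognition trials
#'
#' Repeats [runTrial()] with independent seeds `baseSeed + i` and, when a
#' noise model is given, a fresh noise realization of the probed profile per
#' trial. Summaries (mean, median, 5th/95th percentile, fraction not
#' reached) are computed over the trials that reached the threshold.
#'
#' @param trueProfile Noise-free [RadialProfile-class] of the probed object
#'   (ignored when `truePdf` is given).
#' @param pdfs Named list of noise-free hypothesis PDFs.
#' @param trueHypothesis Label of the probed hypothesis.
#' @param snr Constant SNR applied to `trueProfile` per trial; `NULL`
#'   disables noise.
#' @param truePdf Optional fixed probed PDF used for every trial (bypasses
#'   profile + noise).
#' @param nTrials Number of trials (default 1000).
#' @param baseSeed Base seed (default 1).
#' @param threshold,budget,eps Passed to [runTrial()].
#' @return An [EnsembleResult-class].
#' @export
runEnsemble <- function(trueProfile = NULL, pdfs, trueHypothesis,
                        snr = 2, truePdf = NULL, nTrials = 1000L,
                        baseSeed = 1L, threshold = 0.95, budget = NULL,
                        eps = 0) {
  nTrials <- as.integer(nTrials)
  if (nTrials < 1L) stop("nTrials must be >= 1", call. = FALSE)
  if (is.null(truePdf) && is.null(trueProfile))
    stop("supply either trueProfile or truePdf", call. = FALSE)
  counts <- integer(nTrials)
  for (i in seq_len(nTrials)) {
    seed <- baseSeed + i
    pdf_i <- if (!is.null(truePdf)) {
      truePdf
    } else if (is.null(snr)) {
      radialPdf(trueProfile)
    } else {
      radialPdf(addNoiseConstantSnr(trueProfile, snr, seed = seed))
    }
    tr <- tryCatch(
      runTrial(pdf_i, pdfs, trueHypothesis, threshold = threshold,
               budget = budget, seed = seed, keepTrace = FALSE, eps = eps),
      error = function(e)
        stop(sprintf("trial %d failed: %s", i, conditionMessage(e)),
             call. = FALSE))
    counts[i] <- tr@nToThreshold
  }
  reached <- counts[!is.na(counts)]
  summ <- c(mean = if (length(reached)) mean(reached) else NA_real_,
            median = if (length(reached)) stats::median(reached) else NA_real_,
            q05 = if (length(reached))
              unname(stats::quantile(reached, 0.05)) else NA_real_,
            q95 = if (length(reached))
              unname(stats::quantile(reached, 0.95)) else NA_real_,
            fracNotReached = mean(is.na(counts)))
  new("EnsembleResult", counts = counts, summary = summ, nTrials = nTrials,
      baseSeed = as.numeric(baseSeed), threshold = as.numeric(threshold),
      trueHypothesis = trueHypothesis)
}

#' Radiation dose accounting
#'
#' Converts a particle count over a probed area into an elastic dose, and
#' into a total dose given the elastically scattered fraction (about one
#' X-ray photon in ten scatters elastically; for counted electrons the
#' fraction is taken as 1).
#'
#' @param nParticles Number of elastically scattered particles detected.
#' @param probedArea Probed specimen area in Angstrom^2.
#' @param elasticFraction Fraction of incident particles scattered
#'   elastically, in (0, 1] (default 0.1, the X-ray value).
#' @return A list with `nParticles`, `probedArea`, `elasticFraction`,
#'   `elasticDose` and `totalDose` (particles/Angstrom^2).
#' @examples
#' doseReport(40000, 8.23e5, elasticFraction = 1)$elasticDose  # 0.0486
#' @export
doseReport <- function(nParticles, probedArea, elasticFraction = 0.1) {
  if (!is.numeric(probedArea) || probedArea <= 0)
    stop("probedArea must be positive", call. = FALSE)
  if (!is.numeric(elasticFraction) || elasticFraction <= 0 ||
      elasticFraction > 1)
    stop("elasticFraction must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(nParticles) || nParticles < 0)
    stop("nParticles must be nonnegative", call. = FALSE)
  elastic <- nParticles / probedArea
  structure(list(nParticles = nParticles, probedArea = probedArea,
                 elasticFraction = elasticFraction, elasticDose = elastic,
                 totalDose = elastic / elasticFraction),
            class = "doseReport")
}

#' @export
print.doseReport <- function(x, ...) {
  cat(sprintf(
    "Dose: %g particles over %g A^2 -> elastic %.4g /A^2, total %.4g /A^2 (elastic fraction %g)\n",
    x$nParticles, x$probedArea, x$elasticDose, x$totalDose,
    x$elasticFraction))
  invisible(x)
}

#' Peak normalized cross-correlation between two radial profiles
#'
#' The conventional template-matching baseline: the maximum, over lags, of
#' the mean-subtracted cross-correlation scaled by the product of the two
#' profiles' norms, in \[-1, 1\].
#'
#' @param observed,reference [RadialProfile-class] objects or numeric
#'   vectors of equal length `>= 2`.
#' @param lags Integer lags to search (default all); `0` gives the plain
#'   normalized correlation.
#' @return Peak normalized cross-correlation over the searched lags.
#' @export
ccfSimilarity <- function(observed, reference, lags = NULL) {
  x <- if (is(observed, "RadialProfile")) observed@totals
       else as.numeric(observed)
  y <- if (is(reference, "RadialProfile")) reference@totals
       else as.numeric(reference)
  if (length(x) != length(y) || length(x) < 2L)
    stop("profiles must have equal length >= 2", call. = FALSE)
  x <- x - mean(x); y <- y - mean(y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("undefined correlation: zero-variance profile", call. = FALSE)
  n <- length(x)
  if (is.null(lags)) lags <- -(n - 1L):(n - 1L)
  best <- -Inf
  for (lag in lags) {
    ix <- seq_len(n)
    iy <- ix + lag
    ok <- iy >= 1L & iy <= n
    cc <- sum(x[ix[ok]] * y[iy[ok]]) / (nx * ny)
    if (cc > best) best <- cc
  }
  best
}
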