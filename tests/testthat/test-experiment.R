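# End-to-end recognition trials, ensembles, dose arithmetic and the CCF
# baseline.

test_that("runTrial stops at the first decisive detection", {
  hyp <- list(A = normalizePdf(c(0, 0, 1, 0, 0, 0, 0, 0)),
              B = normalizePdf(c(0, 0, 0, 0, 0, 0, 1, 0)))
  tr <- runTrial(hyp$A, hyp, "A", seed = 1)
  expect_equal(tr@nToThreshold, 1L)
  # identical hypotheses never reach threshold
  same <- list(A = normalizePdf(1:6), B = normalizePdf(1:6))
  tr2 <- runTrial(same$A, same, "A", seed = 2, budget = 300)
  expect_true(is.na(tr2@nToThreshold))
  expect_error(runTrial(hyp$A, hyp, "C"), "not among")
})

test_that("the worked example crosses 0.8 after two detections", {
  hyp <- list(A = normalizePdf(c(9, 1)), B = normalizePdf(c(4, 6)))
  # forcing both detections into bin 1 reproduces the printed trace
  trace <- sequentialRecognition(hyp, c(1, 1))
  expect_equal(particlesToThreshold(trace, "A", 0.8), 2L)
  expect_equal(round(probs(trace)[, "A"], 3), c(0.5, 0.692, 0.835))
})

test_that("ensembles are reproducible and degenerate cases collapse", {
  hyp <- list(A = normalizePdf(c(0, 1, 0, 0)), B = normalizePdf(c(0, 0, 0, 1)))
  e <- runEnsemble(truePdf = hyp$A, pdfs = hyp, trueHypothesis = "A",
                   snr = NULL, nTrials = 100, baseSeed = 7)
  expect_true(all(e@counts == 1L))
  prof <- RadialProfile(exp(-((1:16) - 5)^2 / 8))
  hyp2 <- list(A = radialPdf(prof@totals),
               B = radialPdf(exp(-((1:16) - 9)^2 / 8)))
  e1 <- runEnsemble(prof, hyp2, "A", snr = 2, nTrials = 50, baseSeed = 11,
                    budget = 2000)
  e2 <- runEnsemble(prof, hyp2, "A", snr = 2, nTrials = 50, baseSeed = 11,
                    budget = 2000)
  expect_identical(e1@counts, e2@counts)
  expect_identical(e1@summary, e2@summary)
  expect_equal(sum(table(e1@counts)) + sum(is.na(e1@counts)), 50L)
})

test_that("ensemble medians match the Wald expected-sample-size oracle", {
  q <- 1:32
  profA <- exp(-(q - 10)^2 / 40)
  profB <- exp(-(q - 13.5)^2 / 40)
  pdfs <- list(A = radialPdf(profA), B = radialPdf(profB))
  pA <- densities(pdfs$A); pB <- densities(pdfs$B)
  expect_equal(tvDist(pA, pB), 0.3, tolerance = 0.1)
  counts <- integer(200); drift <- numeric(200)
  for (i in 1:200) {
    noisy <- radialPdf(addNoiseConstantSnr(RadialProfile(profA), 2,
                                           seed = 500 + i))
    # per-event expected log-likelihood ratio under the sampling PDF
    drift[i] <- sum(densities(noisy) * (log(pA) - log(pB)))
    tr <- runTrial(noisy, pdfs, "A", seed = 500 + i, budget = 5000,
                   keepTrace = FALSE)
    counts[i] <- tr@nToThreshold
  }
  predicted <- log(19) / mean(drift)
  observed <- stats::median(counts, na.rm = TRUE)
  expect_lt(abs(observed - predicted) / predicted, 0.3)
  # budget soundness: nothing unfinished at a budget >> the prediction
  expect_lt(mean(is.na(counts)), 0.02)
})

test_that("better-separated hypotheses never need more particles", {
  q <- 1:32
  base <- exp(-(q - 10)^2 / 40)
  meds <- vapply(c(12, 14, 16), function(ctr) {
    pdfs <- list(A = radialPdf(base), B = radialPdf(exp(-(q - ctr)^2 / 40)))
    e <- runEnsemble(RadialProfile(base), pdfs, "A", snr = 2, nTrials = 60,
                     baseSeed = 31, budget = 5000)
    e@summary[["median"]]
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("dose arithmetic matches the reported examples", {
  expect_equal(doseReport(40000, 8.23e5, elasticFraction = 1)$elasticDose,
               48.6e-3, tolerance = 1e-3)
  r <- doseReport(0.11 * 8.23e5, 8.23e5, elasticFraction = 0.1)
  expect_equal(r$elasticDose, 0.11)
  expect_equal(r$totalDose, 1.1)
  z <- doseReport(0, 8.23e5, elasticFraction = 0.5)
  expect_equal(c(z$elasticDose, z$totalDose), c(0, 0))
  expect_equal(r$totalDose, r$elasticDose / r$elasticFraction)
  expect_error(doseReport(10, -1), "positive")
})

test_that("ccfSimilarity is a normalized peak correlation", {
  prof <- exp(-((1:20) - 8)^2 / 10) + 0.2
  expect_equal(ccfSimilarity(prof, prof), 1, tolerance = 1e-12)
  expect_equal(ccfSimilarity(prof, -prof, lags = 0), -1, tolerance = 1e-12)
  expect_gte(ccfSimilarity(prof, prof, lags = 0),
             ccfSimilarity(prof, prof[c(2:20, 1)], lags = 0))
  expect_error(ccfSimilarity(rep(1, 5), prof[1:5]), "zero-variance")
})

test_that("the Bayesian posterior separates profiles the CCF cannot", {
  q <- 1:32
  base <- 100 * exp(-(q - 8)^2 / 30) + 20
  alt <- base; alt[18:24] <- alt[18:24] * 1.30
  pdfs <- list(A = radialPdf(base), B = radialPdf(alt))
  expect_lt(tvDist(densities(pdfs$A), densities(pdfs$B)), 0.05)
  noisy <- addNoiseConstantSnr(RadialProfile(base), 2, seed = 1)
  det <- sampleDetections(radialPdf(noisy), 2000, seed = 10001)
  emp <- tabulate(det, 32)
  ccfGap <- abs(ccfSimilarity(emp, base) - ccfSimilarity(emp, alt))
  post <- probs(sequentialRecognition(pdfs, det))[length(det) + 1, ]
  expect_lt(ccfGap, 0.05)
  expect_gt(post[["A"]] - post[["B"]], 0.9)
})
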