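# Bayesian recognition core: PDF construction, updates, sequential loop.

test_that("normalizePdf rescales intensities into a valid density", {
  expect_equal(densities(normalizePdf(c(9, 1))), c(0.9, 0.1))
  expect_equal(densities(normalizePdf(rep(2, 4))), rep(0.25, 4))
  expect_error(normalizePdf(c(0, 0)), "normalization impossible")
  expect_error(normalizePdf(c(1, -1)), "negative")
  # matrix input yields a planar PDF with a valid center
  p2 <- normalizePdf(matrix(1:16, 4, 4))
  expect_s4_class(p2, "PlanarPDF")
  expect_equal(sum(densities(p2)), 1)
})

test_that("uniformPrior spreads probability equally over hypotheses", {
  expect_equal(unname(probs(uniformPrior(10))), rep(0.1, 10))
  expect_equal(unname(probs(uniformPrior(2))), c(0.5, 0.5))
  expect_equal(unname(probs(uniformPrior(1))), 1)
  expect_equal(hypLabels(uniformPrior(c("up", "down"))), c("up", "down"))
  expect_error(uniformPrior(0), "positive")
})

test_that("bayesUpdate reproduces the two-pixel worked example", {
  prior <- uniformPrior(2, c("A", "B"))
  post1 <- bayesUpdate(prior, c(0.9, 0.4))
  expect_equal(round(unname(probs(post1)), 3), c(0.692, 0.308))
  post2 <- bayesUpdate(post1, c(0.9, 0.4))
  expect_equal(round(unname(probs(post2)), 3), c(0.835, 0.165))
  # equal likelihoods leave any prior unchanged
  pr <- ProbabilityVector(c(0.3, 0.2, 0.5))
  expect_equal(probs(bayesUpdate(pr, c(2, 2, 2) / 6)), probs(pr))
  # zero likelihood eliminates a hypothesis; all-zero is inconsistent
  expect_equal(unname(probs(bayesUpdate(prior, c(0, 0.4)))), c(0, 1))
  expect_error(bayesUpdate(prior, c(0, 0)), "inconsistent")
})

test_that("sequentialRecognition chains updates and matches the worked example", {
  pdfs <- list(A = normalizePdf(c(9, 1)), B = normalizePdf(c(4, 6)))
  tr <- sequentialRecognition(pdfs, c(1, 1))
  expect_equal(round(unname(probs(tr)[, "A"]), 3), c(0.5, 0.692, 0.835))
  # identical hypotheses: trace constant at the prior
  same <- list(A = normalizePdf(1:5), B = normalizePdf(1:5))
  trSame <- sequentialRecognition(same, c(2, 4, 5))
  expect_true(all(abs(probs(trSame) - 0.5) < 1e-12))
  # single hypothesis: constant 1
  tr1 <- sequentialRecognition(list(only = normalizePdf(1:3)), c(1, 2, 3))
  expect_equal(unname(probs(tr1)[, 1]), rep(1, 4))
  # mismatched supports rejected
  expect_error(
    sequentialRecognition(list(A = normalizePdf(1:3), B = normalizePdf(1:4)), 1),
    "support")
  # inconsistent detection reported with its event index
  z <- list(A = normalizePdf(c(1, 0)), B = normalizePdf(c(1, 0)))
  expect_error(sequentialRecognition(z, c(1, 2)), "event 2")
})

test_that("sequential result equals the log-space product oracle", {
  set.seed(42)
  for (rep in 1:5) {
    M <- sample(2:6, 1)
    nbins <- sample(5:20, 1)
    nDet <- sample(10:50, 1)
    pdfs <- lapply(seq_len(M), function(i)
      normalizePdf(stats::runif(nbins) + 0.05))
    names(pdfs) <- paste0("H", seq_len(M))
    det <- sample(nbins, nDet, replace = TRUE)
    tr <- sequentialRecognition(pdfs, det)
    # oracle: normalize(prior_i * prod_k P(p_k | I_i)) in log space
    logw <- vapply(pdfs, function(p)
      log(1 / M) + sum(log(densities(p)[det])), numeric(1))
    oracle <- exp(logw - max(logw))
    oracle <- oracle / sum(oracle)
    expect_equal(unname(probs(tr)[nDet + 1, ]), unname(oracle),
                 tolerance = 1e-9)
  }
})

test_that("posterior rows are simplex vectors and order-invariant", {
  set.seed(7)
  pdfs <- lapply(1:4, function(i) normalizePdf(stats::runif(12) + 0.02))
  names(pdfs) <- paste0("H", 1:4)
  det <- sample(12, 60, replace = TRUE)
  tr <- sequentialRecognition(pdfs, det)
  expect_true(all(probs(tr) >= 0))
  expect_true(all(abs(rowSums(probs(tr)) - 1) < 1e-12))
  trPerm <- sequentialRecognition(pdfs, sample(det))
  expect_equal(probs(tr)[61, ], probs(trPerm)[61, ], tolerance = 1e-12)
})

test_that("posterior concentrates on the sampled hypothesis", {
  # 5 strictly positive hypotheses, detections drawn from hypothesis 3
  pdfs <- lapply(c(8, 12, 16, 20, 24), smoothPdf)
  names(pdfs) <- paste0("H", 1:5)
  dens <- lapply(pdfs, densities)
  minTv <- min(vapply(c(1, 2, 4, 5), function(j)
    tvDist(dens[[3]], dens[[j]]), numeric(1)))
  expect_gt(minTv, 0.05)
  hits <- vapply(1:200, function(i) {
    det <- sampleDetections(pdfs[[3]], 500, seed = 9000 + i)
    probs(sequentialRecognition(pdfs, det))[501, "H3"] > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # also the small DERIVED case: 200 detections, oracle agreement
  det <- sampleDetections(pdfs[[3]], 200, seed = 123)
  fin <- probs(sequentialRecognition(pdfs, det))[201, ]
  expect_equal(unname(which.max(fin)), 3L)
})

test_that("particlesToThreshold finds the first crossing", {
  mk <- function(v) new("PosteriorTrace",
                        probs = cbind(v, 1 - v), labels = c("A", "B"))
  expect_equal(particlesToThreshold(mk(c(0.5, 0.692, 0.835, 0.96)), "A"), 3L)
  expect_true(is.na(particlesToThreshold(mk(rep(0.5, 4)), "A")))
  expect_equal(particlesToThreshold(mk(c(0.5, 0.692, 0.835)), "A", 0.8), 2L)
  expect_error(particlesToThreshold(mk(c(0.5, 0.9)), "C"), "unknown")
  expect_error(particlesToThreshold(mk(c(0.5, 0.9)), "A", 1), "threshold")
})
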