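# Population trajectories, distances, PCA and decoding.

test_that("population vectors require two non-lick units and drop lick cells", {
  ss <- lfp_session()
  cls <- classify_response_windows(ss$bundle)
  pv <- population_vectors(ss$bundle, cls, area = "CA1")
  expect_equal(ncol(pv$plus), length(pv$units))
  expect_identical(dim(pv$plus), dim(pv$minus))
  one_unit <- cls[cls$area == "CA1", ][1, ]
  expect_error(population_vectors(ss$bundle, one_unit, area = "CA1"),
               "at least 2")
})

test_that("distance trace obeys the metric identities", {
  time <- seq(-0.9875, 3.9875, by = 0.025)
  n <- length(time)
  a <- matrix(rnorm(n * 5, 5), n, 5)
  # identical matrices -> raw distance 0 everywhere
  d0 <- distance_trace(a, a, time)
  expect_true(all(d0$raw == 0))
  # single unit, rates 3 vs 7 -> raw distance 4
  d1 <- distance_trace(matrix(3, n, 1), matrix(7, n, 1), time)
  expect_true(all(d1$raw == 4))
  expect_false(d1$zscored)                 # constant baseline -> flagged
  # invariance under a shared orthogonal rotation of the unit axes
  b <- matrix(rnorm(n * 5, 5), n, 5)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  d <- distance_trace(a, b, time)
  dr <- distance_trace(a %*% q, b %*% q, time)
  expect_equal(d$raw, dr$raw)
  # duplicating a unit scales a 1-unit distance by sqrt(2)
  d2 <- distance_trace(matrix(3, n, 2), matrix(7, n, 2), time)
  expect_equal(d2$raw, sqrt(2) * d1$raw)
})

test_that("PCA projection preserves structure of 3-D embedded data", {
  set.seed(4)
  coords <- matrix(rnorm(60 * 3), 60, 3)
  load <- matrix(rnorm(3 * 10), 3, 10)
  mats <- list(plus = coords %*% load + 5,
               minus = (coords + 0.5) %*% load + 5)
  pc <- pca_trajectory(mats)
  expect_equal(pc$k, 3L)
  d_orig <- sqrt(rowSums((mats$plus - mats$minus)^2))
  d_proj <- sqrt(rowSums((pc$plus - pc$minus)^2))
  expect_equal(d_proj, d_orig, tolerance = 1e-8)
  # rank-1 data yields a single usable component, with a flag
  r1 <- list(plus = outer(rnorm(30), rnorm(4)),
             minus = outer(rnorm(30), rnorm(4)) * 0)
  pr1 <- suppressWarnings(pca_trajectory(r1))
  expect_true(pr1$rank_deficient)
  # deterministic sign: largest loading positive
  expect_true(all(apply(pc$loadings, 2L,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("decoder separates planted condition differences", {
  ss <- decode_session()
  cls <- classify_response_windows(ss$bundle)
  set.seed(10)
  dec <- decode_trial_identity(ss$bundle, cls, area = "CA1")
  expect_gte(dec$accuracy, 0.9)
  expect_length(dec$fold_accuracy, 20L)
})

test_that("label shuffling brings accuracy back to chance", {
  ss <- post_session()
  cls <- classify_response_windows(ss$bundle)
  set.seed(11)
  dec <- decode_trial_identity(ss$bundle, cls, area = "CA1", n_perm = 30)
  expect_lt(dec$p_value, 0.05)
  expect_lt(mean(dec$null_accuracy), 0.65)
  expect_gt(mean(dec$null_accuracy), 0.35)
})

test_that("decoding demands enough trials and both CS types", {
  ss <- lfp_session()
  cls <- classify_response_windows(ss$bundle)
  expect_error(decode_trial_identity(ss$bundle, cls, folds = 20),
               "at least 20|stratified")
})
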