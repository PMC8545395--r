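# Reduced-rank regression: subsampling, CV machinery, rank selection.

test_that("subsampling yields four disjoint, equally sized sets", {
  set.seed(1)
  qd <- subsample_quadruple(1:30, 1:50)
  expect_equal(qd$m, 15L)
  expect_length(qd$ca1_source, 15L)
  expect_length(qd$pfc_target, 15L)
  expect_length(intersect(qd$ca1_source, qd$ca1_target), 0L)
  expect_length(intersect(qd$pfc_source, qd$pfc_target), 0L)
  expect_error(subsample_quadruple(1:3, 1:100), "m = 1")
})

test_that("period activity has trials x bins rows and centered columns", {
  ss <- lfp_session()
  x <- period_activity(ss$bundle, "trace", area = "CA1")
  expect_equal(nrow(x), 10L * nrow(ss$bundle$trials))
  expect_true(all(abs(colMeans(x)) < 1e-10))
  x2 <- period_activity(ss$bundle, "trace", area = "CA1")
  expect_equal(x, x2)                       # deterministic given bundle
})

test_that("full-rank reduced-rank predictions equal plain OLS", {
  set.seed(2)
  n <- 200; p <- 6; q <- 4
  x <- matrix(rnorm(n * p), n, p)
  y <- x %*% matrix(rnorm(p * q), p, q) + matrix(rnorm(n * q), n, q)
  # independent OLS oracle reproducing the same fold assignment
  folds <- 10L
  set.seed(77)
  fid <- rep_len(seq_len(folds), n)[sample.int(n)]
  ols_r2 <- vapply(seq_len(folds), function(k) {
    tr <- fid != k
    mx <- colMeans(x[tr, ]); my <- colMeans(y[tr, ])
    xtr <- sweep(x[tr, ], 2, mx); ytr <- sweep(y[tr, ], 2, my)
    xte <- sweep(x[!tr, ], 2, mx); yte <- sweep(y[!tr, ], 2, my)
    b <- solve(crossprod(xtr) + diag(1e-8, p), crossprod(xtr, ytr))
    1 - sum((yte - xte %*% b)^2) / sum(yte^2)
  }, numeric(1))
  set.seed(77)
  rrr_full <- fit_rrr(x, y, rank = q, folds = folds)
  expect_equal(rrr_full, ols_r2, tolerance = 1e-10)
})

test_that("a planted low-rank map is recovered by the performance curve", {
  set.seed(3)
  n <- 400; p <- 8; q <- 8
  x <- matrix(rnorm(n * p), n, p)
  b2 <- matrix(rnorm(p * 2), p, 2) %*% matrix(rnorm(2 * q), 2, q)
  y <- x %*% b2 + 0.5 * matrix(rnorm(n * q), n, q)
  pm <- rrr_cv(x, y)
  means <- colMeans(pm)
  expect_gt(means[2] - means[1], 0.05)      # steep rise to rank 2
  expect_lt(abs(means[4] - means[2]), 0.02) # then plateau
  expect_equal(select_rank(pm), 2L)
})

test_that("held-out R^2 is non-positive when target is independent", {
  set.seed(4)
  x <- matrix(rnorm(300 * 6), 300, 6)
  y <- matrix(rnorm(300 * 6), 300, 6)
  pm <- rrr_cv(x, y)
  expect_lt(max(colMeans(pm)), 0.01)
})

test_that("1-SEM rule picks the smallest rank within reach of the best", {
  expect_equal(select_rank(c(0.50, 0.70, 0.71, 0.715),
                           sem = c(0.01, 0.01, 0.01, 0.01)), 3L)
  expect_equal(select_rank(rep(0.5, 5), sem = rep(0.01, 5)), 1L)
})

test_that("cross-area analysis reports all directions and periods", {
  ss <- lfp_session()
  set.seed(5)
  res <- crossarea_analysis(ss$bundle, periods = "stim",
                            n_subsamples = 2L, folds = 5L,
                            full_control = TRUE)
  expect_equal(nrow(res), 4L)
  expect_setequal(paste(res$source, res$target),
                  c("CA1 CA1", "CA1 PFC", "PFC CA1", "PFC PFC"))
  expect_true(all(res$performance <= 1))
  expect_true(all(res$rank >= 1))
  expect_true(all(is.finite(res$control_mse)))
})
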