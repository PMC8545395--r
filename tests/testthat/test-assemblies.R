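# Assembly detection, activation algebra and reactivation statistics.

test_that("Marcenko-Pastur bound follows the closed form", {
  expect_equal(mp_bound(100, 10000), 1.21)
  expect_error(mp_bound(100, 100), "exceed")
})

test_that("a duplicated unit creates one significant eigenvalue", {
  set.seed(8)
  counts <- matrix(rpois(3000 * 15, 0.1), 3000, 15)
  counts <- cbind(counts, counts[, 1])      # exact copy of unit 1
  m <- assembly_patterns(counts)
  expect_gte(m$n_assemblies, 1L)
  top <- order(abs(m$patterns[, 1]), decreasing = TRUE)[1:2]
  expect_setequal(top, c(1L, 16L))
})

test_that("activation algebra matches hand computation and zero rules", {
  # two members with weights .7/.7 and z = 2/2, all else silent -> 3.92
  w <- c(0.7, 0.7, rep(0, 4)) / sqrt(2 * 0.49)
  w_raw <- c(0.7, 0.7, rep(0, 4))
  z <- matrix(0, 1, 6); z[1, 1:2] <- 2
  expect_equal(unname(drop(activation_quadratic(z, cbind(w_raw)))), 3.92)
  # one active unit -> exactly 0 for any pattern
  z1 <- matrix(0, 1, 6); z1[1, 3] <- 5
  expect_equal(unname(drop(activation_quadratic(z1, cbind(w_raw)))), 0)
  # single-unit population -> identically 0
  zs <- matrix(rnorm(10), 10, 1)
  expect_true(all(activation_quadratic(zs, matrix(1, 1, 1)) == 0))
})

test_that("patterns are unit norm, sign-aligned and seed-stable", {
  ss <- assembly_session(seed = 33, n_assemblies = 2L, n_units = 24L)
  set.seed(1)
  m1 <- detect_assemblies(ss$bundle$spikes$CA1, ss$bundle$trials)
  set.seed(1)
  m2 <- detect_assemblies(ss$bundle$spikes$CA1, ss$bundle$trials)
  expect_identical(m1$patterns, m2$patterns)
  expect_equal(colSums(m1$patterns^2), rep(1, m1$n_assemblies))
  for (j in seq_len(m1$n_assemblies)) {
    i <- which.max(abs(m1$patterns[, j]))
    expect_gt(m1$patterns[i, j], 0)
  }
})

test_that("activation peaks align with planted assembly events", {
  ss <- assembly_session(seed = 35, n_assemblies = 1L, n_units = 20L)
  set.seed(2)
  m <- detect_assemblies(ss$bundle$spikes$CA1, ss$bundle$trials)
  expect_gte(m$n_assemblies, 1L)
  tw <- truth_weights(ss$truth)
  mm <- match_patterns(m$patterns, tw)
  k <- mm$detected[1]
  dur <- ss$bundle$meta$duration_s
  act <- assembly_activation(m, ss$bundle$spikes$CA1, 0, dur)
  ev <- ss$truth$assemblies[[1]]$event_times
  ev <- ev[ev > 1 & ev < dur - 1]
  lags <- vapply(ev, function(t0) {
    sel <- which(abs(act$time - t0) <= 0.1)
    act$time[sel[which.max(act$activation[sel, k])]] - t0
  }, numeric(1))
  expect_lt(median(abs(lags)), 0.02)
})

test_that("reactivation baseline ignores the ripple-center windows", {
  set.seed(9)
  tt <- seq(0.01, 200, by = 0.01)
  a <- matrix(rnorm(length(tt)), ncol = 1)
  act <- structure(list(time = tt, activation = a, step_s = 0.01,
                        bin_width_s = 0.02), class = "activation_trace")
  rt <- seq(10, 190, by = 10)
  re <- swr_triggered_reactivation(act, rt)
  spiked <- a
  for (t0 in rt) spiked[abs(tt - t0) <= 0.02, 1] <- 50
  act2 <- structure(list(time = tt, activation = spiked, step_s = 0.01,
                         bin_width_s = 0.02), class = "activation_trace")
  re2 <- swr_triggered_reactivation(act2, rt)
  expect_equal(re2$baseline_sd, re$baseline_sd, tolerance = 1e-10)
  expect_gt(mean(re2$per_ripple), 10)       # injected peaks score high
})

test_that("block dynamics partition trials evenly and compare edges", {
  ss <- assembly_session(seed = 37, n_assemblies = 2L, n_units = 24L,
                         couplings = c(0.6, 0))
  set.seed(3)
  m <- detect_assemblies(ss$bundle$spikes$CA1, ss$bundle$trials)
  act <- assembly_activation(m, ss$bundle$spikes$CA1, 0,
                             ss$bundle$meta$duration_s)
  re <- swr_triggered_reactivation(act, iti_ripples(ss$truth,
                                                    ss$bundle$trials),
                                   ss$bundle$trials)
  bd <- block_dynamics(re, ss$bundle$trials, ss$bundle$meta$duration_s)
  expect_equal(nrow(bd$block_means), 10L)
  sizes <- table(ceiling(seq_len(nrow(ss$bundle$trials)) /
                           (nrow(ss$bundle$trials) / 10)))
  expect_lte(diff(range(sizes)), 1)
  few <- ss$bundle$trials[1:5, ]
  expect_error(block_dynamics(re, few, 100), "at least 10")
})

test_that("modulation scores and selection follow their definitions", {
  k <- 3L
  per_trial <- array(0, dim = c(20, 4, k),
                     dimnames = list(NULL, c("baseline", "stim", "trace",
                                             "reward"), NULL))
  cs <- rep(c("plus", "minus"), each = 10)
  per_trial[cs == "plus", "stim", 1] <- 2
  per_trial[cs == "plus", "trace", 1] <- 2
  per_trial[cs == "minus", "stim", 1] <- 0.5
  per_trial[cs == "minus", "trace", 1] <- 0.5
  per_trial[, , 2] <- -per_trial[, , 1]
  st <- list(per_trial = per_trial, cs = cs)
  ms <- modulation_scores(st)
  expect_equal(ms$scores$trial_type_score[1], 1.5)
  expect_equal(ms$scores$trial_type_score[2], -1.5)
  expect_equal(ms$selection$cs_plus_suppressed, 2L)
  expect_equal(ms$selection$cs_minus_suppressed, 1L)
  expect_equal(ms$selection$nonmodulated, 3L)
})

test_that("reactivation-modulation correlation guards its inputs", {
  expect_error(reactivation_vs_modulation(c(1, 2), c(1, 2)), "at least 3")
  r <- reactivation_vs_modulation(c(1, 1, 1), c(1, 2, 3))
  expect_true(r$degenerate)
  set.seed(10)
  x <- rnorm(30); y <- -2 * x + rnorm(30, sd = 0.1)
  rr <- reactivation_vs_modulation(x, y)
  expect_lt(rr$r, -0.9)
  expect_lt(rr$p_value, 1e-6)
})

test_that("MAD-based significance fraction handles tails and constants", {
  set.seed(11)
  v <- c(rnorm(900), rep(10, 100))
  f <- significant_reactivation_fraction(v)
  expect_lt(abs(f$fraction - 0.1), 0.02)
  fc <- significant_reactivation_fraction(rep(2, 50))
  expect_true(fc$mad_zero)
  expect_equal(fc$fraction, 0)
})

test_that("quadrant analysis handles comonotone and anti-correlated pairs", {
  v <- rnorm(100)
  co <- quadrant_coactivation(cbind(v), cbind(2 * v + 1))
  expect_equal(co$pairs$q1_pct, 50)
  expect_equal(co$pairs$q2_pct, 0)
  anti <- quadrant_coactivation(cbind(v), cbind(-v))
  expect_equal(anti$pairs$q1_pct, 0)
  expect_error(quadrant_coactivation(cbind(v[1:5]), cbind(v[1:5])),
               "at least 10")
})
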