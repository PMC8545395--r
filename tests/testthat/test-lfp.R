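# Ripple-band preprocessing, ripple detection and multitaper coherence.

ripple_burst <- function(n, fs, t0, amp, freq = 180, env_sd = 0.015) {
  tt <- (seq_len(n) / fs) - t0
  amp * exp(-0.5 * (tt / env_sd)^2) * cos(2 * pi * freq * tt)
}

test_that("common average reference removes the common mode", {
  fs <- 2000
  tt <- seq_len(2 * fs) / fs
  common <- 50 * sin(2 * pi * 200 * tt)
  lfp <- t(matrix(common, ncol = 4, nrow = length(tt)))
  out <- preprocess_ripple_band(lfp, fs)
  expect_lt(max(abs(out)), 1e-6)
  # a single-channel 200 Hz component survives (minus 1/n leakage)
  lfp1 <- matrix(0, 4, length(tt))
  lfp1[2, ] <- common
  out1 <- preprocess_ripple_band(lfp1, fs)
  mid <- seq(fs - 200, fs + 200)
  expect_gt(max(out1[2, mid]), 50 * 0.6)
  # out-of-band 50 Hz attenuated by >= 40 dB
  low <- 100 * sin(2 * pi * 50 * tt)
  lfp2 <- rbind(low, -low)
  out2 <- preprocess_ripple_band(lfp2, fs)
  expect_lt(max(abs(out2[, mid])), 100 / 100)
})

test_that("lean channel path matches the full preprocessing matrix", {
  set.seed(20)
  fs <- 2000
  lfp <- matrix(rnorm(6 * fs * 4, sd = 30), 6)
  lfp[4, ] <- lfp[4, ] + ripple_burst(ncol(lfp), fs, 2, 300)
  full <- preprocess_ripple_band(lfp, fs)
  ch_full <- select_ripple_channel(full)
  lean <- ripple_band_channel(lfp, fs)
  expect_equal(lean$channel, ch_full)
  expect_equal(lean$trace, full[ch_full, ], tolerance = 1e-8)
  expect_equal(lean$power, rowMeans(full^2), tolerance = 1e-8)
})

test_that("ripple channel selection takes the strongest, ties to lowest", {
  x <- matrix(rnorm(3 * 1000), 3, 1000)
  x[2, ] <- x[2, ] * 3
  expect_equal(select_ripple_channel(x), 2L)
  y <- matrix(1, 4, 100)
  expect_equal(select_ripple_channel(y), 1L)
})

test_that("ripple detector applies amplitude, refractory and lick rules", {
  fs <- 2000
  dur <- 60
  n <- dur * fs
  x <- numeric(n)
  ripple_t <- c(5, 10, 15, 20, 25, 30)
  for (t0 in ripple_t) x <- x + ripple_burst(n, fs, t0, 200)
  x <- x + ripple_burst(n, fs, 35, 700)          # artifact
  x <- x + ripple_burst(n, fs, 40, 200)          # near a lick
  x <- x + ripple_burst(n, fs, 45, 200) + ripple_burst(n, fs, 45.15, 200)
  ev <- detect_ripples(x, fs, licks = c(40.1), trials = NULL)
  ret <- ev[ev$retained, ]
  expect_equal(sum(ev$artifact_excluded), 1L)
  expect_equal(sum(ev$near_lick_excluded), 1L)
  expect_equal(sum(ev$merged), 1L)               # 45.15 dropped, keep-first
  expect_equal(nrow(ret), 7L)                    # 6 planted + first of pair
  expect_true(all(diff(ret$time_s) >= 0.2))
  expect_true(all(ret$amp_uv >= 100 & ret$amp_uv < 500))
  expect_true(all(abs(sort(ret$time_s) - c(ripple_t, 45)) < 0.01))
})

test_that("ripple rates recover the planted ITI event rate", {
  ss <- lfp_session()
  filt <- preprocess_ripple_band(ss$bundle$lfp$CA1$data,
                                 ss$bundle$meta$fs_lfp_hz)
  ch <- select_ripple_channel(filt)
  ev <- detect_ripples(filt[ch, ], ss$bundle$meta$fs_lfp_hz,
                       ss$bundle$licks, ss$bundle$trials)
  rr <- ripple_rate_dynamics(ev, ss$bundle$trials,
                             ss$bundle$meta$duration_s)
  n_iti <- sum(ev$retained & ev$in_iti)
  expect_gt(rr$period_rates[["iti"]], 0.04)      # planted 0.12 Hz process
  expect_lt(rr$period_rates[["iti"]], 0.25)
  # empty input gives all-zero rates
  empty <- detect_ripples(numeric(2000), 2000)
  rr0 <- ripple_rate_dynamics(empty, ss$bundle$trials,
                              ss$bundle$meta$duration_s)
  expect_true(all(rr0$period_rates == 0))
})

test_that("coherence is 1 for identical signals and bounded for noise", {
  set.seed(6)
  fs <- 500
  x <- rnorm(fs * 40)
  segs <- cbind(seq(0.5, 35, by = 1.5), seq(1.5, 36, by = 1.5))
  co <- multitaper_coherence(x, x, fs, segs)
  expect_true(all(abs(co$coherence - 1) < 1e-8))
  y <- rnorm(fs * 40)
  co2 <- multitaper_coherence(x, y, fs, segs)
  expect_true(all(co2$coherence >= 0 & co2$coherence <= 1))
  expect_lt(mean(co2$coherence), 0.25)           # estimator bias floor
  # invariance under scalar scaling of either signal
  co3 <- multitaper_coherence(5 * x, 0.2 * y, fs, segs)
  expect_equal(co3$coherence, co2$coherence)
  expect_error(multitaper_coherence(x, y, fs, cbind(0.5, 0.51)),
               "too short")
})

test_that("permutation test rejects planted differences, not null ones", {
  set.seed(7)
  fs <- 500; n <- fs * 120
  x <- rnorm(n); y <- rnorm(n)
  seg_a <- cbind(seq(1, 50, by = 2), seq(2, 51, by = 2))
  seg_b <- seg_a + 60
  sh <- condpipe:::bandlimited_noise(n, fs, c(75, 85)) * 3
  mask <- numeric(n)
  for (i in seq_len(nrow(seg_a)))
    mask[(seg_a[i, 1] * fs):(seg_a[i, 2] * fs)] <- 1
  pt <- per_frequency_permutation_test(x + sh * mask, y + sh * mask, fs,
                                       seg_a, seg_b, n_perm = 200)
  i80 <- which.min(abs(pt$freq - 80))
  expect_true(pt$significant[i80])
  expect_gt(pt$coh_a[i80] - pt$coh_b[i80], 0.5)
  pt0 <- per_frequency_permutation_test(x, y, fs, seg_a, seg_b,
                                        n_perm = 200)
  expect_lt(mean(pt0$significant), 0.15)         # false positives near alpha
  expect_error(per_frequency_permutation_test(x, y, fs, seg_a, seg_b,
                                              n_perm = 0), "n_perm")
})
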