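# Binning, smoothing, z-scoring and the response taxonomy.

test_that("smoothing kernel is normalized and preserves per-trial counts", {
  k <- condpipe:::gaussian_kernel(25)
  expect_equal(sum(k), 1)
  expect_equal(k, rev(k))
  # a single spike without smoothing lands in exactly one bin
  b <- bin_and_smooth(list(c(10.26)), alignment_times = 10,
                      window = c(0, 1), bin_width = 0.025, smooth_bins = 0)
  counts <- b$rates[1, , 1] * 0.025
  expect_equal(sum(counts), 1)
  expect_equal(which(counts == 1), 11L)
  # smoothing redistributes but conserves the total
  set.seed(1)
  spikes <- list(sort(runif(200, 10, 11)))
  bs <- bin_and_smooth(spikes, 10, window = c(0, 1), smooth_bins = 25)
  expect_equal(sum(bs$rates[1, , 1]) * 0.025, 200)
})

test_that("a homogeneous Poisson unit has a flat PSTH at its rate", {
  set.seed(2)
  dur <- 1000
  spikes <- list(sort(runif(rpois(1, 10 * dur), 0, dur)))
  al <- seq(5, dur - 5, by = 8)
  b <- bin_and_smooth(spikes, al, window = c(-1, 1))
  p <- psth(b)
  sem <- sqrt(10 / (0.025 * length(al)))   # per-bin SEM before smoothing
  expect_true(all(abs(p - 10) < 3 * sem))
})

test_that("z-scoring uses baseline statistics and flags degenerate units", {
  time <- seq(-0.9875, 3.9875, by = 0.025)
  n_bins <- length(time)
  base <- time < 0
  x <- rep(5, n_bins)
  x[base] <- 5 + rep(c(-1, 1), length.out = sum(base))  # mean 5, sd ~1
  x[time >= 2 & time < 3] <- 8
  sd_base <- sd(x[base])
  z <- zscore_to_baseline(cbind(x, 0), time)
  expect_equal(unname(z$z[time >= 2 & time < 3, 1]),
               rep((8 - 5) / sd_base, 40))
  expect_equal(mean(z$z[base, 1]), 0)
  expect_true(z$excluded[2])               # all-zero unit flagged
  expect_true(all(is.na(z$z[, 2])))
})

test_that("z-scores are invariant under per-unit rate scaling", {
  time <- seq(-0.9875, 1.9875, by = 0.025)
  x <- 4 + sin(seq_along(time) / 5)
  z1 <- zscore_to_baseline(cbind(x), time)$z
  z3 <- zscore_to_baseline(cbind(3 * x), time)$z
  expect_equal(z1, z3, ignore_attr = TRUE)
})

test_that("classification recovers planted response classes", {
  ss <- post_session()
  cls <- classify_response_windows(ss$bundle)
  correct <- 0L; total <- 0L
  for (a in c("CA1", "PFC")) {
    planted <- ss$truth$unit_class[[a]]
    ca <- cls[cls$area == a, ]
    hit <- vapply(seq_along(planted), function(u) {
      switch(planted[u],
             trace_up = isTRUE(ca$trace_up[u]),
             trace_down = isTRUE(ca$trace_down[u]),
             lick = isTRUE(ca$lick_up[u]),
             evoked = isTRUE(ca$evoked_z_plus[u] >= 1),
             reward = isTRUE(ca$reward_z_plus[u] >= 1),
             unmodulated = !isTRUE(ca$trace_up[u]) &&
               !isTRUE(ca$trace_down[u]) && !isTRUE(ca$lick_up[u]) &&
               !isTRUE(ca$lick_down[u]))
    }, logical(1))
    correct <- correct + sum(hit); total <- total + length(hit)
  }
  expect_gte(correct / total, 0.8)
  # lick cells are rare, so the non-lick population stays large
  expect_gte(sum(nonlick_units(cls)), 0.6 * nrow(cls))
})

test_that("false trace flags on unmodulated units match the 1 SD tail", {
  ss <- null_session(211)
  cls <- classify_response_windows(ss$bundle)
  flag_rate <- mean(cls$trace_up | cls$trace_down)
  # mean z over ~2 effective independent baseline-scaled bins, two CS
  # types: expect a generous tail but far from catching everything
  expect_lt(flag_rate, 0.6)
})

test_that("group score summaries compare groups with rank tests", {
  set.seed(3)
  df <- data.frame(score = c(rnorm(30, 2), rnorm(30, 0)),
                   grp = rep(c("post", "pre"), each = 30))
  g <- group_window_scores(df, "score", "grp")
  expect_equal(nrow(g$summary), 2L)
  expect_lt(g$comparisons$p_value, 0.001)
  # single-member group excluded
  df1 <- rbind(df, data.frame(score = 1, grp = "solo"))
  g1 <- group_window_scores(df1, "score", "grp")
  expect_false("solo" %in% g1$summary$group)
})
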