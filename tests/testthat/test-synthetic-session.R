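# Synthetic-session generator: schedule, licking, spiking and determinism.

test_that("trial schedule respects ITI bounds, CS counts and reward timing", {
  spec <- session_spec(seed = 1, include_lfp = FALSE)
  set.seed(1)
  tr <- generate_trial_schedule(spec)
  expect_equal(nrow(tr), 100L)
  expect_equal(sum(tr$cs_type == "plus"), 50L)
  itis <- diff(tr$onset_s)
  expect_true(all(itis >= 30 & itis <= 45))
  expect_equal(tr$reward_time_s[tr$cs_type == "plus"],
               tr$onset_s[tr$cs_type == "plus"] + 3)
  expect_true(all(is.na(tr$reward_time_s[tr$cs_type == "minus"])))

  single <- session_spec(seed = 2, n_trials_csplus = 1, n_trials_csminus = 0,
                         include_lfp = FALSE)
  set.seed(2)
  tr1 <- generate_trial_schedule(single)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$reward_time_s, tr1$onset_s + 3)
})

test_that("identical spec and seed reproduce a byte-identical session", {
  spec <- session_spec(seed = 7, n_units_ca1 = 8, n_units_pfc = 6,
                       n_trials_csplus = 5, n_trials_csminus = 5,
                       iti_range_s = c(8, 10), n_lfp_channels_ca1 = 4,
                       ripple_peak_channel = 2)
  s1 <- generate_session(spec)
  s2 <- generate_session(spec)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  expect_setequal(names(s1$bundle$spikes), c("CA1", "PFC"))
})

test_that("post-stage licking is classified learned, pre-stage is not", {
  flags <- vapply(1:60, function(s) {
    spec <- session_spec(seed = s, stage = if (s %% 2) "post" else "pre",
                         n_trials_csplus = 25, n_trials_csminus = 25,
                         iti_range_s = c(8, 10), include_lfp = FALSE)
    set.seed(s)
    tr <- generate_trial_schedule(spec)
    dur <- tr$onset_s[nrow(tr)] + 10
    lk <- generate_licks(tr, spec$stage, spec, dur)
    bundle <- list(trials = tr, licks = lk$times,
                   meta = list(duration_s = dur))
    classify_bundle_learning(bundle)$learned
  }, logical(1))
  post <- flags[seq(1, 60, by = 2)]
  pre <- flags[seq(2, 60, by = 2)]
  expect_gte(mean(post), 0.95)
  expect_lt(mean(pre), 0.10)
})

test_that("no trials produce no lick bouts", {
  spec <- session_spec(seed = 3, include_lfp = FALSE)
  lk <- generate_licks(data.frame(onset_s = numeric(0),
                                  cs_type = character(0),
                                  reward_time_s = numeric(0)),
                       "post", spec, 100)
  expect_length(lk$times, 0L)
})

test_that("unmodulated unit spike count matches the Poisson expectation", {
  spec <- session_spec(
    seed = 11, n_units_ca1 = 4, n_units_pfc = 0, n_trials_csplus = 10,
    n_trials_csminus = 10, iti_range_s = c(28, 32), include_lfp = FALSE,
    assembly_defs = list(), comm_rank = 0, within_rank = 0,
    effects_hz = c(evoked = 0, evoked_global = 0, trace_up = 0,
                   trace_down = 0, lick = 0, reward = 0))
  ss <- generate_session(spec)
  dur <- ss$bundle$meta$duration_s
  counts <- lengths(ss$bundle$spikes$CA1)
  expected <- 5 * dur
  # 4 units, each within 4 SD of the Poisson mean
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("planted assembly members co-fire above the non-member background", {
  ss <- assembly_session(seed = 31, n_assemblies = 1L, n_units = 20L)
  members <- ss$truth$assemblies[[1]]$members
  dur <- ss$bundle$meta$duration_s
  n_bins <- floor(dur / 0.02)
  counts <- vapply(ss$bundle$spikes$CA1, function(su)
    as.numeric(condpipe:::bin_counts(su, 0, n_bins, 0.02)), numeric(n_bins))
  cm <- cor(counts)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  is_member_pair <- pairs[, 1] %in% members & pairs[, 2] %in% members
  r <- cm[upper.tri(cm)]
  expect_gt(median(r[is_member_pair]),
            quantile(r[!is_member_pair], 0.99))
})

test_that("trace-down units fire below baseline by the planted effect", {
  ss <- post_session()
  idx <- which(ss$truth$unit_class$CA1 == "trace_down")
  tr <- ss$bundle$trials
  on_p <- tr$onset_s[tr$cs_type == "plus"]
  rate_in <- function(su, t0, t1) {
    mean(vapply(seq_along(t0), function(i)
      sum(su >= t0[i] & su < t1[i]), numeric(1))) / (t1[1] - t0[1])
  }
  rates_trace <- vapply(ss$bundle$spikes$CA1[idx], rate_in,
                        numeric(1), on_p + 2, on_p + 3)
  # planted: 5 Hz baseline minus 2 Hz suppression (latent drive adds noise)
  expect_lt(mean(rates_trace), 4)
  expect_gt(mean(rates_trace), 2)
})

test_that("session bundles satisfy their invariants", {
  ss <- lfp_session()
  expect_equal(nrow(validate_bundle(ss$bundle)), 0L)
  expect_true(!is.unsorted(ss$truth$ripple_times_s, strictly = TRUE))
  for (a in ss$truth$assemblies)
    expect_true(all(a$members >= 1 &
                      a$members <= length(ss$bundle$spikes[[a$area]])))
})
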