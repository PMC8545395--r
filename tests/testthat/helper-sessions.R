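# Shared fixtures: synthetic sessions are generated once per test run and
# memoized, since several files probe different aspects of the same bundle.

.session_cache <- new.env(parent = emptyenv())

memo_session <- function(name, maker) {
  if (is.null(.session_cache[[name]])) .session_cache[[name]] <- maker()
  .session_cache[[name]]
}

# Full-size post-learning session (default study conditions except a
# shortened ITI to keep the simulated recording compact), spikes only.
post_session <- function() {
  memo_session("post", function() {
    generate_session(session_spec(
      seed = 101, stage = "post", iti_range_s = c(10, 14),
      include_lfp = FALSE))
  })
}

# Matching pre-learning session.
pre_session <- function() {
  memo_session("pre", function() {
    generate_session(session_spec(
      seed = 102, stage = "pre", iti_range_s = c(10, 14),
      include_lfp = FALSE))
  })
}

# Planted-difference session for decoder power checks: full response
# classes, no latent common drive (CS-independent correlated noise) and
# no anticipatory licking, so no trace unit is excluded as a lick cell
# and the CS+/CS- trace difference is cleanly linearly separable.
decode_session <- function() {
  memo_session("decode", function() {
    generate_session(session_spec(
      seed = 103, stage = "post", iti_range_s = c(10, 14),
      include_lfp = FALSE, comm_rank = 0, within_rank = 0,
      anticipatory_prob = 0, baseline_lick_rate_hz = 0))
  })
}

# Effect-free session: no planted response classes, assemblies or latent
# drive; spiking carries no information about CS type.
null_session <- function(seed = 201) {
  generate_session(session_spec(
    seed = seed, stage = "pre", n_units_ca1 = 20, n_units_pfc = 0,
    n_trials_csplus = 50, n_trials_csminus = 50, iti_range_s = c(8, 10),
    include_lfp = FALSE, assembly_defs = list(), comm_rank = 0,
    within_rank = 0,
    effects_hz = c(evoked = 0, evoked_global = 0, trace_up = 0,
                   trace_down = 0, lick = 0, reward = 0)))
}

# Session isolating fine-timescale assembly structure (no latent drive).
assembly_session <- function(seed = 301, n_assemblies = 3L,
                             n_units = 34L, couplings = NULL) {
  defs <- lapply(seq_len(n_assemblies), function(i)
    list(area = "CA1", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = c("cs_plus", "cs_minus", "none")[(i - 1L) %% 3L + 1L],
         bias_gain = 3, ripple_coupling =
           if (is.null(couplings)) 0 else couplings[i]))
  generate_session(session_spec(
    seed = seed, stage = "post", n_units_ca1 = n_units, n_units_pfc = 0,
    iti_range_s = c(10, 14), include_lfp = FALSE, assembly_defs = defs,
    comm_rank = 0, within_rank = 0))
}

# Small two-area session with LFP for pipeline / ripple tests.
lfp_session <- function() {
  memo_session("lfp", function() {
    generate_session(session_spec(
      seed = 401, stage = "post", n_units_ca1 = 12, n_units_pfc = 8,
      n_trials_csplus = 8, n_trials_csminus = 8, iti_range_s = c(12, 16),
      ripple_rate_hz = 0.12, assembly_defs = list(), comm_rank = 0,
      within_rank = 0))
  })
}

# Ground-truth ITI mask for ripple times.
iti_ripples <- function(truth, trials) {
  rt <- truth$ripple_times_s
  keep <- vapply(rt, function(t)
    !any(t >= trials$onset_s - 1 & t <= trials$onset_s + 4), logical(1))
  rt[keep]
}

# Ground-truth weight matrix for one area's planted assemblies.
truth_weights <- function(truth, area = "CA1") {
  defs <- Filter(function(a) a$area == area, truth$assemblies)
  if (!length(defs)) return(matrix(numeric(0), 0L, 0L))
  vapply(defs, function(a) a$weights, numeric(length(defs[[1]]$weights)))
}
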