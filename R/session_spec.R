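#' Specification of a synthetic conditioning session
#'
#' Builds the parameter set from which [generate_session()] simulates one
#' head-fixed appetitive auditory trace-conditioning session: interleaved
#' CS+/CS- trials (2 s sound, 1 s silent trace, reward at +3 s on CS+
#' trials), learning-dependent anticipatory licking, Poisson spiking units
#' with planted response classes, planted synchronous cell assemblies,
#' ripple-bearing multichannel CA1 LFP and one PFC LFP channel sharing a
#' band-limited component with CA1 during trials.
#'
#' Defaults are the study conditions the pipeline is designed for: 50 CS+
#' and 50 CS- trials, inter-trial intervals drawn uniformly from 30-45 s,
#' 34 CA1 / 54 PFC units at 5 Hz baseline, 16 CA1 LFP channels at 2 kHz,
#' awake ripples at 0.09 Hz with 200 uV amplitude.
#'
#' @param seed integer RNG seed; the whole session is a deterministic
#'   function of the spec including this seed.
#' @param stage `"pre"` or `"post"` learning. Post sessions have
#'   anticipatory lick bouts on most CS+ trials and full-strength trace and
#'   CS-discriminating evoked modulation; pre sessions lick only after
#'   reward and carry no trace modulation.
#' @param n_units_ca1,n_units_pfc unit counts per area (PFC may be 0 to
#'   simulate a CA1-only session).
#' @param n_trials_csplus,n_trials_csminus trial counts per CS type.
#' @param iti_range_s length-2 vector, uniform range of CS-onset-to-onset
#'   intervals in seconds.
#' @param fs_lfp_hz LFP sampling rate (Hz).
#' @param n_lfp_channels_ca1 number of CA1 LFP channels.
#' @param ripple_peak_channel channel index on which the planted ripple
#'   depth profile peaks.
#' @param baseline_rate_hz baseline Poisson rate of every unit (Hz).
#' @param response_classes list with elements `ca1` and `pfc`, each a named
#'   fraction vector over `evoked`, `trace_up`, `trace_down`, `lick`,
#'   `reward`; the remainder of each area is unmodulated. Fractions must
#'   sum to <= 1.
#' @param effects_hz named vector of response effect sizes in Hz:
#'   `evoked` (class-specific 0-350 ms response), `evoked_global`
#'   (small sound-evoked gain shared by all units), `trace_up`,
#'   `trace_down`, `lick`, `reward`.
#' @param assembly_defs list of planted assemblies; each element is a list
#'   with fields `area` ("CA1"/"PFC"), `n_members` (or explicit `members`
#'   unit indices), `event_rate_hz`, `p_member` (per-member participation
#'   probability per event), `bias` ("none", "cs_plus" or "cs_minus"),
#'   `bias_gain` (event-rate multiplier inside the biased 0-3 s trial
#'   window; values below 1 suppress the assembly there) and
#'   `ripple_coupling` (probability that a ripple triggers an assembly
#'   event).
#' @param ripple_rate_hz,ripple_amp_uv,ripple_freq_hz awake ripple process
#'   rate, planted envelope amplitude (uV) and carrier frequency (must lie
#'   in 150-300 Hz).
#' @param n_artifacts,artifact_amp_uv number and amplitude of planted
#'   high-amplitude artifact transients in the CA1 LFP.
#' @param comm_rank,comm_strength_hz rank and loading scale (Hz, SD) of the
#'   latent drive shared between CA1 and PFC spiking (the planted
#'   communication subspace).
#' @param within_rank,within_strength_hz rank and scale of per-area latent
#'   drive shared among units of the same area only.
#' @param shared_band_hz,shared_gain_uv band (Hz) and amplitude (uV, SD) of
#'   the LFP component shared between CA1 and PFC during trial periods
#'   (0-3 s from CS onset), creating cross-area coherence.
#' @param anticipatory_prob probability of an anticipatory lick bout on a
#'   post-learning CS+ trial.
#' @param bout_rate_hz lick rate within a bout.
#' @param anticipatory_window_s uniform range of bout-onset times relative
#'   to CS onset.
#' @param baseline_lick_rate_hz rate of sparse isolated licks outside bouts.
#' @param include_lfp logical; set `FALSE` to skip LFP synthesis when only
#'   spike-based analyses are needed.
#'
#' @return an object of class `session_spec` (a validated list).
#' @seealso [generate_session()]
#' @export
session_spec <- function(seed = 1L,
                         stage = c("post", "pre"),
                         n_units_ca1 = 34L,
                         n_units_pfc = 54L,
                         n_trials_csplus = 50L,
                         n_trials_csminus = 50L,
                         iti_range_s = c(30, 45),
                         fs_lfp_hz = 2000,
                         n_lfp_channels_ca1 = 16L,
                         ripple_peak_channel = 7L,
                         baseline_rate_hz = 5,
                         response_classes = list(
                           ca1 = c(evoked = 0.10, trace_up = 0.17, trace_down = 0.40,
                                   lick = 0.02, reward = 0.08),
                           pfc = c(evoked = 0.10, trace_up = 0.38, trace_down = 0.33,
                                   lick = 0.04, reward = 0.05)),
                         effects_hz = c(evoked = 6, evoked_global = 0.5,
                                        trace_up = 2, trace_down = 2,
                                        lick = 6, reward = 6),
                         assembly_defs = default_assembly_defs(),
                         ripple_rate_hz = 0.09,
                         ripple_amp_uv = 200,
                         ripple_freq_hz = 180,
                         n_artifacts = 2L,
                         artifact_amp_uv = 1200,
                         comm_rank = 2L,
                         comm_strength_hz = 1.5,
                         within_rank = 2L,
                         within_strength_hz = 1.5,
                         shared_band_hz = c(70, 90),
                         shared_gain_uv = 15,
                         anticipatory_prob = 0.9,
                         bout_rate_hz = 7,
                         anticipatory_window_s = c(2.0, 2.6),
                         baseline_lick_rate_hz = 0.05,
                         include_lfp = TRUE) {
  stage <- match.arg(stage)
  spec <- list(
    seed = as.integer(seed), stage = stage,
    n_units_ca1 = as.integer(n_units_ca1), n_units_pfc = as.integer(n_units_pfc),
    n_trials_csplus = as.integer(n_trials_csplus),
    n_trials_csminus = as.integer(n_trials_csminus),
    iti_range_s = as.numeric(iti_range_s),
    fs_lfp_hz = fs_lfp_hz, n_lfp_channels_ca1 = as.integer(n_lfp_channels_ca1),
    ripple_peak_channel = as.integer(ripple_peak_channel),
    baseline_rate_hz = baseline_rate_hz,
    response_classes = response_classes, effects_hz = effects_hz,
    assembly_defs = assembly_defs,
    ripple_rate_hz = ripple_rate_hz, ripple_amp_uv = ripple_amp_uv,
    ripple_freq_hz = ripple_freq_hz,
    n_artifacts = as.integer(n_artifacts), artifact_amp_uv = artifact_amp_uv,
    comm_rank = as.integer(comm_rank), comm_strength_hz = comm_strength_hz,
    within_rank = as.integer(within_rank), within_strength_hz = within_strength_hz,
    shared_band_hz = as.numeric(shared_band_hz), shared_gain_uv = shared_gain_uv,
    anticipatory_prob = anticipatory_prob, bout_rate_hz = bout_rate_hz,
    anticipatory_window_s = as.numeric(anticipatory_window_s),
    baseline_lick_rate_hz = baseline_lick_rate_hz,
    include_lfp = isTRUE(include_lfp))
  class(spec) <- "session_spec"
  validate_session_spec(spec)
  spec
}

#' Default planted assemblies: three in CA1 (a CS+-suppressed one with
#' strong ripple coupling, a CS--suppressed one with weaker coupling and
#' an unbiased, uncoupled one -- CA1 assemblies in this preparation are
#' suppressed during the stimulus, and the CS+-suppressed ones reactivate
#' most) and two in PFC (one ripple-coupled).
#' @return list of assembly definitions (see [session_spec()])
#' @export
default_assembly_defs <- function() {
  list(
    list(area = "CA1", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = "cs_plus", bias_gain = 0.3, ripple_coupling = 0.5),
    list(area = "CA1", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = "cs_minus", bias_gain = 0.3, ripple_coupling = 0.2),
    list(area = "CA1", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = "none", bias_gain = 1, ripple_coupling = 0),
    list(area = "PFC", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = "none", bias_gain = 1, ripple_coupling = 0.3),
    list(area = "PFC", n_members = 6L, event_rate_hz = 0.5, p_member = 0.8,
         bias = "none", bias_gain = 1, ripple_coupling = 0))
}

validate_session_spec <- function(spec) {
  stopifnot(spec$n_units_ca1 > 0L, spec$n_units_pfc >= 0L,
            spec$n_trials_csplus >= 0L, spec$n_trials_csminus >= 0L,
            spec$n_trials_csplus + spec$n_trials_csminus > 0L,
            length(spec$iti_range_s) == 2L,
            spec$fs_lfp_hz > 0, spec$n_lfp_channels_ca1 >= 2L,
            spec$ripple_peak_channel >= 1L,
            spec$ripple_peak_channel <= spec$n_lfp_channels_ca1,
            spec$baseline_rate_hz > 0, spec$ripple_amp_uv > 0)
  if (spec$iti_range_s[1] >= spec$iti_range_s[2])
    stop("iti_range_s must be an increasing pair")
  if (spec$ripple_freq_hz < 150 || spec$ripple_freq_hz > 300)
    stop("ripple_freq_hz must lie within the 150-300 Hz ripple band")
  for (a in c("ca1", "pfc")) {
    fr <- spec$response_classes[[a]]
    if (any(fr < 0) || sum(fr) > 1 + 1e-9)
      stop("response class fractions for ", a, " must be >= 0 and sum to <= 1")
  }
  for (ad in spec$assembly_defs) {
    if (!ad$area %in% c("CA1", "PFC")) stop("assembly area must be CA1 or PFC")
    if (ad$ripple_coupling < 0 || ad$ripple_coupling > 1)
      stop("ripple_coupling must be a probability")
  }
  invisible(spec)
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> stage=%s seed=%d  %d CA1 / %d PFC units, %d+%d trials\n",
              x$stage, x$seed, x$n_units_ca1, x$n_units_pfc,
              x$n_trials_csplus, x$n_trials_csminus))
  cat(sprintf("  ITI %g-%g s, LFP %g Hz x %d ch, ripples %g Hz @ %g uV, %d assemblies\n",
              x$iti_range_s[1], x$iti_range_s[2], x$fs_lfp_hz,
              x$n_lfp_channels_ca1, x$ripple_rate_hz, x$ripple_amp_uv,
              length(x$assembly_defs)))
  invisible(x)
}

# Learning-stage gain table for planted response classes. Post sessions
# express full trace modulation and a CS+ > CS- evoked difference in PFC
# (CS- responses shrink with learning); pre sessions have no trace
# modulation, CS-symmetric evoked responses (weaker in CA1) and stronger
# reward responses.
stage_gains <- function(stage, area, cs) {
  post <- identical(stage, "post")
  ev <- if (area == "CA1") {
    if (post) 1.0 else 0.5
  } else {
    if (post && cs == "minus") 0.3 else 1.0
  }
  list(evoked = ev,
       trace = if (post) 1.0 else 0.0,
       reward = if (post) 1.0 else 1.5)
}
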