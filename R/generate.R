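# Synthetic-session generation: trial schedule, licking, spike trains with
# planted response classes / assemblies / latent cross-area drive, and LFP
# with planted ripples, artifacts and a shared coherent component.

#' Generate an interleaved CS+/CS- trial schedule
#'
#' CS onsets are spaced by inter-trial intervals drawn uniformly from
#' `spec$iti_range_s`; CS order is randomized; every CS+ trial is rewarded
#' 3 s after onset (2 s sound + 1 s silent trace period).
#'
#' @param spec a [session_spec()]
#' @return data.frame with columns `onset_s`, `cs_type` ("plus"/"minus"),
#'   `reward_time_s` (NA on CS- trials)
#' @export
generate_trial_schedule <- function(spec) {
  n <- spec$n_trials_csplus + spec$n_trials_csminus
  itis <- stats::runif(n, spec$iti_range_s[1], spec$iti_range_s[2])
  onsets <- cumsum(itis)
  cs <- sample(rep(c("plus", "minus"),
                   times = c(spec$n_trials_csplus, spec$n_trials_csminus)))
  data.frame(onset_s = onsets, cs_type = cs,
             reward_time_s = ifelse(cs == "plus", onsets + 3, NA_real_))
}

session_duration <- function(spec, trials) {
  if (nrow(trials) == 0L) return(spec$iti_range_s[2])
  trials$onset_s[nrow(trials)] + spec$iti_range_s[2]
}

#' Generate lick times for a session
#'
#' Post-learning sessions produce anticipatory lick bouts (regular trains at
#' `spec$bout_rate_hz`) starting in the late stimulus / trace period on most
#' CS+ trials and merging into reward consumption; pre-learning sessions
#' lick only after reward delivery. Sparse isolated licks occur throughout.
#'
#' @param trials trial schedule from [generate_trial_schedule()]
#' @param stage "pre" or "post"
#' @param spec the [session_spec()]
#' @param duration_s session length in seconds
#' @return list with `times` (sorted lick times) and `bout_onsets`
#' @export
generate_licks <- function(trials, stage, spec, duration_s) {
  if (nrow(trials) == 0L) return(list(times = numeric(0), bout_onsets = numeric(0)))
  times <- list()
  bout_onsets <- numeric(0)
  bout_train <- function(t0, t1) {
    tt <- seq(t0, max(t0, t1), by = 1 / spec$bout_rate_hz)
    sort(tt + stats::rnorm(length(tt), 0, 0.005))
  }
  for (i in which(trials$cs_type == "plus")) {
    on <- trials$onset_s[i]
    rt <- trials$reward_time_s[i]
    consume_end <- rt + stats::runif(1, 1, 2)
    anticipatory <- identical(stage, "post") &&
      stats::runif(1) < spec$anticipatory_prob
    if (anticipatory) {
      t0 <- on + stats::runif(1, spec$anticipatory_window_s[1],
                              spec$anticipatory_window_s[2])
      times[[length(times) + 1L]] <- bout_train(t0, consume_end)
      bout_onsets <- c(bout_onsets, t0)
    } else {
      t0 <- rt + stats::runif(1, 0.05, 0.15)
      times[[length(times) + 1L]] <- bout_train(t0, consume_end)
      bout_onsets <- c(bout_onsets, t0)
    }
  }
  base <- poisson_times(spec$baseline_lick_rate_hz, 0, duration_s)
  all_licks <- sort(c(unlist(times), base))
  all_licks <- all_licks[all_licks > 0 & all_licks < duration_s]
  list(times = all_licks, bout_onsets = sort(bout_onsets))
}

# Awake ripple ground-truth times: homogeneous Poisson across the session,
# thinned so every planted ripple is detectable under the detector's rules
# (>= 250 ms apart, >= 250 ms from any lick, away from session edges).
generate_ripple_times <- function(spec, duration_s, lick_times) {
  cand <- poisson_times(spec$ripple_rate_hz, 2, duration_s - 2)
  if (length(cand) == 0L) return(numeric(0))
  if (length(lick_times) > 0L) {
    near <- vapply(cand, function(t) any(abs(lick_times - t) < 0.25), logical(1))
    cand <- cand[!near]
  }
  keep <- numeric(0)
  last <- -Inf
  for (t in cand) {
    if (t - last >= 0.25) { keep <- c(keep, t); last <- t }
  }
  keep
}

# Per-trial additive rate profiles (Hz) on the fine simulation grid.
# Window is [-1, 6] s around CS onset in 50 ms bins (140 bins).
.SIM_BIN <- 0.05
.SIM_W0 <- -1
.SIM_NB <- 140L

trial_bin_centers <- function() .SIM_W0 + (seq_len(.SIM_NB) - 0.5) * .SIM_BIN
trial_bin_starts <- function() .SIM_W0 + (seq_len(.SIM_NB) - 1) * .SIM_BIN

#' Generate spike trains with planted structure
#'
#' Every unit is an inhomogeneous Poisson process at
#' `spec$baseline_rate_hz`, modulated by its planted response class
#' (evoked 0-350 ms, trace up/down 2-3 s post CS+ onset, lick +-250 ms
#' around bout onsets, reward 0-0.5 s post reward), by a small
#' sound-evoked gain common to all units, and by low-rank latent drive
#' (within-area and cross-area). Planted assemblies superimpose excess
#' synchronous spikes within shared 20 ms windows at assembly event times,
#' biased to the configured trial period and coupled to ripples with the
#' configured probability.
#'
#' @param spec a [session_spec()]
#' @param trials trial schedule
#' @param licks list from [generate_licks()]
#' @param ripple_times ground-truth ripple times
#' @param duration_s session length (s)
#' @return list with `spikes` (list per area of per-unit sorted spike time
#'   vectors) and `truth` (unit classes, assembly memberships/weights and
#'   event times)
#' @export
generate_spike_trains <- function(spec, trials, licks, ripple_times, duration_s) {
  areas <- c("CA1", "PFC")[c(TRUE, spec$n_units_pfc > 0L)]
  n_units <- c(CA1 = spec$n_units_ca1, PFC = spec$n_units_pfc)
  n_tr <- nrow(trials)
  starts <- trial_bin_starts()
  centers <- trial_bin_centers()
  n_lat <- 70L                      # 100 ms latent bins across [-1, 6]
  lat_of_bin <- rep(seq_len(n_lat), each = 2L)

  # latent time courses, shared (comm) and per-area
  L_comm <- if (spec$comm_rank > 0L && n_tr > 0L)
    array(stats::rnorm(n_tr * n_lat * spec$comm_rank),
          dim = c(n_tr, n_lat, spec$comm_rank)) else NULL
  L_within <- lapply(areas, function(a) {
    if (spec$within_rank > 0L && n_tr > 0L)
      array(stats::rnorm(n_tr * n_lat * spec$within_rank),
            dim = c(n_tr, n_lat, spec$within_rank)) else NULL
  })
  names(L_within) <- areas

  class_levels <- c("evoked", "trace_up", "trace_down", "lick", "reward",
                    "unmodulated")
  eff <- spec$effects_hz
  spikes <- list()
  unit_class <- list()
  for (a in areas) {
    n <- n_units[[a]]
    fr <- spec$response_classes[[tolower(a)]]
    cnt <- floor(fr * n + 0.5)
    while (sum(cnt) > n) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    labels <- c(rep(names(cnt), times = cnt),
                rep("unmodulated", n - sum(cnt)))
    labels <- labels[sample.int(n)]
    cls_id <- match(labels, class_levels)

    W_comm <- if (!is.null(L_comm))
      matrix(stats::rnorm(n * spec$comm_rank, sd = spec$comm_strength_hz),
             n, spec$comm_rank) else NULL
    W_win <- if (!is.null(L_within[[a]]))
      matrix(stats::rnorm(n * spec$within_rank, sd = spec$within_strength_hz),
             n, spec$within_rank) else NULL

    unit_times <- vector("list", n)
    for (u in seq_len(n)) unit_times[[u]] <- vector("list", n_tr + 8L)

    for (i in seq_len(n_tr)) {
      on <- trials$onset_s[i]
      cs <- trials$cs_type[i]
      g <- stage_gains(spec$stage, a, cs)
      prof <- matrix(0, .SIM_NB, length(class_levels))
      ev_bins <- starts >= 0 & starts < 0.35
      tr_bins <- starts >= 2 & starts < 3
      prof[ev_bins, 1L] <- eff[["evoked"]] * g$evoked
      if (cs == "plus") {
        prof[tr_bins, 2L] <- eff[["trace_up"]] * g$trace
        prof[tr_bins, 3L] <- -eff[["trace_down"]] * g$trace
        rw_bins <- starts >= 3 & starts < 3.5
        prof[rw_bins, 5L] <- eff[["reward"]] * g$reward
      }
      # lick responses lock to bout onsets wherever they fall in the window
      bouts <- licks$bout_onsets[licks$bout_onsets > on - 1.25 &
                                 licks$bout_onsets < on + 6.25]
      for (b in bouts) {
        lk <- abs(centers - (b - on)) <= 0.25
        prof[lk, 4L] <- eff[["lick"]]
      }
      R <- matrix(spec$baseline_rate_hz, .SIM_NB, n)
      R <- R + prof[, cls_id, drop = FALSE]
      R[ev_bins, ] <- R[ev_bins, ] + eff[["evoked_global"]] * g$evoked
      if (!is.null(W_comm))
        R <- R + (matrix(L_comm[i, , ], n_lat) %*% t(W_comm))[lat_of_bin, , drop = FALSE]
      if (!is.null(W_win))
        R <- R + (matrix(L_within[[a]][i, , ], n_lat) %*% t(W_win))[lat_of_bin, , drop = FALSE]
      R[R < 0] <- 0
      # truncate at the next trial's window start so coverage never overlaps
      lim <- if (i < n_tr) trials$onset_s[i + 1L] - 1 else duration_s
      C <- matrix(stats::rpois(.SIM_NB * n, as.vector(R) * .SIM_BIN), .SIM_NB, n)
      nz <- which(C > 0L)
      if (length(nz)) {
        cval <- C[nz]
        brow <- (nz - 1L) %% .SIM_NB + 1L
        ucol <- (nz - 1L) %/% .SIM_NB + 1L
        tt <- on + starts[rep(brow, cval)] + stats::runif(sum(cval)) * .SIM_BIN
        uu <- rep(ucol, cval)
        ok <- tt < lim & tt >= 0 & tt < duration_s
        tt <- tt[ok]; uu <- uu[ok]
        sp <- split(tt, uu)
        for (nm in names(sp)) {
          u <- as.integer(nm)
          unit_times[[u]][[i]] <- sp[[nm]]
        }
      }
    }

    # homogeneous baseline spiking between trial windows
    w_start <- trials$onset_s - 1
    w_end <- pmin(trials$onset_s + 6,
                  c(trials$onset_s[-1] - 1, duration_s))
    seg_start <- c(0, w_end)
    seg_end <- c(w_start, duration_s)
    keep <- seg_end > seg_start
    seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
    for (u in seq_len(n)) {
      iti_sp <- unlist(lapply(seq_along(seg_start), function(s)
        poisson_times(spec$baseline_rate_hz, seg_start[s], seg_end[s])))
      unit_times[[u]][[n_tr + 1L]] <- iti_sp
    }
    spikes[[a]] <- lapply(unit_times, function(l) sort(unlist(l)))
    unit_class[[a]] <- labels
  }

  # planted assemblies: excess synchronous spikes in shared 20 ms windows
  assemblies <- list()
  for (ad in spec$assembly_defs) {
    a <- ad$area
    if (!a %in% areas) next
    n <- n_units[[a]]
    members <- if (!is.null(ad$members)) as.integer(ad$members) else
      sample.int(n, ad$n_members)
    ev <- poisson_times(ad$event_rate_hz, 0, duration_s)
    if (!identical(ad$bias, "none") && ad$bias_gain != 1 && n_tr > 0L) {
      want <- if (identical(ad$bias, "cs_plus")) "plus" else "minus"
      onb <- trials$onset_s[trials$cs_type == want]
      if (ad$bias_gain > 1) {
        for (on in onb)
          ev <- c(ev, poisson_times(ad$event_rate_hz * (ad$bias_gain - 1),
                                    on, on + 3))
      } else {
        # suppression: thin events inside the biased trial period
        inside <- vapply(ev, function(t)
          any(t >= onb & t < onb + 3), logical(1))
        drop <- inside & stats::runif(length(ev)) > ad$bias_gain
        ev <- ev[!drop]
      }
    }
    if (ad$ripple_coupling > 0 && length(ripple_times) > 0L) {
      hit <- stats::runif(length(ripple_times)) < ad$ripple_coupling
      ev <- c(ev, ripple_times[hit] + stats::runif(sum(hit), -0.005, 0.005))
    }
    ev <- sort(ev[ev > 0 & ev < duration_s - 0.02])
    for (t0 in ev) {
      part <- members[stats::runif(length(members)) < ad$p_member]
      if (length(part)) {
        add <- t0 + stats::runif(length(part), 0, 0.02)
        for (j in seq_along(part)) {
          u <- part[j]
          spikes[[a]][[u]] <- c(spikes[[a]][[u]], add[j])
        }
      }
    }
    w <- numeric(n); w[members] <- 1 / sqrt(length(members))
    assemblies[[length(assemblies) + 1L]] <-
      list(area = a, members = members, weights = w, event_times = ev,
           ripple_coupling = ad$ripple_coupling, bias = ad$bias)
  }
  for (a in areas) spikes[[a]] <- lapply(spikes[[a]], sort)

  list(spikes = spikes,
       truth = list(unit_class = unit_class, assemblies = assemblies))
}

# Band-limited Gaussian noise via FFT masking, unit SD. Works on a
# highly composite length (R's FFT is slow on awkward prime factors) and
# truncates back.
bandlimited_noise <- function(n, fs, band) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(n2)
  X <- stats::fft(x)
  f <- (seq_len(n2) - 1) * fs / n2
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / n2
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate session LFP with planted ripples and shared coherence component
#'
#' CA1 channels carry 1/f^2-like background noise (leaky-integrated white
#' noise), ripple bursts (Gaussian-enveloped carrier at
#' `spec$ripple_freq_hz`, ~75 ms long) with a Gaussian depth profile
#' peaking on `spec$ripple_peak_channel`, and optional high-amplitude
#' artifact transients with an alternating channel profile (so they
#' survive common-average referencing). The single PFC channel shares a
#' band-limited component with all CA1 channels during trial periods
#' (0-3 s from CS onset), creating cross-area coherence.
#'
#' @inheritParams generate_spike_trains
#' @return list with per-area `list(data = channels x samples matrix (uV),
#'   fs_hz)`, plus `artifact_times`
#' @export
generate_lfp <- function(spec, ripple_times, trials, licks, duration_s) {
  if (spec$ripple_amp_uv <= 0) stop("ripple_amp_uv must be > 0")
  fs <- spec$fs_lfp_hz
  n <- as.integer(round(duration_s * fs))
  nch <- spec$n_lfp_channels_ca1
  a_lp <- 1 - 2 * pi * 0.5 / fs            # pole at ~0.5 Hz -> 1/f^2 above
  sd_e <- 150 / sqrt(1 / (1 - a_lp^2))     # background SD ~150 uV
  bg_channel <- function() {
    as.numeric(stats::filter(stats::rnorm(n, sd = sd_e), a_lp,
                             method = "recursive"))
  }
  ca1 <- matrix(0, nch, n)
  for (ch in seq_len(nch)) ca1[ch, ] <- bg_channel()
  pfc <- bg_channel()

  # shared band-limited component during trial periods
  if (spec$shared_gain_uv > 0 && nrow(trials) > 0L) {
    shared <- bandlimited_noise(n, fs, spec$shared_band_hz) * spec$shared_gain_uv
    mask <- numeric(n)
    for (i in seq_len(nrow(trials))) {
      i0 <- max(1L, as.integer(round(trials$onset_s[i] * fs)))
      i1 <- min(n, as.integer(round((trials$onset_s[i] + 3) * fs)))
      if (i1 > i0) mask[i0:i1] <- 1
    }
    shared <- shared * mask
    for (chn in seq_len(nch)) ca1[chn, ] <- ca1[chn, ] + shared
    pfc <- pfc + shared
    rm(shared, mask)
  }

  profile <- exp(-0.5 * ((seq_len(nch) - spec$ripple_peak_channel) / 2)^2)
  burst_wave <- function(t0, amp, freq, env_sd) {
    i0 <- as.integer(round((t0 - 0.05) * fs))
    i1 <- as.integer(round((t0 + 0.05) * fs))
    if (i0 < 1L || i1 > n) return(NULL)
    tt <- (i0:i1) / fs - t0
    list(i0 = i0, i1 = i1,
         wave = amp * exp(-0.5 * (tt / env_sd)^2) *
           cos(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi)))
  }
  # bursts are added in the function body (not through a helper taking the
  # matrix) so the large LFP matrix is modified in place
  for (t0 in ripple_times) {
    b <- burst_wave(t0, spec$ripple_amp_uv, spec$ripple_freq_hz, 0.015)
    if (!is.null(b)) ca1[, b$i0:b$i1] <- ca1[, b$i0:b$i1] + outer(profile, b$wave)
  }

  artifact_times <- numeric(0)
  if (spec$n_artifacts > 0L) {
    gains <- rep(c(0, 1), length.out = nch)
    guard <- function(t) {
      (length(ripple_times) == 0L || min(abs(ripple_times - t)) > 1) &&
        (length(licks) == 0L || min(abs(licks - t)) > 0.5)
    }
    tries <- 0L
    while (length(artifact_times) < spec$n_artifacts && tries < 200L) {
      t0 <- stats::runif(1, 2, duration_s - 2)
      tries <- tries + 1L
      if (guard(t0) && (length(artifact_times) == 0L ||
                        min(abs(artifact_times - t0)) > 1)) {
        b <- burst_wave(t0, spec$artifact_amp_uv, 220, 0.01)
        if (!is.null(b))
          ca1[, b$i0:b$i1] <- ca1[, b$i0:b$i1] + outer(gains, b$wave)
        artifact_times <- c(artifact_times, t0)
      }
    }
    artifact_times <- sort(artifact_times)
  }

  list(CA1 = list(data = ca1, fs_hz = fs),
       PFC = list(data = matrix(pfc, 1L), fs_hz = fs),
       artifact_times = artifact_times)
}

#' Generate one complete synthetic session with ground truth
#'
#' Composes [generate_trial_schedule()], [generate_licks()], the ripple
#' process, [generate_spike_trains()] and [generate_lfp()] into a
#' `session_bundle` plus a `ground_truth` record. Deterministic given the
#' spec (including its seed).
#'
#' @param spec a [session_spec()]
#' @return list with elements `bundle` (class `session_bundle`) and
#'   `truth` (class `ground_truth`)
#' @export
generate_session <- function(spec) {
  validate_session_spec(spec)
  set.seed(spec$seed)
  trials <- generate_trial_schedule(spec)
  duration_s <- session_duration(spec, trials)
  licks <- generate_licks(trials, spec$stage, spec, duration_s)
  ripple_times <- generate_ripple_times(spec, duration_s, licks$times)
  spk <- generate_spike_trains(spec, trials, licks, ripple_times, duration_s)
  lfp <- if (spec$include_lfp)
    generate_lfp(spec, ripple_times, trials, licks$times, duration_s) else NULL

  bundle <- structure(list(
    spikes = spk$spikes,
    lfp = if (is.null(lfp)) NULL else lfp[c("CA1", "PFC")],
    trials = trials,
    licks = licks$times,
    meta = list(stage = spec$stage, areas = names(spk$spikes),
                duration_s = duration_s, seed = spec$seed,
                fs_lfp_hz = spec$fs_lfp_hz)),
    class = "session_bundle")
  truth <- structure(list(
    unit_class = spk$truth$unit_class,
    assemblies = spk$truth$assemblies,
    ripple_times_s = ripple_times,
    artifact_times_s = if (is.null(lfp)) numeric(0) else lfp$artifact_times,
    planted_comm_rank = spec$comm_rank,
    lick_bout_onsets_s = licks$bout_onsets,
    learned = identical(spec$stage, "post")),
    class = "ground_truth")
  list(bundle = bundle, truth = truth)
}

#' @export
print.session_bundle <- function(x, ...) {
  nu <- vapply(x$spikes, length, integer(1))
  cat(sprintf("<session_bundle> stage=%s, %.0f s, %d trials, units: %s%s\n",
              x$meta$stage, x$meta$duration_s, nrow(x$trials),
              paste(sprintf("%s=%d", names(nu), nu), collapse = " "),
              if (is.null(x$lfp)) ", no LFP" else ""))
  invisible(x)
}
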