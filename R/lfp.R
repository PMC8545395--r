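# Ripple-band preprocessing, awake ripple detection with exclusion rules,
# ripple rate dynamics, and multitaper CA1-PFC coherence with a
# per-frequency permutation test.

#' Band-pass filter to the ripple band and common-average reference
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass at
#' 150-300 Hz applied per channel, followed by subtraction of the
#' per-sample mean across channels (common average reference), which
#' removes common-mode artifacts.
#'
#' @param lfp channels x samples matrix (uV)
#' @param fs sampling rate (Hz)
#' @param band filter band (default c(150, 300) Hz)
#' @return filtered, referenced channels x samples matrix
#' @export
preprocess_ripple_band <- function(lfp, fs, band = c(150, 300)) {
  if (nrow(lfp) < 2L) stop("need at least 2 channels for the CAR")
  if (fs < 2 * band[2]) stop("sampling rate too low for the ripple band")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- t(apply(lfp, 1L, function(ch) signal::filtfilt(bf, ch)))
  sweep(out, 2L, colMeans(out))
}

#' Memory-lean ripple-band preprocessing and channel selection
#'
#' Equivalent to [preprocess_ripple_band()] followed by
#' [select_ripple_channel()], but never materializes the full filtered
#' matrix: because the band-pass is linear, the common average reference
#' equals subtracting the band-passed cross-channel mean, so channels are
#' filtered one at a time and only the winning trace is kept. Intended
#' for long multichannel recordings.
#'
#' @inheritParams preprocess_ripple_band
#' @return list with `channel` (selected index), `trace` (its filtered,
#'   referenced signal) and `power` (per-channel mean square)
#' @export
ripple_band_channel <- function(lfp, fs, band = c(150, 300)) {
  if (nrow(lfp) < 2L) stop("need at least 2 channels for the CAR")
  if (fs < 2 * band[2]) stop("sampling rate too low for the ripple band")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  m <- signal::filtfilt(bf, colMeans(lfp))
  power <- numeric(nrow(lfp))
  best <- NULL; best_ch <- 1L
  for (ch in seq_len(nrow(lfp))) {
    f <- signal::filtfilt(bf, lfp[ch, ]) - m
    power[ch] <- mean(f^2)
    if (ch == 1L || power[ch] > power[best_ch]) {
      best <- f; best_ch <- ch
    }
  }
  list(channel = best_ch, trace = best, power = power)
}

#' Select the channel with the strongest average ripple power
#'
#' @param filtered output of [preprocess_ripple_band()]
#' @return channel index (lowest index on ties)
#' @export
select_ripple_channel <- function(filtered) {
  power <- rowMeans(filtered^2)
  which.max(power)                      # which.max takes the first maximum
}

#' Detect awake sharp-wave ripples on one ripple-band channel
#'
#' Candidate events are contiguous epochs where the analytic-signal
#' envelope of the ripple-band trace crosses `low_cut`; each event is
#' stamped at the envelope peak. Events with peak amplitude >= `high_cut`
#' are rejected as artifacts; events within +-200 ms of any lick are
#' rejected; among the remainder, an event within 200 ms of the previous
#' retained event is dropped (keep-first refractory rule). Events are
#' labeled as inter-trial-interval (ITI) when they fall outside
#' `[onset - 1, onset + 4]` of every trial.
#'
#' @param filtered_channel ripple-band trace of the detection channel (uV)
#' @param fs sampling rate (Hz)
#' @param licks lick times (s)
#' @param trials trial schedule (may have zero rows)
#' @param low_cut detection threshold on the envelope (uV, default 100)
#' @param high_cut artifact-rejection threshold (uV, default 500)
#' @return object of class `ripple_events`: data.frame with `time_s`,
#'   `amp_uv`, `artifact_excluded`, `near_lick_excluded`, `merged`,
#'   `in_iti`, `retained`
#' @export
detect_ripples <- function(filtered_channel, fs, licks = numeric(0),
                           trials = NULL, low_cut = 100, high_cut = 500) {
  stopifnot(low_cut > 0, low_cut < high_cut)
  env <- Mod(analytic_signal(filtered_channel))
  above <- env >= low_cut
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) {
    ev <- data.frame(time_s = numeric(0), amp_uv = numeric(0),
                     artifact_excluded = logical(0),
                     near_lick_excluded = logical(0), merged = logical(0),
                     in_iti = logical(0), retained = logical(0))
    class(ev) <- c("ripple_events", "data.frame")
    return(ev)
  }
  peak_i <- vapply(runs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    i0 + which.max(env[i0:i1]) - 1L
  }, integer(1))
  time_s <- (peak_i - 0.5) / fs
  amp <- env[peak_i]
  artifact <- amp >= high_cut
  near_lick <- if (length(licks)) vapply(time_s, function(t)
    any(abs(licks - t) <= 0.2), logical(1)) else rep(FALSE, length(time_s))
  merged <- rep(FALSE, length(time_s))
  last <- -Inf
  for (i in order(time_s)) {
    if (artifact[i] || near_lick[i]) next
    if (time_s[i] - last < 0.2) merged[i] <- TRUE else last <- time_s[i]
  }
  in_iti <- rep(TRUE, length(time_s))
  if (!is.null(trials) && nrow(trials) > 0L) {
    in_iti <- vapply(time_s, function(t)
      !any(t >= trials$onset_s - 1 & t <= trials$onset_s + 4), logical(1))
  }
  ev <- data.frame(time_s = time_s, amp_uv = amp,
                   artifact_excluded = artifact,
                   near_lick_excluded = near_lick, merged = merged,
                   in_iti = in_iti,
                   retained = !artifact & !near_lick & !merged)
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("ripple_events", "data.frame")
  ev
}

#' Ripple rate per task period and per session block
#'
#' Rates (events/s) of retained ripples in the ITI, stimulus (0-2 s),
#' trace (2-3 s) and reward (3-3.5 s) windows, and per block of equal
#' trial count.
#'
#' @param events a `ripple_events` data.frame
#' @param trials trial schedule
#' @param duration_s session duration (s)
#' @param n_blocks number of equal-trial session blocks (default 10)
#' @return list with `period_rates` (named vector), `block` (data.frame
#'   block, n_events, duration_s, rate_hz)
#' @export
ripple_rate_dynamics <- function(events, trials, duration_s, n_blocks = 10L) {
  t_ev <- events$time_s[events$retained]
  on <- trials$onset_s
  n_tr <- length(on)
  in_any <- function(t, w0, w1) any(t >= on + w0 & t < on + w1)
  cnt <- function(w0, w1) sum(vapply(t_ev, in_any, logical(1), w0, w1))
  period_rates <- c(
    stim = if (n_tr) cnt(0, 2) / (2 * n_tr) else 0,
    trace = if (n_tr) cnt(2, 3) / (1 * n_tr) else 0,
    reward = if (n_tr) cnt(3, 3.5) / (0.5 * n_tr) else 0)
  trial_time <- 5 * n_tr                       # [-1, 4] around each onset
  iti_count <- sum(vapply(t_ev, function(t)
    !any(t >= on - 1 & t <= on + 4), logical(1)))
  period_rates <- c(period_rates,
                    iti = iti_count / max(duration_s - trial_time, 1e-9))
  block <- NULL
  if (n_tr >= n_blocks) {
    bid <- ceiling(seq_len(n_tr) / (n_tr / n_blocks))
    edges <- c(vapply(seq_len(n_blocks), function(b) min(on[bid == b]),
                      numeric(1)), duration_s)
    block <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      n_ev <- sum(t_ev >= edges[b] & t_ev < edges[b + 1])
      dur <- edges[b + 1] - edges[b]
      data.frame(block = b, n_events = n_ev, duration_s = dur,
                 rate_hz = n_ev / dur)
    }))
  }
  list(period_rates = period_rates, block = block)
}

# --- multitaper machinery ---------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the eigenvectors of the standard symmetric tridiagonal
#' matrix whose top eigenvectors are the DPSS sequences; tapers are
#' unit-norm with positive mean sign convention and cached per
#' (length, bandwidth) pair.
#'
#' @param n taper length in samples
#' @param nw time-bandwidth product (default 3)
#' @param k number of tapers (default 5; must be <= 2*nw - 1)
#' @return n x k matrix of tapers
#' @export
dpss_tapers <- function(n, nw = 3, k = 5L) {
  stopifnot(n >= 8L, k >= 1L, k <= 2 * nw - 1 + 1e-9)
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  tm <- diag(d)
  tm[cbind(seq_len(n - 1), 2:n)] <- e
  tm[cbind(2:n, seq_len(n - 1))] <- e
  eg <- eigen(tm, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

# Per-segment multitaper auto- and cross-spectra. `segments` is a 2-column
# matrix of start/end times (s); all segments are truncated to the length
# of the shortest. Returns freq, and freq x n_seg arrays sxx, syy, sxy.
mtm_segment_spectra <- function(x, y, fs, segments, nw = 3, k = 5L) {
  segments <- matrix(as.numeric(as.matrix(segments)), ncol = 2L)
  if (nrow(segments) == 0L) stop("no segments supplied")
  i0 <- pmax(1L, as.integer(round(segments[, 1] * fs)) + 1L)
  i1 <- pmin(length(x), as.integer(round(segments[, 2] * fs)))
  len <- min(i1 - i0 + 1L)
  if (len < 2L * k) stop("segments too short for ", k, " tapers")
  tap <- dpss_tapers(len, nw, k)
  nf <- len %/% 2L
  freq <- (seq_len(nf) - 1) * fs / len
  n_seg <- nrow(segments)
  sxx <- syy <- matrix(0, nf, n_seg)
  sxy <- matrix(complex(real = 0), nf, n_seg)
  for (s in seq_len(n_seg)) {
    xs <- x[i0[s]:(i0[s] + len - 1L)]; xs <- xs - mean(xs)
    ys <- y[i0[s]:(i0[s] + len - 1L)]; ys <- ys - mean(ys)
    for (j in seq_len(k)) {
      fx <- stats::fft(xs * tap[, j])[seq_len(nf)]
      fy <- stats::fft(ys * tap[, j])[seq_len(nf)]
      sxx[, s] <- sxx[, s] + Mod(fx)^2
      syy[, s] <- syy[, s] + Mod(fy)^2
      sxy[, s] <- sxy[, s] + fx * Conj(fy)
    }
  }
  list(freq = freq, sxx = sxx / k, syy = syy / k, sxy = sxy / k)
}

coherence_from_spectra <- function(sp, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(sp$sxx))
  num <- Mod(rowSums(sp$sxy[, cols, drop = FALSE]))
  den <- sqrt(rowSums(sp$sxx[, cols, drop = FALSE]) *
                rowSums(sp$syy[, cols, drop = FALSE]))
  num / pmax(den, .Machine$double.eps)
}

#' Multitaper magnitude coherence between two signals
#'
#' Slepian-taper cross-spectral estimate averaged over trial segments
#' (time-bandwidth product `nw`, `k` tapers per segment).
#'
#' @param x,y signals at the same sampling rate
#' @param fs sampling rate (Hz)
#' @param segments 2-column matrix or data.frame of segment start/end
#'   times (s)
#' @param nw time-bandwidth product (default 3)
#' @param k tapers per segment (default 5)
#' @param fmax upper frequency limit of the output (default 200 Hz)
#' @return object of class `coherence_result`: list with `freq`,
#'   `coherence` (magnitude, in [0, 1]), `n_segments`
#' @export
multitaper_coherence <- function(x, y, fs, segments, nw = 3, k = 5L,
                                 fmax = 200) {
  sp <- mtm_segment_spectra(x, y, fs, segments, nw, k)
  keep <- sp$freq <= fmax
  structure(list(freq = sp$freq[keep],
                 coherence = coherence_from_spectra(sp)[keep],
                 n_segments = ncol(sp$sxx), nw = nw, k = k),
            class = "coherence_result")
}

#' Per-frequency permutation test of a coherence difference
#'
#' Compares the segment-averaged coherence of two segment sets (e.g.
#' trace-period vs baseline segments, or CS+ vs CS- trials) by shuffling
#' segment condition labels; two-sided p-value per frequency with a
#' significance mask at `alpha`.
#'
#' @param x,y signals at the same sampling rate
#' @param fs sampling rate (Hz)
#' @param segments_a,segments_b 2-column matrices of segment times (s) for
#'   the two conditions (>= 5 segments each)
#' @param n_perm number of permutations (default 1000)
#' @param alpha significance level (default 0.05)
#' @inheritParams multitaper_coherence
#' @return data.frame with `freq`, `coh_a`, `coh_b`, `diff`, `p_value`,
#'   `significant`
#' @export
per_frequency_permutation_test <- function(x, y, fs, segments_a, segments_b,
                                           n_perm = 1000L, alpha = 0.05,
                                           nw = 3, k = 5L, fmax = 200) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  na <- nrow(as.matrix(segments_a)); nb <- nrow(as.matrix(segments_b))
  if (na < 5L || nb < 5L) stop("need at least 5 segments per condition")
  segs <- rbind(as.matrix(segments_a), as.matrix(segments_b))
  sp <- mtm_segment_spectra(x, y, fs, segs, nw, k)
  keep <- sp$freq <= fmax
  ia <- seq_len(na)
  coh_a <- coherence_from_spectra(sp, ia)[keep]
  coh_b <- coherence_from_spectra(sp, setdiff(seq_len(na + nb), ia))[keep]
  obs <- coh_a - coh_b
  exceed <- numeric(sum(keep))
  for (p in seq_len(n_perm)) {
    pa <- sample.int(na + nb, na)
    d <- coherence_from_spectra(sp, pa)[keep] -
      coherence_from_spectra(sp, setdiff(seq_len(na + nb), pa))[keep]
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  pval <- (exceed + 1) / (n_perm + 1)
  data.frame(freq = sp$freq[keep], coh_a = coh_a, coh_b = coh_b,
             diff = obs, p_value = pval, significant = pval < alpha)
}

#' Trial-period segments for coherence analysis
#'
#' Helper building (start, end) segment tables from a trial schedule for a
#' named task period.
#'
#' @param trials trial schedule
#' @param period one of "baseline", "stim", "trace", "reward"
#' @param cs optional CS-type filter ("plus"/"minus")
#' @return 2-column matrix of segment times (s)
#' @export
period_segments <- function(trials, period = c("baseline", "stim", "trace",
                                               "reward"), cs = NULL) {
  period <- match.arg(period)
  win <- switch(period, baseline = c(-1, 0), stim = c(0, 2),
                trace = c(2, 3), reward = c(3, 3.5))
  on <- trials$onset_s
  if (!is.null(cs)) on <- on[trials$cs_type == cs]
  cbind(on + win[1], on + win[2])
}
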