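# Binning, smoothing, z-scoring, PSTHs and the +-1 SD response taxonomy.

#' Bin spike trains around alignment events and smooth
#'
#' Spike counts in `bin_width`-wide bins across `window` (relative to each
#' alignment time) are convolved per trial with a normalized
#' Gaussian-weighted moving-average kernel (`smooth_bins` bins of support,
#' SD = `smooth_bins`/5, reflection padding, so per-trial totals are
#' preserved) and converted to rates in Hz.
#'
#' @param spikes list of per-unit sorted spike-time vectors (s)
#' @param alignment_times event times (s), one per trial
#' @param window length-2 vector, window around each event (s)
#' @param bin_width bin width in seconds (default 0.025)
#' @param smooth_bins Gaussian filter support in bins (default 25; 0
#'   disables smoothing)
#' @param t_max session duration; trials whose window exceeds
#'   `[0, t_max]` are dropped with a warning
#' @return object of class `binned_population`: list with `rates`
#'   (trials x bins x units array, Hz), `counts` kept implicitly via
#'   `rates * bin_width` when unsmoothed, `time` (bin centers),
#'   `bin_width_s`, `smooth_bins`, `alignment_times`
#' @export
bin_and_smooth <- function(spikes, alignment_times, window = c(-1, 4),
                           bin_width = 0.025, smooth_bins = 25L,
                           t_max = Inf) {
  stopifnot(length(window) == 2L, window[2] > window[1], bin_width > 0)
  ok <- alignment_times + window[1] >= 0 & alignment_times + window[2] <= t_max
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: window exceeds session bounds")
    alignment_times <- alignment_times[ok]
  }
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  n_tr <- length(alignment_times)
  n_u <- length(spikes)
  arr <- array(0, dim = c(n_tr, n_bins, n_u))
  for (u in seq_len(n_u)) {
    su <- spikes[[u]]
    for (i in seq_len(n_tr)) {
      arr[i, , u] <- bin_counts(su, alignment_times[i] + window[1],
                                n_bins, bin_width)
    }
  }
  if (smooth_bins > 0L && n_tr > 0L) {
    flat <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = n_bins)
    flat <- smooth_columns(flat, smooth_bins)
    arr <- aperm(array(flat, dim = c(n_bins, n_tr, n_u)), c(2L, 1L, 3L))
  }
  structure(list(rates = arr / bin_width,
                 time = window[1] + (seq_len(n_bins) - 0.5) * bin_width,
                 window = window, bin_width_s = bin_width,
                 smooth_bins = smooth_bins,
                 alignment_times = alignment_times,
                 dropped = sum(!ok)),
            class = "binned_population")
}

#' Trial-averaged PSTH matrix from a binned population
#'
#' @param binned a [bin_and_smooth()] result
#' @return bins x units matrix of mean rates (Hz)
#' @export
psth <- function(binned) {
  apply(binned$rates, c(2L, 3L), mean)
}

#' Z-score PSTHs to the pre-stimulus baseline
#'
#' Per unit, subtracts the mean and divides by the SD of the trial-averaged
#' baseline bins. Units with zero baseline SD are flagged and their z
#' columns set to NA rather than returning infinities.
#'
#' @param psth_mat bins x units PSTH matrix (Hz)
#' @param time bin-center times (s) matching rows
#' @param baseline_window length-2 window defining baseline bins
#'   (default (-1, 0) s)
#' @return list with `z` (bins x units), `excluded` (logical per unit),
#'   `baseline_mean`, `baseline_sd`
#' @export
zscore_to_baseline <- function(psth_mat, time, baseline_window = c(-1, 0)) {
  base <- time >= baseline_window[1] & time < baseline_window[2]
  if (!any(base)) stop("no baseline bins inside the PSTH window")
  m <- colMeans(psth_mat[base, , drop = FALSE])
  s <- apply(psth_mat[base, , drop = FALSE], 2L, stats::sd)
  excluded <- !is.finite(s) | s == 0
  z <- sweep(sweep(psth_mat, 2L, m), 2L, ifelse(excluded, NA, s), `/`)
  list(z = z, excluded = excluded, baseline_mean = m, baseline_sd = s)
}

window_mean <- function(mat, time, win) {
  sel <- time >= win[1] & time < win[2]
  colMeans(mat[sel, , drop = FALSE])
}

#' Single-cell response taxonomy for one session
#'
#' Computes z-scored CS-aligned PSTHs per unit and CS type and applies the
#' +-1 SD classification: `trace_up`/`trace_down` if the mean z in the
#' trace window (2-3 s post CS onset) is >= +1 / <= -1 in either CS+ or
#' CS- trials (thresholds inclusive); `evoked` and `reward` window scores
#' are the mean z in 0-0.35 s post CS and 3-3.5 s (0-0.5 s post reward).
#' Lick responsiveness compares the raw rate in -0.25..+0.25 s around the
#' first anticipatory lick with the pretrial baseline (-1..0 s before CS+
#' onset): a unit is `lick_up`/`lick_down` when the lick-window rate is at
#' least one SD above/below the mean of the per-trial baseline rates.
#'
#' @param bundle a `session_bundle`
#' @param first_licks optional result of [first_anticipatory_lick()]
#'   (computed if missing)
#' @param bin_width,smooth_bins binning parameters (see [bin_and_smooth()])
#' @return data.frame, one row per unit: `unit`, `area`, class flags
#'   (`evoked`, `trace_up`, `trace_down`, `lick_up`, `lick_down`), window
#'   scores per CS type, `baseline_excluded`, `lick_defined`
#' @export
classify_response_windows <- function(bundle, first_licks = NULL,
                                      bin_width = 0.025, smooth_bins = 25L) {
  if (is.null(first_licks)) first_licks <- first_anticipatory_lick(bundle)
  trials <- bundle$trials
  out <- list()
  for (a in names(bundle$spikes)) {
    sp <- bundle$spikes[[a]]
    zs <- list(); bl <- list()
    for (cs in c("plus", "minus")) {
      al <- trials$onset_s[trials$cs_type == cs]
      b <- bin_and_smooth(sp, al, window = c(-1, 4), bin_width = bin_width,
                          smooth_bins = smooth_bins,
                          t_max = bundle$meta$duration_s)
      p <- psth(b)
      zz <- zscore_to_baseline(p, b$time, c(-1, 0))
      zs[[cs]] <- list(z = zz$z, time = b$time, excluded = zz$excluded)
    }
    time <- zs$plus$time
    ev_p <- window_mean(zs$plus$z, time, c(0, 0.35))
    ev_m <- window_mean(zs$minus$z, time, c(0, 0.35))
    tr_p <- window_mean(zs$plus$z, time, c(2, 3))
    tr_m <- window_mean(zs$minus$z, time, c(2, 3))
    rw_p <- window_mean(zs$plus$z, time, c(3, 3.5))

    # lick criterion on raw rates, aligned to first anticipatory licks
    fl <- first_licks$first_lick_s[!is.na(first_licks$first_lick_s)]
    lick_defined <- length(fl) > 0L
    n_u <- length(sp)
    lick_up <- lick_down <- rep(NA, n_u)
    if (lick_defined) {
      lb <- bin_and_smooth(sp, fl, window = c(-0.5, 0.5),
                           bin_width = bin_width, smooth_bins = 0L,
                           t_max = bundle$meta$duration_s)
      lick_rate <- window_mean(psth(lb), lb$time, c(-0.25, 0.25))
      on_p <- trials$onset_s[trials$cs_type == "plus"]
      base_rate <- vapply(sp, function(su) {
        vapply(on_p, function(on) count_in_window(su, on - 1, on), numeric(1))
      }, numeric(length(on_p)))
      base_rate <- matrix(base_rate, nrow = length(on_p))
      bm <- colMeans(base_rate)
      bs <- apply(base_rate, 2L, stats::sd)
      lick_up <- lick_rate >= bm + bs
      lick_down <- lick_rate <= bm - bs
    }
    thr <- 1
    out[[a]] <- data.frame(
      unit = seq_along(sp), area = a,
      evoked = pmax(ev_p, ev_m, na.rm = TRUE) >= thr,
      trace_up = (tr_p >= thr | tr_m >= thr) %in% TRUE,
      trace_down = (tr_p <= -thr | tr_m <= -thr) %in% TRUE,
      lick_up = lick_up, lick_down = lick_down,
      evoked_z_plus = ev_p, evoked_z_minus = ev_m,
      trace_z_plus = tr_p, trace_z_minus = tr_m,
      reward_z_plus = rw_p,
      baseline_excluded = zs$plus$excluded | zs$minus$excluded,
      lick_defined = lick_defined)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Non-lick unit mask used by population analyses
#'
#' @param classification result of [classify_response_windows()], possibly
#'   subset to one area
#' @return logical vector: TRUE for units that are neither lick_up nor
#'   lick_down (undefined lick flags count as non-lick)
#' @export
nonlick_units <- function(classification) {
  up <- classification$lick_up %in% TRUE
  dn <- classification$lick_down %in% TRUE
  !(up | dn)
}

#' Group summary and rank-based comparison of window scores
#'
#' Mean +- SEM of a score per group plus two-sample Wilcoxon rank-sum tests
#' between all pairs of group levels. Groups with fewer than two finite
#' values (SEM undefined) are excluded.
#'
#' @param scores data.frame of per-unit scores
#' @param value name of the score column
#' @param group name of the grouping column
#' @return list with `summary` (group, n, mean, sem) and `comparisons`
#'   (group_a, group_b, p_value)
#' @export
group_window_scores <- function(scores, value, group) {
  v <- scores[[value]]
  g <- as.character(scores[[group]])
  keep <- is.finite(v)
  v <- v[keep]; g <- g[keep]
  levs <- unique(g)
  stats_tab <- do.call(rbind, lapply(levs, function(l) {
    x <- v[g == l]
    if (length(x) < 2L) return(NULL)
    data.frame(group = l, n = length(x), mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)))
  }))
  levs <- stats_tab$group
  comps <- list()
  if (length(levs) >= 2L) {
    for (i in seq_len(length(levs) - 1L)) for (j in (i + 1L):length(levs)) {
      p <- stats::wilcox.test(v[g == levs[i]], v[g == levs[j]],
                              exact = FALSE)$p.value
      comps[[length(comps) + 1L]] <-
        data.frame(group_a = levs[i], group_b = levs[j], p_value = p)
    }
  }
  list(summary = stats_tab,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}
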