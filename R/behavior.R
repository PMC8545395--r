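# Lick-based learning classification and anticipatory-lick detection.

#' Per-trial change in lick count, trace period minus baseline
#'
#' For each trial, counts licks in the trace period `[onset+2, onset+3)`
#' and subtracts the count in the pre-stimulus baseline `[onset-1, onset)`.
#' Windows are half-open so a lick exactly at the window edge is counted
#' once at most.
#'
#' @param bundle a `session_bundle`
#' @return data.frame with `trial`, `cs_type`, `lick_change`
#' @export
lick_rate_change_per_trial <- function(bundle) {
  trials <- bundle$trials
  licks <- bundle$licks
  ch <- vapply(seq_len(nrow(trials)), function(i) {
    on <- trials$onset_s[i]
    count_in_window(licks, on + 2, on + 3) - count_in_window(licks, on - 1, on)
  }, numeric(1))
  data.frame(trial = seq_len(nrow(trials)), cs_type = trials$cs_type,
             lick_change = ch)
}

#' Classify whether a session shows learned anticipatory licking
#'
#' Two-sample t-test of the per-trial lick-rate change between CS+ and CS-
#' trials; the session counts as learned when the difference is significant
#' at `alpha` and in the CS+ > CS- direction.
#'
#' @param changes numeric vector of per-trial lick changes
#' @param cs_labels matching character vector of "plus"/"minus"
#' @param alpha significance level (default 0.05)
#' @return list with `learned` (logical), `p_value`, `mean_plus`,
#'   `mean_minus`
#' @export
classify_session_learning <- function(changes, cs_labels, alpha = 0.05) {
  plus <- changes[cs_labels == "plus"]
  minus <- changes[cs_labels == "minus"]
  if (length(plus) < 2L || length(minus) < 2L)
    stop("need at least 2 trials of each CS type")
  p <- if (stats::sd(plus) == 0 && stats::sd(minus) == 0) {
    if (mean(plus) == mean(minus)) 1 else 0
  } else {
    stats::t.test(plus, minus)$p.value
  }
  list(learned = (p < alpha) && (mean(plus) > mean(minus)),
       p_value = p, mean_plus = mean(plus), mean_minus = mean(minus))
}

#' Learning classification of a whole session bundle
#'
#' Convenience wrapper: [lick_rate_change_per_trial()] followed by
#' [classify_session_learning()].
#'
#' @inheritParams lick_rate_change_per_trial
#' @param alpha significance level
#' @return list as in [classify_session_learning()] plus `changes`
#' @export
classify_bundle_learning <- function(bundle, alpha = 0.05) {
  ch <- lick_rate_change_per_trial(bundle)
  res <- classify_session_learning(ch$lick_change, ch$cs_type, alpha)
  res$changes <- ch
  res
}

#' First anticipatory lick per CS+ trial
#'
#' The first lick after CS+ onset and before reward delivery that is
#' followed by at least three further licks within the next second
#' (followers may fall after reward). `NA` when no lick qualifies.
#'
#' @param bundle a `session_bundle`
#' @return data.frame with `trial` (row index into the CS+ trials of the
#'   bundle's schedule), `onset_s`, `first_lick_s` (NA if absent)
#' @export
first_anticipatory_lick <- function(bundle) {
  trials <- bundle$trials
  licks <- bundle$licks
  idx <- which(trials$cs_type == "plus")
  out <- lapply(idx, function(i) {
    on <- trials$onset_s[i]
    rt <- trials$reward_time_s[i]
    if (is.na(rt)) rt <- on + 3
    cand <- licks[licks > on & licks < rt]
    hit <- NA_real_
    for (t0 in cand) {
      if (sum(licks > t0 & licks <= t0 + 1) >= 3L) { hit <- t0; break }
    }
    data.frame(trial = i, onset_s = on, first_lick_s = hit)
  })
  do.call(rbind, out)
}
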