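# Cell-assembly detection (PCA + Marcenko-Pastur threshold + ICA in the
# significant subspace), activation projection, ripple-triggered
# reactivation, within-session dynamics, modulation scores and CA1-PFC
# coactivation.

#' Marcenko-Pastur upper eigenvalue bound
#'
#' Analytic upper edge `(1 + sqrt(n_units / n_bins))^2` of the eigenvalue
#' distribution of a random correlation matrix; eigenvalues above it mark
#' significant coactivation structure.
#'
#' @param n_units number of units (matrix columns)
#' @param n_bins number of time bins (matrix rows); must exceed `n_units`
#' @return the bound (numeric scalar)
#' @export
mp_bound <- function(n_units, n_bins) {
  if (n_bins <= n_units)
    stop("n_bins must exceed n_units for the Marcenko-Pastur bound")
  (1 + sqrt(n_units / n_bins))^2
}

# Symmetric fixed-point FastICA with the cube nonlinearity on whitened
# data (samples x comps, identity covariance). Restarted `n_restarts`
# times; the run with the largest summed component kurtosis wins.
fastica_whitened <- function(xw, n_restarts = 5L, max_iter = 200L,
                             tol = 1e-6) {
  p <- ncol(xw)
  n <- nrow(xw)
  sym_orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  best <- NULL
  best_kurt <- -Inf
  for (r in seq_len(n_restarts)) {
    w <- sym_orth(matrix(stats::rnorm(p * p), p, p))
    for (it in seq_len(max_iter)) {
      s <- xw %*% w
      w_new <- sym_orth(crossprod(xw, s^3) / n - 3 * w)
      delta <- 1 - min(abs(colSums(w_new * w)))
      w <- w_new
      if (delta < tol) break
    }
    s <- xw %*% w
    kurt <- sum(abs(colMeans(s^4) - 3))
    if (kurt > best_kurt) { best_kurt <- kurt; best <- w }
  }
  best
}

#' Extract assembly patterns from a binned activity matrix
#'
#' Columns (units) are z-scored; the number of assemblies is the number of
#' correlation-matrix eigenvalues above the Marcenko-Pastur bound; the
#' data are projected onto the significant principal subspace, unmixed
#' with independent component analysis, and the resulting patterns are
#' back-projected to unit space, normalized to unit L2 norm and
#' sign-aligned (largest-magnitude weight positive). Units with zero
#' variance are excluded from the decomposition and get zero weight.
#'
#' @param counts bins x units matrix of spike counts
#' @param n_restarts ICA restarts (best summed kurtosis kept)
#' @return object of class `assembly_model`: list with `patterns`
#'   (units x n_assemblies), `n_assemblies`, `mp_lambda_max`,
#'   `eigenvalues`, `unit_mean`, `unit_sd`, `active` (units entering the
#'   decomposition), `bin_width_s` (filled by [detect_assemblies()])
#' @export
assembly_patterns <- function(counts, n_restarts = 5L) {
  counts <- as.matrix(counts)
  n_units <- ncol(counts)
  mu <- colMeans(counts)
  sdv <- apply(counts, 2L, stats::sd)
  active <- sdv > 0
  z <- sweep(sweep(counts[, active, drop = FALSE], 2L, mu[active]), 2L,
             sdv[active], `/`)
  n_act <- sum(active)
  lam_max <- mp_bound(n_act, nrow(counts))
  cm <- stats::cor(z)
  eg <- eigen(cm, symmetric = TRUE)
  k <- sum(eg$values > lam_max)
  patterns <- matrix(numeric(0), n_units, 0L)
  if (k > 0L) {
    e_sub <- eg$vectors[, seq_len(k), drop = FALSE]
    l_sub <- eg$values[seq_len(k)]
    # whitened projections of the z-scored data onto the subspace
    xw <- sweep(z %*% e_sub, 2L, sqrt(l_sub * nrow(z) / (nrow(z) - 1)), `/`)
    w <- fastica_whitened(xw, n_restarts = n_restarts)
    pat_act <- e_sub %*% (sqrt(l_sub) * w)       # mixing back in unit space
    patterns <- matrix(0, n_units, k)
    patterns[active, ] <- pat_act
    for (j in seq_len(k)) {
      patterns[, j] <- patterns[, j] / sqrt(sum(patterns[, j]^2))
      i <- which.max(abs(patterns[, j]))
      if (patterns[i, j] < 0) patterns[, j] <- -patterns[, j]
    }
  }
  structure(list(patterns = patterns, n_assemblies = k,
                 mp_lambda_max = lam_max, eigenvalues = eg$values,
                 unit_mean = mu, unit_sd = sdv, active = active,
                 bin_width_s = NA_real_, window = NULL),
            class = "assembly_model")
}

#' Detect cell assemblies from trial activity
#'
#' Bins the spikes of every trial (-1 to 4 s from stimulus onset) into
#' 20 ms bins, concatenates trials and runs [assembly_patterns()].
#'
#' @param spikes list of per-unit spike-time vectors (one area)
#' @param trials trial schedule (uses all trials)
#' @param window trial window relative to CS onset (default c(-1, 4))
#' @param bin_width_s bin width (default 0.020 s)
#' @param n_restarts ICA restarts
#' @return an `assembly_model` (empty model when no eigenvalue exceeds the
#'   bound)
#' @export
detect_assemblies <- function(spikes, trials, window = c(-1, 4),
                              bin_width_s = 0.020, n_restarts = 5L) {
  if (length(spikes) < 2L) stop("need at least 2 units")
  if (nrow(trials) < 1L) stop("need at least 1 trial")
  n_bins <- as.integer(round(diff(window) / bin_width_s))
  blocks <- lapply(trials$onset_s, function(on) {
    vapply(spikes, function(su)
      as.numeric(bin_counts(su, on + window[1], n_bins, bin_width_s)),
      numeric(n_bins))
  })
  counts <- do.call(rbind, lapply(blocks, function(b) matrix(b, nrow = n_bins)))
  model <- assembly_patterns(counts, n_restarts = n_restarts)
  model$bin_width_s <- bin_width_s
  model$window <- window
  model
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model> %d assemblies over %d units (MP bound %.3f)\n",
              x$n_assemblies, nrow(x$patterns), x$mp_lambda_max))
  invisible(x)
}

#' Assembly activation quadratic form
#'
#' `A_k(t) = z(t)' P_k z(t)` with `P_k = w_k w_k'` and the diagonal of
#' `P_k` zeroed, so a bin in which at most one member unit is active
#' scores 0.
#'
#' @param z bins x units matrix of z-scored activity
#' @param patterns units x assemblies weight matrix
#' @return bins x assemblies activation matrix
#' @export
activation_quadratic <- function(z, patterns) {
  z <- as.matrix(z); patterns <- as.matrix(patterns)
  (z %*% patterns)^2 - (z^2) %*% (patterns^2)
}

#' Project spiking activity onto assembly patterns over time
#'
#' Sliding 20 ms bins advancing in 10 ms steps (50% overlap) across
#' `[t_start, t_end]`; counts are z-scored with the model's training
#' statistics and projected through [activation_quadratic()].
#'
#' @param model an `assembly_model`
#' @param spikes the same unit list the model was fit on
#' @param t_start,t_end time range (s)
#' @param step_s sliding step (default 0.010 s)
#' @return object of class `activation_trace`: list with `time` (window
#'   centers), `activation` (bins x assemblies), `step_s`, `bin_width_s`
#' @export
assembly_activation <- function(model, spikes, t_start, t_end,
                                step_s = 0.010) {
  if (model$n_assemblies == 0L) stop("empty assembly model")
  if (length(spikes) != nrow(model$patterns))
    stop("unit count does not match the model")
  bw <- if (is.na(model$bin_width_s)) 0.020 else model$bin_width_s
  n_el <- as.integer(floor((t_end - t_start) / step_s))
  el <- vapply(spikes, function(su)
    as.numeric(bin_counts(su, t_start, n_el, step_s)), numeric(n_el))
  el <- matrix(el, nrow = n_el)
  n_win <- n_el - 1L
  s <- el[seq_len(n_win), , drop = FALSE] + el[1L + seq_len(n_win), , drop = FALSE]
  sdv <- ifelse(model$active, model$unit_sd, Inf)
  z <- sweep(sweep(s, 2L, model$unit_mean), 2L, sdv, `/`)
  a <- activation_quadratic(z, model$patterns)
  structure(list(time = t_start + bw / 2 + (seq_len(n_win) - 1L) * step_s,
                 activation = a, step_s = step_s, bin_width_s = bw),
            class = "activation_trace")
}

# Index of the activation sample closest to time t.
.act_index <- function(act, t) {
  i <- as.integer(round((t - act$time[1]) / act$step_s)) + 1L
  pmin(pmax(i, 1L), length(act$time))
}

#' Ripple-triggered assembly reactivation
#'
#' Averages z-scored assembly activation around ITI ripple times. The
#' z-transform baseline is the activation outside the 50 ms
#' ripple-centered windows (restricted to inter-trial intervals when a
#' trial schedule is supplied). Per-ripple reactivation is the mean
#' z-scored activation in the 50 ms window centered on the ripple;
#' triggered traces are smoothed with a 100 ms Gaussian window.
#'
#' @param act an `activation_trace` covering the session
#' @param ripples a `ripple_events` data.frame (retained ITI events are
#'   used) or a numeric vector of ripple times
#' @param trials optional trial schedule restricting the baseline to ITIs
#' @param window triggered window half-width (s, default 1)
#' @param smooth_s Gaussian smoothing window for the traces (default 0.1)
#' @return object of class `reactivation_summary`: list with `lags`,
#'   `triggered` (lags x assemblies, z), `per_ripple`
#'   (ripples x assemblies), `ripple_times`, `mean_reactivation`,
#'   `baseline_mean`, `baseline_sd`
#' @export
swr_triggered_reactivation <- function(act, ripples, trials = NULL,
                                       window = 1, smooth_s = 0.1) {
  rt <- if (is.data.frame(ripples))
    ripples$time_s[ripples$retained & ripples$in_iti] else as.numeric(ripples)
  rt <- rt[rt - window >= act$time[1] & rt + window <= act$time[length(act$time)]]
  k <- ncol(act$activation)
  if (length(rt) == 0L) {
    return(structure(list(lags = numeric(0), triggered = NULL,
                          per_ripple = matrix(numeric(0), 0L, k),
                          ripple_times = numeric(0),
                          mean_reactivation = rep(NA_real_, k),
                          baseline_mean = NULL, baseline_sd = NULL),
                     class = "reactivation_summary"))
  }
  tt <- act$time
  base_mask <- rep(TRUE, length(tt))
  if (!is.null(trials) && nrow(trials) > 0L) {
    for (on in trials$onset_s)
      base_mask[tt >= on - 1 & tt <= on + 4] <- FALSE
  }
  for (t0 in rt) base_mask[abs(tt - t0) <= 0.025] <- FALSE
  bm <- colMeans(act$activation[base_mask, , drop = FALSE])
  bs <- apply(act$activation[base_mask, , drop = FALSE], 2L, stats::sd)
  bs[bs == 0] <- Inf
  z <- sweep(sweep(act$activation, 2L, bm), 2L, bs, `/`)

  half <- as.integer(round(window / act$step_s))
  lags <- (-half:half) * act$step_s
  centers <- .act_index(act, rt)
  tr_sum <- matrix(0, length(lags), k)
  per_ripple <- matrix(NA_real_, length(rt), k)
  cwin <- as.integer(round(0.025 / act$step_s))
  for (i in seq_along(rt)) {
    idx <- centers[i] + (-half:half)
    tr_sum <- tr_sum + z[idx, , drop = FALSE]
    ctr <- centers[i] + (-cwin:cwin)
    per_ripple[i, ] <- colMeans(z[ctr, , drop = FALSE])
  }
  triggered <- tr_sum / length(rt)
  sm_bins <- max(3L, as.integer(round(smooth_s / act$step_s)))
  triggered <- smooth_columns(triggered, sm_bins)
  structure(list(lags = lags, triggered = triggered,
                 per_ripple = per_ripple, ripple_times = rt,
                 mean_reactivation = colMeans(per_ripple),
                 baseline_mean = bm, baseline_sd = bs),
            class = "reactivation_summary")
}

#' Stimulus-triggered assembly activation
#'
#' CS-aligned assembly activation z-scored to the pre-stimulus period
#' (-1 to 0 s, both CS types pooled), with per-trial means for the
#' baseline, stimulus (0-2 s), trace (2-3 s) and reward (3-3.5 s)
#' periods.
#'
#' @param act an `activation_trace` covering the session
#' @param trials trial schedule with both CS types
#' @return list with `lags`, `traces` (list `plus`/`minus`, lags x
#'   assemblies, z), `period_means` (data.frame assembly x cs x period),
#'   `per_trial` (trials x periods x assemblies array), `cs` (trial
#'   labels)
#' @export
stimulus_triggered_activation <- function(act, trials) {
  if (length(unique(trials$cs_type)) < 2L) stop("both CS types required")
  tt <- act$time
  base_mask <- rep(FALSE, length(tt))
  for (on in trials$onset_s) base_mask[tt >= on - 1 & tt < on] <- TRUE
  bm <- colMeans(act$activation[base_mask, , drop = FALSE])
  bs <- apply(act$activation[base_mask, , drop = FALSE], 2L, stats::sd)
  bs[bs == 0] <- Inf
  z <- sweep(sweep(act$activation, 2L, bm), 2L, bs, `/`)
  k <- ncol(z)
  half0 <- as.integer(round(1 / act$step_s))
  half1 <- as.integer(round(4 / act$step_s))
  lags <- (-half0:half1) * act$step_s
  periods <- list(baseline = c(-1, 0), stim = c(0, 2), trace = c(2, 3),
                  reward = c(3, 3.5))
  n_tr <- nrow(trials)
  per_trial <- array(NA_real_, dim = c(n_tr, length(periods), k),
                     dimnames = list(NULL, names(periods), NULL))
  sums <- list(plus = matrix(0, length(lags), k),
               minus = matrix(0, length(lags), k))
  n_cs <- c(plus = 0L, minus = 0L)
  for (i in seq_len(n_tr)) {
    on <- trials$onset_s[i]
    ctr <- .act_index(act, on)
    idx <- ctr + (-half0:half1)
    idx <- pmin(pmax(idx, 1L), length(tt))
    cs <- trials$cs_type[i]
    sums[[cs]] <- sums[[cs]] + z[idx, , drop = FALSE]
    n_cs[[cs]] <- n_cs[[cs]] + 1L
    for (p in seq_along(periods)) {
      w <- periods[[p]]
      sel <- tt >= on + w[1] & tt < on + w[2]
      per_trial[i, p, ] <- colMeans(z[sel, , drop = FALSE])
    }
  }
  traces <- list(plus = sums$plus / max(n_cs[["plus"]], 1L),
                 minus = sums$minus / max(n_cs[["minus"]], 1L))
  pm <- do.call(rbind, lapply(c("plus", "minus"), function(cs) {
    sel <- trials$cs_type == cs
    do.call(rbind, lapply(seq_along(periods), function(p) {
      mu <- colMeans(array(per_trial[sel, p, ], dim = c(sum(sel), k)))
      data.frame(assembly = seq_len(k), cs = cs, period = names(periods)[p],
                 mean = mu)
    }))
  }))
  list(lags = lags, traces = traces, period_means = pm,
       per_trial = per_trial, cs = trials$cs_type)
}

#' Within-session reactivation dynamics over trial blocks
#'
#' Divides the session into `n_blocks` blocks of equal trial count,
#' assigns ITI ripples to blocks by time, computes per-assembly per-block
#' mean reactivation, groups assemblies by the sign of their session-mean
#' reactivation (reactivation+ / reactivation-), and compares the first
#' three and last three blocks with a Wilcoxon signed-rank test per group.
#'
#' @param summary a `reactivation_summary`
#' @param trials trial schedule (>= `n_blocks` trials)
#' @param duration_s session duration (s)
#' @param n_blocks number of blocks (default 10)
#' @return list with `block_means` (blocks x assemblies), `group`
#'   (per-assembly "+"/"-"), `group_block_means`, `first_last_p` (named
#'   p-values per group)
#' @export
block_dynamics <- function(summary, trials, duration_s, n_blocks = 10L) {
  n_tr <- nrow(trials)
  if (n_tr < n_blocks) stop("need at least ", n_blocks, " trials")
  bid <- ceiling(seq_len(n_tr) / (n_tr / n_blocks))
  edges <- c(vapply(seq_len(n_blocks), function(b)
    min(trials$onset_s[bid == b]), numeric(1)), duration_s)
  rt <- summary$ripple_times
  k <- ncol(summary$per_ripple)
  block_means <- matrix(NA_real_, n_blocks, k)
  for (b in seq_len(n_blocks)) {
    sel <- rt >= edges[b] & rt < edges[b + 1]
    if (any(sel))
      block_means[b, ] <- colMeans(summary$per_ripple[sel, , drop = FALSE])
  }
  grp <- ifelse(summary$mean_reactivation > 0, "+", "-")
  group_block_means <- sapply(c("+", "-"), function(g) {
    sel <- grp == g
    if (!any(sel)) return(rep(NA_real_, n_blocks))
    rowMeans(block_means[, sel, drop = FALSE], na.rm = TRUE)
  })
  first_last_p <- vapply(c("+", "-"), function(g) {
    sel <- which(grp == g)
    if (length(sel) < 2L) return(NA_real_)
    a <- colMeans(block_means[seq_len(3L), sel, drop = FALSE], na.rm = TRUE)
    b <- colMeans(block_means[n_blocks - (2:0), sel, drop = FALSE],
                  na.rm = TRUE)
    if (all(is.na(a - b)) || stats::sd(a - b, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }, numeric(1))
  list(block_means = block_means, group = grp,
       group_block_means = group_block_means, first_last_p = first_last_p)
}

#' Trial-type and trial-period modulation scores per assembly
#'
#' The trial-type score is the mean assembly activation during CS+ trials
#' minus the mean during CS- trials (stimulus + trace periods, 0-3 s);
#' the trial-period score is the mean activation during stimulus minus
#' the mean during trace, computed on CS- trials only. Per session the
#' most negative (CS+ suppressed), most positive (CS- suppressed) and
#' least-|score| (nonmodulated) assemblies are selected.
#'
#' @param stim_act result of [stimulus_triggered_activation()]
#' @return list with `scores` (data.frame per assembly) and `selection`
#'   (named indices; `complete` FALSE when fewer than 3 assemblies exist)
#' @export
modulation_scores <- function(stim_act) {
  pt <- stim_act$per_trial
  cs <- stim_act$cs
  k <- dim(pt)[3]
  stim_trace <- (pt[, "stim", , drop = FALSE] + pt[, "trace", , drop = FALSE]) / 2
  stim_trace <- array(stim_trace, dim = c(dim(pt)[1], k))
  tt_score <- colMeans(stim_trace[cs == "plus", , drop = FALSE]) -
    colMeans(stim_trace[cs == "minus", , drop = FALSE])
  minus <- cs == "minus"
  tp_score <- colMeans(array(pt[minus, "stim", ], dim = c(sum(minus), k))) -
    colMeans(array(pt[minus, "trace", ], dim = c(sum(minus), k)))
  scores <- data.frame(assembly = seq_len(k), trial_type_score = tt_score,
                       trial_period_score = tp_score)
  selection <- list(cs_plus_suppressed = which.min(tt_score),
                    cs_minus_suppressed = which.max(tt_score),
                    nonmodulated = which.min(abs(tt_score)),
                    complete = k >= 3L)
  list(scores = scores, selection = selection)
}

#' Correlation between aSWR reactivation and trial-type modulation
#'
#' Pearson correlation (two-sided) across assemblies between the mean
#' ripple-window reactivation and the trial-type modulation score.
#'
#' @param mean_reactivation per-assembly mean reactivation
#' @param modulation per-assembly trial-type modulation scores
#' @return list with `r`, `p_value`, `n`
#' @export
reactivation_vs_modulation <- function(mean_reactivation, modulation) {
  ok <- is.finite(mean_reactivation) & is.finite(modulation)
  x <- mean_reactivation[ok]; y <- modulation[ok]
  if (length(x) < 3L) stop("need at least 3 assemblies")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Fraction of significant per-ripple reactivations
#'
#' Fraction of per-ripple reactivation values exceeding the median by more
#' than two standard deviations, with the SD estimated robustly as
#' 1.4826 x the median absolute deviation. When the MAD is zero, the
#' fraction of values above the median is returned with a flag.
#'
#' @param per_ripple_values numeric vector (>= 10 ripples)
#' @return list with `fraction`, `threshold`, `mad_zero`
#' @export
significant_reactivation_fraction <- function(per_ripple_values) {
  v <- per_ripple_values[is.finite(per_ripple_values)]
  if (length(v) < 10L) stop("need at least 10 ripples")
  med <- stats::median(v)
  sd_est <- stats::mad(v)                 # already scaled by 1.4826
  if (sd_est == 0)
    return(list(fraction = mean(v > med), threshold = med, mad_zero = TRUE))
  list(fraction = mean(v > med + 2 * sd_est), threshold = med + 2 * sd_est,
       mad_zero = FALSE)
}

#' CA1-PFC assembly coactivation during ripples (quadrant analysis)
#'
#' For every CA1 x PFC assembly pair, each area's per-ripple reactivation
#' is median-split; %Q1 is the percentage of ripples with both areas
#' above their medians and %Q2 the percentage with CA1 above and PFC
#' below. Q1 and Q2 are compared over all pairs with a paired Wilcoxon
#' signed-rank test.
#'
#' @param per_ripple_ca1,per_ripple_pfc ripples x assemblies per-ripple
#'   reactivation matrices on a shared ripple list (>= 10 ripples)
#' @return list with `pairs` (data.frame ca1, pfc, q1_pct, q2_pct) and
#'   `p_value`
#' @export
quadrant_coactivation <- function(per_ripple_ca1, per_ripple_pfc) {
  a <- as.matrix(per_ripple_ca1); b <- as.matrix(per_ripple_pfc)
  if (nrow(a) != nrow(b)) stop("areas must share the ripple event list")
  if (nrow(a) < 10L) stop("need at least 10 shared ripples")
  out <- list()
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    ma <- stats::median(a[, i]); mb <- stats::median(b[, j])
    q1 <- 100 * mean(a[, i] > ma & b[, j] > mb)
    q2 <- 100 * mean(a[, i] > ma & b[, j] < mb)
    out[[length(out) + 1L]] <- data.frame(ca1 = i, pfc = j,
                                          q1_pct = q1, q2_pct = q2)
  }
  pairs <- do.call(rbind, out)
  p <- if (nrow(pairs) >= 2L && stats::sd(pairs$q1_pct - pairs$q2_pct) > 0)
    stats::wilcox.test(pairs$q1_pct, pairs$q2_pct, paired = TRUE,
                       exact = FALSE)$p.value else NA_real_
  list(pairs = pairs, p_value = p)
}

#' Match detected assembly patterns to ground-truth memberships
#'
#' Greedy bipartite matching on absolute cosine similarity between
#' detected patterns and planted membership weight vectors (ties broken
#' by similarity magnitude).
#'
#' @param patterns units x detected matrix
#' @param truth_weights units x planted matrix
#' @return data.frame with `detected`, `planted`, `cosine`
#' @export
match_patterns <- function(patterns, truth_weights) {
  p <- as.matrix(patterns); tw <- as.matrix(truth_weights)
  if (ncol(p) == 0L || ncol(tw) == 0L)
    return(data.frame(detected = integer(0), planted = integer(0),
                      cosine = numeric(0)))
  norm <- function(m) sweep(m, 2L, sqrt(colSums(m^2)), `/`)
  sim <- abs(crossprod(norm(p), norm(tw)))
  out <- list()
  while (length(out) < min(ncol(p), ncol(tw))) {
    i <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
    out[[length(out) + 1L]] <- data.frame(detected = i[1L], planted = i[2L],
                                          cosine = sim[i[1L], i[2L]])
    sim[i[1L], ] <- -1
    sim[, i[2L]] <- -1
  }
  do.call(rbind, out)
}
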