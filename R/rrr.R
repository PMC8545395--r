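# Reduced-rank regression between and within areas: subsampling,
# cross-validated per-rank performance, 1-SEM rank selection, and a
# regularized full-rank control.

#' Subsample four disjoint, equally sized unit sets
#'
#' Splits each area's units into a random disjoint source/target pair and
#' truncates all four sets to the same size
#' `m = min(floor(n_ca1/2), floor(n_pfc/2))`.
#'
#' @param units_ca1,units_pfc integer vectors of unit indices per area
#' @return list with `ca1_source`, `ca1_target`, `pfc_source`,
#'   `pfc_target`, `m`
#' @export
subsample_quadruple <- function(units_ca1, units_pfc) {
  m <- min(floor(length(units_ca1) / 2), floor(length(units_pfc) / 2))
  if (m < 2L) stop("subsampled set size m = ", m, " < 2; need more units")
  pick <- function(u) {
    s <- sample(u, 2L * m)
    list(source = s[seq_len(m)], target = s[m + seq_len(m)])
  }
  ca1 <- pick(units_ca1); pfc <- pick(units_pfc)
  list(ca1_source = ca1$source, ca1_target = ca1$target,
       pfc_source = pfc$source, pfc_target = pfc$target, m = m)
}

#' Trial-period spike-count activity matrix
#'
#' Spike counts of one area's units in 100 ms bins inside a task period
#' window, concatenated across trials and per-unit mean-centered.
#' Period windows relative to CS onset: baseline -1-0 s, stim 0-2 s,
#' trace 2-3 s, reward 3-3.5 s.
#'
#' @param bundle a `session_bundle`
#' @param period one of "baseline", "stim", "trace", "reward"
#' @param area "CA1" or "PFC"
#' @param bin_width bin width in seconds (default 0.1)
#' @param units optional unit subset
#' @return samples x units matrix of centered counts
#' @export
period_activity <- function(bundle, period = c("baseline", "stim", "trace",
                                               "reward"),
                            area = "CA1", bin_width = 0.1, units = NULL) {
  period <- match.arg(period)
  win <- switch(period, baseline = c(-1, 0), stim = c(0, 2),
                trace = c(2, 3), reward = c(3, 3.5))
  sp <- bundle$spikes[[area]]
  if (!is.null(units)) sp <- sp[units]
  onsets <- bundle$trials$onset_s
  if (length(onsets) == 0L) stop("no trials in bundle")
  n_bins <- as.integer(round(diff(win) / bin_width))
  rows <- lapply(onsets, function(on) {
    vapply(sp, function(su)
      as.numeric(bin_counts(su, on + win[1], n_bins, bin_width)),
      numeric(n_bins))
  })
  x <- do.call(rbind, lapply(rows, function(r) matrix(r, nrow = n_bins)))
  scale(x, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Cross-validated reduced-rank regression performance curve
#'
#' Per fold: ordinary least squares on the training split (with a tiny
#' ridge jitter on the Gram matrix for numerical safety), then held-out
#' predictions projected onto the top-r principal components of the
#' fitted training values (the reduced-rank estimator) for every rank r.
#' At the maximal rank the projector is the identity, so the performance
#' equals that of the full regression.
#'
#' @param x,y samples x units source and target matrices
#' @param folds CV folds (default 10)
#' @param ranks rank grid (default 1..min dimension)
#' @param ridge_eps Gram-matrix jitter
#' @return folds x ranks matrix of held-out R^2 with a `ranks` attribute
#' @export
rrr_cv <- function(x, y, folds = 10L, ranks = NULL, ridge_eps = 1e-8) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n, n >= folds)
  q <- ncol(y)
  max_rank <- min(ncol(x), q)
  if (is.null(ranks)) ranks <- seq_len(max_rank)
  stopifnot(max(ranks) <= max_rank)
  fid <- rep_len(seq_len(folds), n)[sample.int(n)]
  perf <- matrix(NA_real_, folds, length(ranks))
  for (k in seq_len(folds)) {
    tr <- fid != k
    mx <- colMeans(x[tr, , drop = FALSE])
    my <- colMeans(y[tr, , drop = FALSE])
    xtr <- sweep(x[tr, , drop = FALSE], 2L, mx)
    ytr <- sweep(y[tr, , drop = FALSE], 2L, my)
    xte <- sweep(x[!tr, , drop = FALSE], 2L, mx)
    yte <- sweep(y[!tr, , drop = FALSE], 2L, my)
    g <- crossprod(xtr) + diag(ridge_eps, ncol(x))
    b <- solve(g, crossprod(xtr, ytr))
    v <- svd(xtr %*% b, nu = 0, nv = q)$v          # PCs of fitted values
    t_te <- (xte %*% b) %*% v                      # test fits in PC coords
    yv <- yte %*% v
    ss_tot <- sum(yte^2)
    cross <- cumsum(colSums(yv * t_te))
    norms <- cumsum(colSums(t_te^2))
    for (j in seq_along(ranks)) {
      r <- ranks[j]
      ss_res <- ss_tot - 2 * cross[r] + norms[r]
      perf[k, j] <- 1 - ss_res / ss_tot
    }
  }
  colnames(perf) <- paste0("rank", ranks)
  attr(perf, "ranks") <- ranks
  perf
}

#' Cross-validated reduced-rank regression at one rank
#'
#' @param x,y samples x units source and target matrices
#' @param rank rank constraint
#' @param folds CV folds (default 10)
#' @return numeric vector of per-fold held-out R^2
#' @export
fit_rrr <- function(x, y, rank, folds = 10L) {
  as.numeric(rrr_cv(x, y, folds = folds, ranks = rank))
}

#' 1-SEM rank selection
#'
#' The smallest rank whose mean cross-validated performance is within one
#' standard error of the best rank's mean performance.
#'
#' @param perf folds x ranks performance matrix (from [rrr_cv()]) or a
#'   numeric vector of per-rank means (then `sem` must be given)
#' @param sem per-rank SEMs when `perf` is a vector of means
#' @return selected rank (integer index into the rank grid)
#' @export
select_rank <- function(perf, sem = NULL) {
  if (is.matrix(perf)) {
    ranks <- attr(perf, "ranks") %||% seq_len(ncol(perf))
    means <- colMeans(perf)
    sems <- apply(perf, 2L, stats::sd) / sqrt(nrow(perf))
  } else {
    ranks <- seq_along(perf)
    means <- perf
    sems <- sem
    stopifnot(!is.null(sems), length(sems) == length(means))
  }
  best <- which.max(means)
  thr <- means[best] - sems[best]
  ranks[which(means >= thr)[1L]]
}

# Regularized full-rank control: penalized multiresponse regression over a
# lambda grid; the best penalty is the one with the highest average CV
# performance; reports the held-out MSE at that penalty.
penalized_full_control <- function(x, y, folds = 5L, alpha = 0,
                                   lambda = 10^seq(2, -3, length.out = 7)) {
  n <- nrow(x)
  fid <- rep_len(seq_len(folds), n)[sample.int(n)]
  mse <- matrix(NA_real_, folds, length(lambda))
  for (k in seq_len(folds)) {
    tr <- fid != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                          family = "mgaussian", alpha = alpha,
                          lambda = lambda, standardize = FALSE)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE])
    for (j in seq_along(lambda))
      mse[k, j] <- mean((y[!tr, , drop = FALSE] - pr[, , j])^2)
  }
  cvm <- colMeans(mse)
  best <- which.min(cvm)
  list(lambda = lambda[best], mse = cvm[best], cv_mse = cvm, alpha = alpha)
}

#' Cross-area reduced-rank regression analysis
#'
#' For each source-target direction (CA1->CA1, CA1->PFC, PFC->PFC,
#' PFC->CA1) and task period, repeatedly subsamples four disjoint equally
#' sized unit sets, computes the cross-validated RRR performance curve,
#' selects the rank with the 1-SEM rule and averages performance and rank
#' over subsample replicates. Optionally adds a penalized full-rank
#' control (default pure ridge; the L1 mixing weight `alpha` is exposed)
#' on the first replicate of each cell.
#'
#' @param bundle a `session_bundle` with both areas
#' @param periods task periods to analyze
#' @param n_subsamples subsample replicates (default 10)
#' @param folds CV folds (default 10)
#' @param full_control logical: run the penalized full-rank control
#' @param alpha elastic-net mixing weight for the control (0 = ridge)
#' @return data.frame with one row per direction x period: mean selected
#'   rank, mean performance at the selected rank, SEM over replicates, and
#'   (when requested) control lambda and held-out MSE
#' @export
crossarea_analysis <- function(bundle,
                               periods = c("baseline", "stim", "trace",
                                           "reward"),
                               n_subsamples = 10L, folds = 10L,
                               full_control = FALSE, alpha = 0) {
  areas <- names(bundle$spikes)
  if (length(areas) < 2L)
    warning("single-area bundle: only within-area results computed")
  dirs <- expand.grid(source = areas, target = areas,
                      stringsAsFactors = FALSE)
  out <- list()
  for (period in periods) {
    acts <- lapply(areas, function(a)
      period_activity(bundle, period, area = a))
    names(acts) <- areas
    n_ca1 <- length(bundle$spikes[[areas[1]]])
    n_pfc <- if (length(areas) > 1L) length(bundle$spikes[[areas[2]]]) else n_ca1
    for (d in seq_len(nrow(dirs))) {
      src <- dirs$source[d]; tgt <- dirs$target[d]
      perfs <- ranks <- numeric(n_subsamples)
      ctrl <- NULL
      for (s in seq_len(n_subsamples)) {
        qd <- subsample_quadruple(seq_len(n_ca1), seq_len(n_pfc))
        sets <- list(CA1 = list(source = qd$ca1_source, target = qd$ca1_target),
                     PFC = list(source = qd$pfc_source, target = qd$pfc_target))
        x <- acts[[src]][, sets[[src]]$source, drop = FALSE]
        y <- acts[[tgt]][, sets[[tgt]]$target, drop = FALSE]
        pm <- rrr_cv(x, y, folds = folds)
        r <- select_rank(pm)
        ranks[s] <- r
        perfs[s] <- mean(pm[, r])
        if (full_control && s == 1L)
          ctrl <- penalized_full_control(x, y, alpha = alpha)
      }
      out[[length(out) + 1L]] <- data.frame(
        source = src, target = tgt, period = period,
        rank = mean(ranks), performance = mean(perfs),
        performance_sem = stats::sd(perfs) / sqrt(n_subsamples),
        control_lambda = if (is.null(ctrl)) NA_real_ else ctrl$lambda,
        control_mse = if (is.null(ctrl)) NA_real_ else ctrl$mse)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
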