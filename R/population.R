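# Population rate-vector trajectories, CS+/CS- Euclidean distance, PCA
# visualization and trial-identity decoding.

#' Per-condition population rate matrices
#'
#' Trial-averaged, Gaussian-smoothed rate matrices (bins x units) for CS+
#' and CS- trials, restricted to non-lick units of one area.
#'
#' @param bundle a `session_bundle`
#' @param classification result of [classify_response_windows()]
#' @param area "CA1" or "PFC"
#' @param window,bin_width,smooth_bins binning parameters
#' @return list with `plus`, `minus` (bins x units matrices, Hz), `time`,
#'   `units` (indices of the units used)
#' @export
population_vectors <- function(bundle, classification, area = "CA1",
                               window = c(-1, 4), bin_width = 0.025,
                               smooth_bins = 25L) {
  cls <- classification[classification$area == area, , drop = FALSE]
  keep <- which(nonlick_units(cls))
  if (length(keep) < 2L)
    stop("need at least 2 non-lick units for population analysis")
  sp <- bundle$spikes[[area]][keep]
  mats <- lapply(c(plus = "plus", minus = "minus"), function(cs) {
    al <- bundle$trials$onset_s[bundle$trials$cs_type == cs]
    b <- bin_and_smooth(sp, al, window = window, bin_width = bin_width,
                        smooth_bins = smooth_bins,
                        t_max = bundle$meta$duration_s)
    psth(b)
  })
  n_bins <- nrow(mats$plus)
  list(plus = mats$plus, minus = mats$minus,
       time = window[1] + (seq_len(n_bins) - 0.5) * bin_width,
       units = keep)
}

#' Euclidean distance between two population trajectories
#'
#' Per-bin L2 distance across units between two bins x units matrices,
#' z-scored to the baseline bins. When the baseline SD is zero the raw
#' distance is returned with `zscored = FALSE`.
#'
#' @param mat_a,mat_b bins x units matrices with identical shape
#' @param time bin-center times
#' @param baseline_window window defining baseline bins (default (-1, 0) s)
#' @return list with `distance` (per bin; z-scored unless flagged), `raw`
#'   (raw distance), `zscored` (logical)
#' @export
distance_trace <- function(mat_a, mat_b, time, baseline_window = c(-1, 0)) {
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  d <- sqrt(rowSums((mat_a - mat_b)^2))
  base <- time >= baseline_window[1] & time < baseline_window[2]
  m <- mean(d[base]); s <- stats::sd(d[base])
  if (!is.finite(s) || s == 0)
    return(list(distance = d, raw = d, zscored = FALSE))
  list(distance = (d - m) / s, raw = d, zscored = TRUE)
}

#' Joint PCA trajectory of both conditions
#'
#' PCA over the concatenated condition matrices; both conditions are
#' projected into the shared space of the first three components (fewer,
#' with a flag, when the data rank is lower). Component signs are fixed so
#' the largest-magnitude loading is positive.
#'
#' @param mats list with `plus` and `minus` bins x units matrices
#' @return list with `plus`, `minus` (bins x k coordinate matrices),
#'   `k` (number of usable components), `rank_deficient` (logical),
#'   `loadings`
#' @export
pca_trajectory <- function(mats) {
  x <- rbind(mats$plus, mats$minus)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pos <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  k <- min(3L, pos)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ctr <- pc$center
  proj <- function(m) sweep(m, 2L, ctr) %*% rot
  list(plus = proj(mats$plus), minus = proj(mats$minus), k = k,
       rank_deficient = k < 3L, loadings = rot)
}

# Stratified fold assignment: each class is spread across folds as evenly
# as possible; errors when a fold would miss a class entirely.
stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- sample(which(labels == l))
    if (length(idx) < folds)
      stop("cannot build ", folds, " stratified folds: class '", l,
           "' has only ", length(idx), " trials")
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

svm_cv_accuracy <- function(x, y, folds) {
  fid <- stratified_folds(y, folds)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fid != k
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    mean(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  acc
}

#' Decode trial identity from trace-period population rates
#'
#' Per-trial mean firing rates of non-lick units in the trace period
#' (2-3 s post CS onset) feed a linear maximum-margin classifier
#' (cost 1) evaluated with stratified 20-fold cross-validation. Optional
#' single-session significance via label permutation.
#'
#' @param bundle a `session_bundle`
#' @param classification result of [classify_response_windows()]
#' @param area "CA1" or "PFC"
#' @param window rate window relative to CS onset (default trace period)
#' @param folds number of CV folds (default 20)
#' @param n_perm label permutations for the p-value (0 skips the test)
#' @return list with `accuracy`, `fold_accuracy`, `p_value` (NA when
#'   `n_perm = 0`), `null_accuracy` (permutation accuracies), `n_trials`,
#'   `n_units`
#' @export
decode_trial_identity <- function(bundle, classification, area = "CA1",
                                  window = c(2, 3), folds = 20L,
                                  n_perm = 0L) {
  trials <- bundle$trials
  if (nrow(trials) < folds) stop("need at least ", folds, " trials")
  if (length(unique(trials$cs_type)) < 2L) stop("both CS types required")
  cls <- classification[classification$area == area, , drop = FALSE]
  keep <- which(nonlick_units(cls))
  if (length(keep) < 1L) stop("no usable units")
  sp <- bundle$spikes[[area]][keep]
  x <- vapply(sp, function(su) {
    vapply(trials$onset_s, function(on)
      count_in_window(su, on + window[1], on + window[2]) /
        diff(window), numeric(1))
  }, numeric(nrow(trials)))
  x <- matrix(x, nrow = nrow(trials))
  y <- factor(trials$cs_type)
  acc <- svm_cv_accuracy(x, y, folds)
  null_acc <- numeric(0)
  p <- NA_real_
  if (n_perm > 0L) {
    null_acc <- vapply(seq_len(n_perm), function(i)
      mean(svm_cv_accuracy(x, sample(y), folds)), numeric(1))
    p <- (sum(null_acc >= mean(acc)) + 1) / (n_perm + 1)
  }
  list(accuracy = mean(acc), fold_accuracy = acc, p_value = p,
       null_accuracy = null_acc, n_trials = nrow(trials),
       n_units = length(keep))
}
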