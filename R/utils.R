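# Internal numerical helpers shared across modules.

#' Normalized Gaussian-weighted moving-average kernel
#'
#' @param width_bins odd kernel support in bins
#' @param sigma_bins Gaussian standard deviation in bins (default width/5)
#' @return numeric vector of length `width_bins` summing to 1
#' @keywords internal
gaussian_kernel <- function(width_bins = 25L, sigma_bins = width_bins / 5) {
  width_bins <- as.integer(width_bins)
  if (width_bins < 1L) stop("kernel width must be >= 1 bin")
  if (width_bins %% 2L == 0L) width_bins <- width_bins + 1L
  half <- (width_bins - 1L) %/% 2L
  k <- exp(-0.5 * ((-half:half) / sigma_bins)^2)
  k / sum(k)
}

# Convolve each column of `x` (bins x series) with a normalized Gaussian
# kernel, padding edges by mirror reflection (edge sample repeated). For a
# symmetric normalized kernel this preserves column sums exactly.
smooth_columns <- function(x, width_bins = 25L, sigma_bins = width_bins / 5) {
  x <- as.matrix(x)
  k <- gaussian_kernel(width_bins, sigma_bins)
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(x)
  if (n == 0L) return(x)
  pad <- min(half, n)
  idx <- c(rev(seq_len(pad)), seq_len(n), n + 1L - seq_len(pad))
  if (pad < half) {
    # very short traces: recycle reflection until long enough
    while (length(idx) < n + 2L * half) idx <- c(rev(idx[seq_len(min(length(idx), half))]), idx)
    idx <- idx[seq_len(n + 2L * half)]
  }
  xp <- x[idx, , drop = FALSE]
  out <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2L))
  out <- matrix(out, nrow = nrow(xp))
  out[(half + 1L):(half + n), , drop = FALSE]
}

smooth_vector <- function(x, width_bins = 25L, sigma_bins = width_bins / 5) {
  drop(smooth_columns(matrix(x, ncol = 1L), width_bins, sigma_bins))
}

# Counts of event times falling in [start + (i-1)*bw, start + i*bw), i = 1..n.
bin_counts <- function(times, start, n_bins, bin_width) {
  if (length(times) == 0L) return(integer(n_bins))
  i <- floor((times - start) / bin_width) + 1
  i <- i[i >= 1 & i <= n_bins]
  tabulate(as.integer(i), nbins = as.integer(n_bins))
}

# Number of elements of sorted/unsorted `times` in the half-open window [a, b).
count_in_window <- function(times, a, b) sum(times >= a & times < b)

# Discrete analytic signal (one-sided spectrum) of a real vector.
# Zero-pads to a highly composite length first: R's FFT is O(n^2) on
# lengths with large prime factors, which arbitrary session durations
# readily produce.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  n2 <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(n2 - n))
  h <- numeric(n2)
  h[c(1L, n2 / 2L + 1L)] <- 1
  h[2L:(n2 / 2L)] <- 2
  out <- stats::fft(stats::fft(xp) * h, inverse = TRUE) / n2
  out[seq_len(n)]
}

# Draw n event times from a homogeneous Poisson process on [t0, t1).
poisson_times <- function(rate, t0, t1) {
  len <- t1 - t0
  if (len <= 0 || rate <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * len)
  sort(stats::runif(n, t0, t1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
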