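# Shared numerical helpers: zero-phase low-pass filtering and finite
# differences. Filtering uses reflective padding so filtfilt start-up
# transients never reach the analyzed samples.

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]) after reflecting the series about its endpoints,
#' which suppresses edge transients on short trials.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz; `NULL` returns `x` unchanged.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass <- function(x, sample_rate, cutoff = 6) {
  if (is.null(cutoff)) return(x)
  if (!is.finite(cutoff) || cutoff <= 0) gd_config_error("filter cutoff must be positive")
  if (cutoff >= sample_rate / 2)
    gd_config_error(sprintf("filter cutoff %g Hz must be below the Nyquist rate %g Hz",
                            cutoff, sample_rate / 2))
  n <- length(x)
  if (n < 8) return(x)
  # demean and reflect-pad: filtfilt starts from zero state, so a DC offset
  # or short series would otherwise leak start-up transients into the data
  np <- min(n - 1L, max(16L, ceiling(3 * sample_rate / cutoff)))
  mu <- mean(x)
  xc <- x - mu
  pad_head <- 2 * xc[1] - rev(xc[2:(np + 1)])
  pad_tail <- 2 * xc[n] - rev(xc[(n - np):(n - 1)])
  bf <- signal::butter(2, cutoff / (sample_rate / 2))
  xf <- signal::filtfilt(bf, c(pad_head, xc, pad_tail))
  xf[(np + 1):(np + n)] + mu
}

# Central finite difference, one-sided at the ends; returns units of x per
# sample until multiplied by the rate.
central_diff <- function(x) {
  n <- length(x)
  if (n < 2) gd_domain_error("need at least 2 samples to differentiate")
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  v[1] <- x[2] - x[1]
  v[n] <- x[n] - x[n - 1]
  v
}

# Linear interpolation over internal NA runs no longer than max_gap frames.
# Longer runs (or NA at the series ends) raise a data-quality error.
fill_gaps <- function(x, max_gap = 10L, what = "series") {
  if (!anyNA(x)) return(x)
  isna <- is.na(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (starts[i] == 1L || ends[i] == length(x))
      gd_data_error(sprintf("%s: missing data at series boundary (frames %d-%d)",
                            what, starts[i], ends[i]))
    if (r$lengths[i] > max_gap)
      gd_data_error(sprintf("%s: gap of %d frames (frames %d-%d) exceeds max_gap = %d",
                            what, r$lengths[i], starts[i], ends[i], max_gap))
  }
  idx <- which(!isna)
  approx(idx, x[idx], xout = seq_along(x))$y
}

# Draw n sub-seeds (< 2^31) from a master seed without disturbing the
# caller's RNG state.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
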