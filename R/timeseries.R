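#' Uniformly sampled physiological time series
#'
#' Light-weight container for one channel: a numeric vector sampled at a
#' fixed rate from a session start time, with a units label and a validity
#' mask. Invalid samples keep their (possibly interpolated) numeric value;
#' the mask is what preprocessing and estimation stages consult.
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds (default 0).
#' @param units character units label, e.g. `"ms"`, `"uS"`, `"mm"`.
#' @param valid logical mask, same length as `values`; `FALSE` marks
#'   samples excluded by artifact rules. Defaults to all valid.
#' @return An object of class `pav_ts`.
#' @export
pav_ts <- function(values, rate, start = 0, units = "", valid = NULL) {
  stopifnot(is.numeric(values), length(rate) == 1L, rate > 0)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  stopifnot(length(valid) == length(values))
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         start = as.numeric(start), units = units, valid = as.logical(valid)),
    class = "pav_ts"
  )
}

#' Sample times of a time series
#' @param ts a [pav_ts()] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  ts$start + (seq_along(ts$values) - 1L) / ts$rate
}

#' @export
print.pav_ts <- function(x, ...) {
  dur <- length(x$values) / x$rate
  cat(sprintf("<pav_ts> %d samples @ %g Hz (%.1f s), units '%s', %d invalid\n",
              length(x$values), x$rate, dur, x$units, sum(!x$valid)))
  invisible(x)
}

#' Zero-phase Butterworth filtering
#'
#' Bidirectional (forward-backward) Butterworth filtering with independent
#' high-pass and low-pass stages. A band-pass is realised as a cascade of an
#' `order`-th order high-pass and an `order`-th order low-pass, each applied
#' with [signal::filtfilt()]; a direct high-order band-pass in
#' transfer-function form is numerically unstable at the very low normalized
#' cutoffs used for heart period (0.015 Hz at 100 Hz sampling).
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param high high-pass cutoff in Hz, or `NULL` to skip.
#' @param low low-pass cutoff in Hz, or `NULL` to skip (also skipped when at
#'   or above the Nyquist frequency).
#' @param order filter order of each stage (default 2, giving a 4th-order
#'   band-pass overall).
#' @return filtered numeric vector, same length as `x`.
#' @export
butter_bandpass <- function(x, rate, high = NULL, low = NULL, order = 2) {
  stopifnot(is.numeric(x), rate > 0)
  nyq <- rate / 2
  y <- x
  if (!is.null(high) && high > 0) {
    hp <- signal::butter(order, high / nyq, type = "high")
    y <- signal::filtfilt(hp, y)
  }
  if (!is.null(low) && low < nyq) {
    lp <- signal::butter(order, low / nyq, type = "low")
    y <- signal::filtfilt(lp, y)
  }
  y
}

#' Linear resampling onto a uniform grid
#'
#' @param t sample times (seconds, increasing, not necessarily uniform).
#' @param x values at `t`.
#' @param rate target rate in Hz.
#' @param t_start,t_end grid limits in seconds; default to the data range.
#' @param rule extrapolation rule passed to [stats::approx()] (2 holds the
#'   edge values).
#' @return a [pav_ts()] at `rate` starting at `t_start`.
#' @export
resample_linear <- function(t, x, rate, t_start = NULL, t_end = NULL, rule = 2) {
  stopifnot(length(t) == length(x), length(t) >= 2L)
  if (is.null(t_start)) t_start <- t[1L]
  if (is.null(t_end)) t_end <- t[length(t)]
  grid <- seq(t_start, t_end, by = 1 / rate)
  out <- stats::approx(t, x, xout = grid, rule = rule)$y
  pav_ts(out, rate = rate, start = t_start)
}

# Run expr with a private, restored RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Spectrally shaped 1/f ("pink") Gaussian noise with fixed FFT length,
# scaled to standard deviation `sd`.
pink_noise <- function(n, sd = 1) {
  if (sd == 0 || n == 0L) return(numeric(n))
  nfft <- 2^ceiling(log2(max(n, 2L)))
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1L))
  f <- pmin(f, nfft - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sd / s)
}
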