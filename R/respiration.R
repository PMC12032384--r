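#' Detect respiration cycles and per-cycle amplitudes
#'
#' Band-limits the belt signal, locates cycle starts at rising
#' zero-crossings, and measures each cycle's peak-to-trough amplitude.
#' Cycles with implausible duration (outside 1-15 s) are discarded.
#'
#' @param ts respiration belt [pav_ts()], rate >= 10 Hz.
#' @param band band-limit applied before zero-crossing detection (Hz).
#' @return data.frame with `onset`, `midpoint`, `duration` (s) and
#'   `amplitude` (peak-to-trough, channel units) per retained cycle.
#' @export
detect_cycles <- function(ts, band = c(0.05, 1)) {
  stopifnot(inherits(ts, "pav_ts"), ts$rate >= 10)
  x <- butter_bandpass(ts$values, ts$rate, high = band[1], low = band[2],
                       order = 2)
  up <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  if (length(up) < 2L) stop("no respiration cycles found")
  t <- ts_time(ts)
  onsets <- t[up]
  n_cyc <- length(up) - 1L
  amp <- t_peak <- t_trough <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    idx <- up[i]:up[i + 1L]
    seg <- ts$values[idx]
    amp[i] <- max(seg) - min(seg)
    t_peak[i] <- t[idx[which.max(seg)]]
    t_trough[i] <- t[idx[which.min(seg)]]
  }
  dur <- diff(onsets)
  out <- data.frame(onset = onsets[seq_len(n_cyc)],
                    midpoint = onsets[seq_len(n_cyc)] + dur / 2,
                    duration = dur, amplitude = amp,
                    t_peak = t_peak, t_trough = t_trough)
  out[out$duration >= 1 & out$duration <= 15, , drop = FALSE]
}

#' Respiration-amplitude time series
#'
#' Linearly interpolates per-cycle amplitudes (anchored at cycle midpoints)
#' at 10 Hz and band-pass filters bidirectionally (0.01-Hz high-pass,
#' 2-Hz low-pass).
#'
#' @param cycles data.frame from [detect_cycles()].
#' @param t_end end of the output grid (s); defaults to the last cycle.
#' @param rate output rate (Hz).
#' @param band band-pass cutoffs (Hz).
#' @return a [pav_ts()] at `rate`.
#' @export
rar_timeseries <- function(cycles, t_end = NULL, rate = 10,
                           band = c(0.01, 2)) {
  stopifnot(nrow(cycles) >= 2L)
  if (is.null(t_end)) t_end <- max(cycles$midpoint)
  ts <- resample_linear(cycles$midpoint, cycles$amplitude, rate,
                        t_start = 0, t_end = t_end)
  bp <- signal::butter(1, band / (rate / 2), type = "pass")
  ts$values <- signal::filtfilt(bp, ts$values - mean(ts$values))
  ts$units <- "a.u."
  ts
}

#' Condition-wise respiration-amplitude response estimation
#'
#' Condition-wise convolution GLM with the respiration-amplitude kernel,
#' on nonreinforced CS+ and CS− trials (reinforced CS+ and US onsets enter
#' as nuisance regressors). The regressor time courses are passed through
#' the same transform as the data — sampled at the detected cycle
#' midpoints, linearly interpolated at 10 Hz, and band-pass filtered — so
#' that the cycle-level resampling of the envelope does not bias the
#' amplitude estimates.
#'
#' @param ts respiration-amplitude [pav_ts()] from [rar_timeseries()].
#' @param events event table.
#' @param rf the respiration kernel (default `rf_registry("rarf_rew")`).
#' @param cycles the cycle table used to build `ts` (for the resampling
#'   transform); `NULL` skips that transform.
#' @param band the band-pass applied to the data.
#' @return list with `csp`, `csm` amplitudes and the [glm_invert()] `fit`.
#' @export
estimate_rar_amplitudes <- function(ts, events, rf = rf_registry("rarf_rew"),
                                    cycles = NULL, band = c(0.01, 2)) {
  retained <- events$trial_index[events$condition == "CS-" |
                                 !events$reinforced]
  nuis <- list()
  reinf <- events[events$reinforced, ]
  if (nrow(reinf) > 0L) {
    nuis$csp_reinforced <- reinf$cs_onset
    nuis$us <- reinf$us_onset
  }
  des <- build_design(events, rf, rate = ts$rate,
                      n_samples = length(ts$values), mode = "condition",
                      retained = retained,
                      nuisance = if (length(nuis)) nuis else NULL,
                      intercept = TRUE, normalise = TRUE)
  tg <- ts_time(ts)
  bp <- signal::butter(1, band / (ts$rate / 2), type = "pass")
  task <- colnames(des$X) != "(intercept)"
  des$X[, task] <- apply(des$X[, task, drop = FALSE], 2, function(col) {
    if (!is.null(cycles)) {
      # peak-to-trough sampling: the measured cycle amplitude reflects the
      # envelope averaged at the cycle's peak and trough times
      at_cyc <- (stats::approx(tg, col, xout = cycles$t_peak, rule = 2)$y +
                 stats::approx(tg, col, xout = cycles$t_trough,
                               rule = 2)$y) / 2
      col <- stats::approx(cycles$midpoint, at_cyc, xout = tg, rule = 2)$y
    }
    signal::filtfilt(bp, col)
  })
  fit <- glm_invert(ts, des)
  list(csp = unname(fit$betas["CS+"]), csm = unname(fit$betas["CS-"]),
       fit = fit)
}
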