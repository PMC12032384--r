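#' Skin conductance preprocessing
#'
#' Applies the published artifact rules: samples outside the valid range
#' (0.05-100 microsiemens) or with an absolute slope over 10 uS/s are
#' marked missing; missing spans are linearly interpolated for filtering
#' (and stay flagged for estimation); the series is band-pass filtered with
#' a bidirectional 1st-order Butterworth (0.0159-5 Hz) and downsampled to
#' 10 Hz.
#'
#' @param ts raw skin conductance [pav_ts()] in microsiemens, rate >= 10 Hz.
#' @param valid_range plausible conductance range (uS).
#' @param max_slope maximum absolute slope (uS/s).
#' @param band band-pass cutoffs (Hz).
#' @param out_rate output rate (Hz).
#' @return a [pav_ts()] at `out_rate` with the artifact mask carried
#'   through; attribute `channel_invalid` is `TRUE` when more than 90% of
#'   the raw samples are missing.
#' @export
scr_preprocess <- function(ts, valid_range = c(0.05, 100), max_slope = 10,
                           band = c(0.0159, 5), out_rate = 10) {
  stopifnot(inherits(ts, "pav_ts"), ts$rate >= out_rate)
  x <- ts$values
  valid <- ts$valid & !is.na(x)
  valid[!is.na(x) & (x < valid_range[1] | x > valid_range[2])] <- FALSE
  slope <- c(0, abs(diff(x)) * ts$rate)
  valid[!is.na(slope) & slope > max_slope] <- FALSE
  # a steep rise makes both flanking samples suspect
  valid[which(!is.na(slope) & slope > max_slope) - 1L] <- FALSE
  channel_invalid <- mean(!valid) > 0.9
  t <- ts_time(ts)
  if (any(valid) && any(!valid)) {
    x[!valid] <- stats::approx(t[valid], x[valid], xout = t[!valid],
                               rule = 2)$y
  }
  x[is.na(x)] <- if (any(valid)) mean(x[valid]) else 0
  bp <- signal::butter(1, band / (ts$rate / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))  # demean: limit edge transients
  step <- round(ts$rate / out_rate)
  keep <- seq(1L, length(xf), by = step)
  out <- pav_ts(xf[keep], rate = ts$rate / step, start = ts$start,
                units = "uS", valid = valid[keep])
  attr(out, "channel_invalid") <- channel_invalid
  out
}

#' Canonical skin conductance response kernel
#'
#' A bi-exponential (difference of exponentials) phasic kernel with onset
#' latency `t0`, rise time constant `tau_rise` and decay time constant
#' `tau_decay`, normalised to unit peak. This is a named, configurable
#' stand-in for the validated peripheral SCR model; the trial-wise
#' estimator built on it is labelled `estimator = "constrained_glm"`.
#'
#' @param t0 onset latency after the driving event (s).
#' @param tau_rise,tau_decay rise/decay time constants (s).
#' @param support kernel support (s).
#' @return a `pav_rf` empirical kernel at 100 Hz.
#' @export
scr_kernel <- function(t0 = 1, tau_rise = 0.8, tau_decay = 4,
                       support = c(0, 25)) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  t <- seq(support[1], support[2], by = 0.01)
  x <- pmax(t - t0, 0)
  v <- exp(-x / tau_decay) - exp(-x / tau_rise)
  v[t < t0] <- 0
  rf_empirical(t, v / max(v),
               provenance = "canonical bi-exponential SCR kernel",
               name = "scrf")
}

#' Trial-wise SCR amplitude estimation (constrained GLM)
#'
#' Estimates, per trial, a CS-onset-locked response and a US/US-omission
#' response at `cs_onset + soa`, by inverting one session-wide trial-wise
#' GLM in which every CS and every US/omission event has its own regressor
#' (all responses are modelled jointly, so neighbouring-trial overlap does
#' not bias the estimates). This is a linear approximation of the
#' variational trial-wise estimator used with real data.
#'
#' @param ts preprocessed SCR [pav_ts()] (see [scr_preprocess()]).
#' @param events event table.
#' @param kernel the SCR kernel (default [scr_kernel()]).
#' @param soa CS onset to US (or omission) interval (s).
#' @param band the band-pass applied to the data by [scr_preprocess()];
#'   re-applied to the regressors so filtering does not bias the
#'   amplitudes (`NULL` to skip).
#' @return data.frame with one row per trial: `trial_index`, `condition`,
#'   `reinforced`, `cs_amplitude`, `us_amplitude`, `retained`; attribute
#'   `estimator` is `"constrained_glm"`.
#' @export
estimate_scr_amplitudes <- function(ts, events, kernel = scr_kernel(),
                                    soa = 5, band = c(0.0159, 5)) {
  n <- length(ts$values)
  cs_des <- build_design(events, kernel, rate = ts$rate, n_samples = n,
                         mode = "trial", intercept = FALSE)
  ev_us <- events
  ev_us$cs_onset <- ev_us$cs_onset + soa
  us_des <- build_design(ev_us, kernel, rate = ts$rate, n_samples = n,
                         mode = "trial", intercept = FALSE)
  colnames(us_des$X) <- sub("^trial_", "us_", colnames(us_des$X))
  X <- cbind(cs_des$X, us_des$X)
  if (!is.null(band)) {
    bp <- signal::butter(1, pmin(band, ts$rate / 2 * 0.999) / (ts$rate / 2),
                         type = "pass")
    X <- apply(X, 2, function(col) signal::filtfilt(bp, col))
  }
  X <- cbind(X, `(intercept)` = 1)
  fit <- glm_invert(ts, X)
  cs_amp <- fit$betas[paste0("trial_", events$trial_index)]
  us_amp <- fit$betas[paste0("us_", events$trial_index)]
  out <- data.frame(trial_index = events$trial_index,
                    condition = events$condition,
                    reinforced = events$reinforced,
                    cs_amplitude = unname(cs_amp),
                    us_amplitude = unname(us_amp),
                    retained = TRUE)
  attr(out, "estimator") <- "constrained_glm"
  out
}

#' Normalize SCR amplitudes by the participant's CS− mean
#'
#' Divides every amplitude by the mean CS− `cs_amplitude` of the same
#' participant, making estimates dimensionless and invariant to
#' multiplicative gain changes of the raw channel. When the CS− mean is
#' not positive the participant is flagged and normalization skipped with
#' a warning.
#'
#' @param est trial estimates from [estimate_scr_amplitudes()].
#' @return `est` with amplitudes normalized and attribute
#'   `normalization_failed` (logical).
#' @export
normalize_by_csminus <- function(est) {
  csm <- est$cs_amplitude[est$condition == "CS-" & est$retained]
  csm <- csm[!is.na(csm)]
  if (!length(csm)) stop("no valid CS- trials to normalize by")
  denom <- mean(csm)
  if (denom <= 0) {
    warning("CS- mean amplitude <= 0; normalization skipped")
    attr(est, "normalization_failed") <- TRUE
    return(est)
  }
  est$cs_amplitude <- est$cs_amplitude / denom
  est$us_amplitude <- est$us_amplitude / denom
  attr(est, "normalization_failed") <- FALSE
  est
}
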