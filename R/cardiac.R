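#' Inter-beat intervals from beat timestamps
#'
#' Computes the preceding inter-beat interval (IBI) for each detected beat
#' and applies the cardiac range filter: IBIs corresponding to a heart rate
#' outside 50-150 beats per minute are marked invalid.
#'
#' @param beat_times strictly increasing beat timestamps (s), length >= 2.
#' @param bpm_range valid heart-rate range in beats per minute.
#' @return data.frame with `beat_time` (time of the second beat of each
#'   interval), `ibi` (s), and `valid`.
#' @export
beats_to_ibi <- function(beat_times, bpm_range = c(50, 150)) {
  stopifnot(length(beat_times) >= 2L)
  if (any(diff(beat_times) <= 0))
    stop("beat timestamps must be strictly increasing")
  ibi <- diff(beat_times)
  bpm <- 60 / ibi
  data.frame(beat_time = beat_times[-1L], ibi = ibi,
             valid = bpm >= bpm_range[1] & bpm <= bpm_range[2])
}

#' Continuous heart-period series from IBIs
#'
#' Valid IBIs are linearly interpolated in chronological time onto a
#' uniform grid (default 100 Hz), converted to milliseconds, and band-pass
#' filtered with a zero-phase (bidirectional) Butterworth filter
#' (0.015-0.5 Hz). Invalid IBIs are bridged by the interpolation; gaps of
#' valid data longer than `max_gap` seconds are marked invalid in the
#' output mask.
#'
#' @param ibi data.frame from [beats_to_ibi()].
#' @param rate output rate (Hz).
#' @param band band-pass cutoffs (Hz), `c(high_pass, low_pass)`.
#' @param max_gap longest bridged gap (s) before samples are flagged
#'   invalid.
#' @param t_start,t_end output grid limits (s); default to the beat range.
#' @param anchor where in its interval each IBI value is anchored for the
#'   chronological interpolation: `"midpoint"` (default; an interval
#'   estimates the heart period halfway through it, avoiding a systematic
#'   half-beat lag) or `"beat"` (the second beat).
#' @return a [pav_ts()] in ms at `rate`, band-passed; attribute `anchors`
#'   holds the anchor times used.
#' @export
ibi_to_heart_period <- function(ibi, rate = 100, band = c(0.015, 0.5),
                                max_gap = 5, t_start = 0, t_end = NULL,
                                anchor = c("midpoint", "beat")) {
  anchor <- match.arg(anchor)
  ok <- ibi$valid
  if (sum(ok) < 2L) stop("fewer than 2 valid inter-beat intervals")
  tv <- ibi$beat_time[ok]
  if (anchor == "midpoint") tv <- tv - ibi$ibi[ok] / 2
  xv <- ibi$ibi[ok] * 1000
  if (is.null(t_end)) t_end <- max(ibi$beat_time)
  if ((t_end - t_start) * min(band) < 0.5)
    stop("session too short for the ", band[1],
         "-Hz high-pass warm-up; record longer or pad the series")
  ts <- resample_linear(tv, xv, rate, t_start = t_start, t_end = t_end)
  # demean before filtering: the ~900-ms DC level would otherwise drive
  # large edge transients of the very-low-cutoff high-pass
  ts$values <- butter_bandpass(ts$values - mean(ts$values), rate,
                               high = band[1], low = band[2], order = 2)
  ts$units <- "ms"
  # flag samples inside bridged gaps longer than max_gap
  gaps <- which(diff(tv) > max_gap)
  tgrid <- ts_time(ts)
  for (g in gaps)
    ts$valid[tgrid > tv[g] & tgrid < tv[g + 1L]] <- FALSE
  attr(ts, "anchors") <- tv
  ts
}

#' Baseline-corrected trial segments
#'
#' Extracts per-trial segments of a uniformly sampled series, subtracting
#' the mean over a pre-CS baseline window from each. For heart period the
#' retained trials are CS− and nonreinforced CS+ only (the response
#' outlasts the CS-US interval, so reinforced trials are contaminated by
#' the US response).
#'
#' @param ts a [pav_ts()].
#' @param events event table.
#' @param window post-onset segment length (s).
#' @param baseline_window pre-onset baseline length (s).
#' @param retain `"nonreinforced"` (CS− plus nonreinforced CS+, the heart
#'   period rule) or `"all"`.
#' @return list with `values` (trials x samples matrix, `NA` at invalid
#'   samples), `rel_time` (s, 0 = CS onset), and `trials` (metadata with
#'   `missing_fraction` and a `complete` flag; trials whose window exceeds
#'   the recording are flagged incomplete).
#' @export
extract_segments <- function(ts, events, window = 25, baseline_window = 5,
                             retain = c("nonreinforced", "all")) {
  retain <- match.arg(retain)
  ev <- events
  if (retain == "nonreinforced")
    ev <- ev[ev$condition == "CS-" | !ev$reinforced, ]
  rel <- seq(-baseline_window, window, by = 1 / ts$rate)
  n <- length(ts$values)
  vals <- matrix(NA_real_, nrow(ev), length(rel))
  miss <- numeric(nrow(ev))
  complete <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- round((ev$cs_onset[i] - ts$start + rel) * ts$rate) + 1L
    inside <- idx >= 1L & idx <= n
    complete[i] <- all(inside)
    seg <- rep(NA_real_, length(rel))
    seg[inside] <- ts$values[idx[inside]]
    seg[inside][!ts$valid[idx[inside]]] <- NA
    base <- seg[rel < 0]
    base_mean <- if (all(is.na(base))) NA_real_ else mean(base, na.rm = TRUE)
    vals[i, ] <- seg - base_mean
    post <- seg[rel >= 0]
    miss[i] <- mean(is.na(post))
  }
  trials <- ev
  trials$missing_fraction <- miss
  trials$complete <- complete
  list(values = vals, rel_time = rel, trials = trials)
}

#' Grand-mean condition difference waveform
#'
#' Averages baseline-corrected segments first within condition and
#' participant, then across participants, and returns the CS+ minus CS−
#' difference as an empirical waveform (the input to response-function
#' fitting). Participants lacking either condition are dropped with a
#' warning.
#'
#' @param segment_list list of [extract_segments()] results, one per
#'   participant (all on the same `rel_time` grid).
#' @return a `pav_rf` empirical kernel holding the difference waveform.
#' @export
condition_mean_difference <- function(segment_list) {
  stopifnot(length(segment_list) >= 1L)
  rel <- segment_list[[1L]]$rel_time
  per_part <- lapply(segment_list, function(s) {
    stopifnot(identical(s$rel_time, rel))
    csp <- s$values[s$trials$condition == "CS+", , drop = FALSE]
    csm <- s$values[s$trials$condition == "CS-", , drop = FALSE]
    if (nrow(csp) == 0L || nrow(csm) == 0L) return(NULL)
    colMeans(csp, na.rm = TRUE) - colMeans(csm, na.rm = TRUE)
  })
  drop <- vapply(per_part, is.null, TRUE)
  if (any(drop))
    warning(sum(drop), " participant(s) lacking a condition dropped from ",
            "the grand mean")
  per_part <- per_part[!drop]
  if (!length(per_part)) stop("no participant has both conditions")
  diffw <- colMeans(do.call(rbind, per_part), na.rm = TRUE)
  rf_empirical(rel, diffw, provenance = "grand mean CS+ - CS- difference")
}

#' Condition-wise heart-period response amplitudes
#'
#' Condition-wise convolution GLM on the band-passed heart-period series:
#' one regressor for nonreinforced CS+ onsets, one for CS− onsets, plus
#' nuisance regressors for reinforced CS+ onsets and US onsets (present in
#' the recording but not analysed). Design columns are passed through the
#' same transform as the data — optionally the beat-level sampling and
#' interpolation (when the series carries its `anchors` attribute from
#' [ibi_to_heart_period()]), then the zero-phase band-pass — so neither
#' resampling nor filtering biases the amplitude estimates.
#'
#' @param ts band-passed heart-period [pav_ts()] (ms).
#' @param events event table.
#' @param rf the heart-period kernel (default `rf_registry("hprf_rew")`).
#' @param band the band-pass applied to the data (re-applied to the
#'   regressors); `NULL` to skip.
#' @return list with `csp` and `csm` amplitudes (ms), and the full
#'   [glm_invert()] `fit`.
#' @export
estimate_hpr_amplitudes <- function(ts, events, rf = rf_registry("hprf_rew"),
                                    band = c(0.015, 0.5)) {
  anchors <- attr(ts, "anchors")
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
  task <- colnames(des$X) != "(intercept)"
  des$X[, task] <- apply(des$X[, task, drop = FALSE], 2, function(col) {
    if (!is.null(anchors)) {
      at <- stats::approx(tg, col, xout = anchors, rule = 2)$y
      col <- stats::approx(anchors, at, xout = tg, rule = 2)$y
    }
    if (!is.null(band))
      col <- butter_bandpass(col, ts$rate, high = band[1], low = band[2],
                             order = 2)
    col
  })
  fit <- glm_invert(ts, des)
  list(csp = unname(fit$betas["CS+"]), csm = unname(fit$betas["CS-"]),
       fit = fit)
}
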