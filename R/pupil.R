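#' Pupil preprocessing specification
#'
#' Validity-filter and preprocessing constants for pupil diameter.
#' Thresholds not printed in the published protocol follow the cited
#' preprocessing algorithm's defaults and are all configurable: plausible
#' diameter range 1.5-9 mm, dilation-speed outlier criterion of
#' median + `speed_mad_mult` * MAD, 40-ms trim around gaps, islands of
#' valid data shorter than 50 ms removed.
#'
#' @param range plausible diameter range (mm).
#' @param speed_mad_mult multiplier of the median absolute deviation in the
#'   dilation-speed criterion.
#' @param gap_min_dur gap duration (s) above which edges are trimmed.
#' @param gap_edge trim margin around gaps (s).
#' @param island_min_dur minimum duration (s) of a retained valid run.
#' @param speed_min absolute dilation-speed floor (mm/s) below which
#'   samples are never flagged, guarding the MAD criterion against
#'   degenerate (near-noiseless) recordings where ordinary response slopes
#'   would otherwise become "outliers".
#' @param gaze_limit maximum gaze deviation from screen centre (degrees
#'   visual angle).
#' @param lowpass low-pass cutoff (Hz) applied before resampling.
#' @param out_rate output rate (Hz).
#' @return a list of class `pupil_preproc_spec`.
#' @export
pupil_preproc_spec <- function(range = c(1.5, 9), speed_mad_mult = 16,
                               gap_min_dur = 0.075, gap_edge = 0.04,
                               island_min_dur = 0.05, speed_min = 10,
                               gaze_limit = 5, lowpass = 50,
                               out_rate = 100) {
  structure(list(range = range, speed_mad_mult = speed_mad_mult,
                 gap_min_dur = gap_min_dur, gap_edge = gap_edge,
                 island_min_dur = island_min_dur, speed_min = speed_min,
                 gaze_limit = gaze_limit,
                 lowpass = lowpass, out_rate = out_rate),
            class = "pupil_preproc_spec")
}

# Extend an invalid mask: trim gap edges and drop short valid islands.
trim_mask <- function(valid, rate, spec) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  edge_n <- round(spec$gap_edge * rate)
  gap_n <- round(spec$gap_min_dur * rate)
  island_n <- round(spec$island_min_dur * rate)
  out <- valid
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] && r$lengths[k] >= gap_n) {
      lo <- max(1L, starts[k] - edge_n)
      hi <- min(length(valid), ends[k] + edge_n)
      out[lo:hi] <- FALSE
    }
    if (r$values[k] && r$lengths[k] < island_n) {
      left_gap <- k > 1L && !r$values[k - 1L]
      right_gap <- k < length(r$lengths) && !r$values[k + 1L]
      if (left_gap || right_gap) out[starts[k]:ends[k]] <- FALSE
    }
  }
  out
}

#' Preprocess a pupil diameter series
#'
#' Marks invalid samples (out-of-range diameter, dilation-speed outliers by
#' a median-absolute-deviation criterion, gap edges and isolated islands),
#' removes samples with gaze more than `gaze_limit` degrees from the screen
#' centre, applies a first-order cosine foreshortening correction
#' (diameter divided by the cosine of the angular gaze deviation),
#' interpolates, low-pass filters at 50 Hz (when below Nyquist), resamples
#' to 100 Hz, and optionally z-scores each block.
#'
#' @param ts pupil diameter [pav_ts()] in mm.
#' @param gaze_x,gaze_y gaze coordinates (degrees visual angle from screen
#'   centre), same length as `ts$values`.
#' @param events event table (provides block boundaries for z-scoring).
#' @param spec a [pupil_preproc_spec()].
#' @param zscore z-score the series within each block (`TRUE`, the model
#'   default, units `"z"`) or keep millimetres (`FALSE`).
#' @return a [pav_ts()] at `spec$out_rate` with the invalid mask carried
#'   through.
#' @export
pupil_preprocess <- function(ts, gaze_x, gaze_y, events,
                             spec = pupil_preproc_spec(), zscore = TRUE) {
  stopifnot(inherits(ts, "pav_ts"),
            length(gaze_x) == length(ts$values),
            length(gaze_y) == length(ts$values))
  x <- ts$values
  valid <- ts$valid & !is.na(x)
  if (!any(valid)) stop("pupil channel entirely missing")
  valid[!is.na(x) & (x < spec$range[1] | x > spec$range[2])] <- FALSE
  # dilation-speed criterion on neighbouring differences
  d <- abs(diff(x)) * ts$rate
  speed <- pmax(c(d[1], d), c(d, d[length(d)]), na.rm = TRUE)
  thr <- max(stats::median(speed[valid], na.rm = TRUE) +
               spec$speed_mad_mult * stats::mad(speed[valid], na.rm = TRUE),
             spec$speed_min)
  valid[!is.na(speed) & speed > thr] <- FALSE
  # gaze filter and foreshortening correction
  dev <- sqrt(gaze_x^2 + gaze_y^2)
  valid[is.na(dev) | dev > spec$gaze_limit] <- FALSE
  corr <- x / cos(pmin(dev, 89) * pi / 180)
  valid <- trim_mask(valid, ts$rate, spec)
  t <- ts_time(ts)
  y <- corr
  if (any(!valid)) {
    if (sum(valid) < 2L) stop("pupil channel entirely missing")
    y[!valid] <- stats::approx(t[valid], corr[valid], xout = t[!valid],
                               rule = 2)$y
  }
  if (spec$lowpass < ts$rate / 2)
    y <- butter_bandpass(y, ts$rate, low = spec$lowpass, order = 2)
  out <- resample_linear(t, y, spec$out_rate, t_start = t[1L],
                         t_end = t[length(t)])
  vres <- stats::approx(t, as.numeric(valid), xout = ts_time(out),
                        method = "constant", f = 0, rule = 2)$y
  out$valid <- vres >= 1
  out$units <- "mm"
  if (zscore) {
    # block b spans from its first CS onset (first block: recording start)
    # to the next block's first CS onset
    block_start <- tapply(events$cs_onset, events$block, min)
    edges <- c(-Inf, unname(block_start)[-1L], Inf)
    tg <- ts_time(out)
    for (b in seq_len(length(edges) - 1L)) {
      in_b <- tg >= edges[b] & tg < edges[b + 1L]
      if (!any(in_b)) next
      mu <- mean(out$values[in_b])
      sdv <- stats::sd(out$values[in_b])
      if (!is.finite(sdv) || sdv < 1e-8) {
        warning("block ", b, ": near-zero variance; SD floor applied")
        sdv <- 1
      }
      out$values[in_b] <- (out$values[in_b] - mu) / sdv
    }
    out$units <- "z"
  }
  out
}

#' Extract pupil trial segments for a given kernel or scoring window
#'
#' Window lengths follow the kernel registry (15 s for RF1, 3.5 s for RF2
#' and RF6, 3 s for RF3-RF5). RF1 extends beyond the CS-US interval, so
#' only nonreinforced CS+ trials (plus all CS−) are retained for it; all
#' other kernels use all trials. A 2-s pre-CS baseline stretch is always
#' included so the peak-scoring methods can use the same segments.
#'
#' @param ts preprocessed pupil [pav_ts()].
#' @param events event table.
#' @param rf kernel name (see [rf_registry()]), a `pav_rf`, or `NULL` to
#'   use an explicit `window`.
#' @param window segment length (s) when `rf` is `NULL`.
#' @param baseline_window pre-CS stretch (s) included in the segment.
#' @return as [extract_segments()].
#' @export
extract_pupil_segments <- function(ts, events, rf = NULL, window = 5,
                                   baseline_window = 2) {
  retain <- "all"
  if (!is.null(rf)) {
    if (is.character(rf)) rf <- rf_registry(rf)
    stopifnot(inherits(rf, "pav_rf"), !is.na(rf$window))
    window <- rf$window
    if (identical(rf$name, "psr_rf1")) retain <- "nonreinforced"
  }
  extract_segments(ts, events, window = window,
                   baseline_window = baseline_window, retain = retain)
}

#' Trial-wise pupil response amplitudes
#'
#' Projects each segment onto the kernel over `[0, window]`
#' (see [trialwise_amplitude()]). Baseline samples are not part of the fit.
#'
#' @param segments output of [extract_pupil_segments()].
#' @param rf kernel name or `pav_rf`.
#' @return data.frame of trial estimates: `trial_index`, `condition`,
#'   `reinforced`, `amplitude`, `missing_fraction`.
#' @export
psr_amplitudes <- function(segments, rf) {
  if (is.character(rf)) rf <- rf_registry(rf)
  post <- segments$rel_time >= 0 & segments$rel_time <= rf$window
  k <- rf_evaluate(rf, segments$rel_time[post], normalise = TRUE)
  amps <- apply(segments$values[, post, drop = FALSE], 1,
                trialwise_amplitude, kernel = k)
  data.frame(trial_index = segments$trials$trial_index,
             condition = segments$trials$condition,
             reinforced = segments$trials$reinforced,
             amplitude = amps,
             missing_fraction = segments$trials$missing_fraction)
}

#' Trial-wise pupil amplitudes via a session-wide GLM
#'
#' Joint estimation of all retained trials in one trial-wise convolution
#' GLM over the whole session. Used for RF1, whose 15-s support is as long
#' as the shortest trial spacing, so segment projection would be biased by
#' the preceding trial's tail.
#'
#' @param ts preprocessed pupil [pav_ts()].
#' @param events event table.
#' @param rf kernel name or `pav_rf`.
#' @param retained trial indices to report; defaults to the kernel's
#'   retention rule (nonreinforced CS+ plus CS− for RF1, all otherwise).
#'   Every trial gets a regressor — non-retained trials are modelled as
#'   nuisance so their responses cannot bias the retained estimates — but
#'   only retained trials are reported.
#' @return data.frame as [psr_amplitudes()] (retained trials only).
#' @export
psr_amplitudes_joint <- function(ts, events, rf, retained = NULL) {
  if (is.character(rf)) rf <- rf_registry(rf)
  if (is.null(retained)) {
    retained <- if (identical(rf$name, "psr_rf1"))
      events$trial_index[events$condition == "CS-" | !events$reinforced]
    else events$trial_index
  }
  des <- build_design(events, rf, rate = ts$rate,
                      n_samples = length(ts$values), mode = "trial",
                      retained = events$trial_index, intercept = TRUE,
                      normalise = TRUE)
  fit <- glm_invert(ts, des)
  ev <- events[events$trial_index %in% retained, ]
  miss <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- round((ev$cs_onset[i] - ts$start) * ts$rate) + 1L
    idx <- idx:min(idx + round(rf$window * ts$rate), length(ts$values))
    mean(!ts$valid[idx])
  }, 0)
  data.frame(trial_index = ev$trial_index, condition = ev$condition,
             reinforced = ev$reinforced,
             amplitude = unname(fit$betas[paste0("trial_", ev$trial_index)]),
             missing_fraction = miss)
}

#' Peak-scored pupil dilation
#'
#' Two standard baseline-corrected maximum scores. Method `"finke"`:
#' baseline is the mean over the 1-s pre-CS period; the score is the
#' maximum of the baseline-corrected series between CS onset and US onset
#' (`soa` s). Method `"pietrock"`: baseline spans the 2-s pre-CS period;
#' the peak is the maximum during the final second before US onset. Trials
#' with an all-missing baseline are marked missing.
#'
#' @param segments output of [extract_pupil_segments()] with
#'   `baseline_window >= 2` and `window >= soa`.
#' @param method `"finke"` or `"pietrock"`.
#' @param soa CS onset to US onset interval (s).
#' @return data.frame of trial estimates (as [psr_amplitudes()]).
#' @export
peak_score <- function(segments, method = c("finke", "pietrock"), soa = 5) {
  method <- match.arg(method)
  rel <- segments$rel_time
  if (method == "finke") {
    base_idx <- rel >= -1 & rel < 0
    peak_idx <- rel >= 0 & rel <= soa
  } else {
    base_idx <- rel >= -2 & rel < 0
    peak_idx <- rel >= soa - 1 & rel <= soa
  }
  score_one <- function(seg) {
    base <- seg[base_idx]
    if (all(is.na(base))) return(NA_real_)
    win <- seg[peak_idx]
    if (all(is.na(win))) return(NA_real_)
    max(win, na.rm = TRUE) - mean(base, na.rm = TRUE)
  }
  amps <- apply(segments$values, 1, score_one)
  data.frame(trial_index = segments$trials$trial_index,
             condition = segments$trials$condition,
             reinforced = segments$trials$reinforced,
             amplitude = amps,
             missing_fraction = segments$trials$missing_fraction)
}

#' Pupil trial and participant exclusion rules
#'
#' Drops trials with implausible amplitude estimates (|estimate| above
#' `max_abs`, the printed +/-6-mm rule) or with more than
#' `max_missing_fraction` missing samples; flags the participant when more
#' than `max_excluded_fraction` of trials are dropped.
#'
#' @param est trial estimates (from [psr_amplitudes()] or [peak_score()]).
#' @param max_abs maximum absolute estimate.
#' @param max_missing_fraction per-trial missing-data limit.
#' @param max_excluded_fraction participant-level limit on dropped trials.
#' @return list with `estimates` (retained trials), `n_excluded`, and
#'   `participant_excluded`.
#' @export
apply_pupil_exclusions <- function(est, max_abs = 6,
                                   max_missing_fraction = 0.5,
                                   max_excluded_fraction = 0.5) {
  bad <- is.na(est$amplitude) | abs(est$amplitude) > max_abs |
    est$missing_fraction > max_missing_fraction
  list(estimates = est[!bad, , drop = FALSE],
       n_excluded = sum(bad),
       participant_excluded = mean(bad) > max_excluded_fraction)
}
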