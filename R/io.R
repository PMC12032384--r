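#' Write / read a channel time series as delimited text
#'
#' Channels are stored as tab-separated text (`time_s`, `value`, `valid`)
#' with a small DCF sidecar (`<path>.meta`) carrying units, rate and start
#' time, so fixtures stay diffable. The round trip is lossless for values,
#' mask and metadata.
#'
#' @param ts a [pav_ts()].
#' @param path output path (`.tsv`).
#' @return `write_channel()`: the path, invisibly; `read_channel()`: a
#'   [pav_ts()].
#' @export
write_channel <- function(ts, path) {
  stopifnot(inherits(ts, "pav_ts"))
  df <- data.frame(time_s = ts_time(ts), value = ts$values,
                   valid = as.integer(ts$valid))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- data.frame(units = ts$units, rate = ts$rate, start = ts$start)
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_channel
#' @export
read_channel <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column in ", path)
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
    units <- meta$units
    rate <- as.numeric(meta$rate)
    start <- as.numeric(meta$start)
  } else {
    warning("missing sidecar ", meta_path, "; inferring metadata")
    units <- ""
    rate <- 1 / stats::median(diff(df$time_s))
    start <- df$time_s[1L]
  }
  med_dt <- stats::median(diff(df$time_s))
  if (abs(med_dt * rate - 1) > 0.01)
    stop("declared rate inconsistent with sampling interval in ", path)
  valid <- if ("valid" %in% names(df)) df$valid == 1 else NULL
  pav_ts(df$value, rate = rate, start = start, units = units, valid = valid)
}

#' Write / import an event table as BIDS-events-like TSV
#'
#' Columns: `onset`, `duration`, `trial_type` (`CS+`/`CS-`), `reinforced`,
#' `block`, `us_onset`, `iti_duration`, `swallow_onset`, all times in
#' seconds. `import_events()` validates structure (required columns,
#' strictly increasing onsets, no reinforced CS−) and returns the internal
#' event-table layout.
#'
#' @param events internal event table (see [generate_trial_sequence()]).
#' @param path file path.
#' @param cs_duration CS duration written to the `duration` column.
#' @return `import_events()`: the internal event table data.frame.
#' @export
write_events <- function(events, path, cs_duration = 6) {
  out <- data.frame(onset = events$cs_onset, duration = cs_duration,
                    trial_type = events$condition,
                    reinforced = as.integer(events$reinforced),
                    block = events$block, us_onset = events$us_onset,
                    iti_duration = events$iti_duration,
                    swallow_onset = events$swallow_onset)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
import_events <- function(path) {
  df <- utils::read.delim(path, na.strings = c("NA", "n/a"))
  need <- c("onset", "trial_type", "reinforced", "block", "us_onset",
            "iti_duration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("events file lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(diff(df$onset) <= 0)) stop("onsets not strictly increasing")
  if (any(df$reinforced == 1 & df$trial_type == "CS-"))
    stop("validation error: reinforced CS- row present")
  data.frame(trial_index = seq_len(nrow(df)), block = df$block,
             condition = df$trial_type, reinforced = df$reinforced == 1,
             cs_onset = df$onset, us_onset = df$us_onset,
             iti_duration = df$iti_duration,
             swallow_onset = if ("swallow_onset" %in% names(df))
               df$swallow_onset else NA_real_)
}

#' Run the full simulate-preprocess-estimate-report pipeline
#'
#' Executes: synthetic cohort generation, per-channel preprocessing and
#' amplitude estimation, exclusions, paired tests with Hedges g, and the
#' calibration report. Identical config and seed reproduce identical
#' outputs. When `outdir` is given, per-measure condition-estimate tables
#' and the report are written as TSV.
#'
#' @param config list with elements `design` ([design_spec()]), `cohort`
#'   ([cohort_spec()]), `phase`, `channels`, `sides`, `threshold`, and
#'   optional `outdir`.
#' @return list with `report` (see [calibration_report()]) and `analysis`
#'   (see [analyze_cohort()]).
#' @export
run_pipeline <- function(config) {
  design <- if (is.null(config$design)) design_spec() else config$design
  cspec <- if (is.null(config$cohort)) cohort_spec() else config$cohort
  phase <- if (is.null(config$phase)) "learning" else config$phase
  channels <- if (is.null(config$channels))
    c("hpr", "scr", "psr_rf5", "peak1", "peak2", "rar") else config$channels
  sides <- if (is.null(config$sides)) "two" else config$sides
  threshold <- if (is.null(config$threshold)) 0.5 else config$threshold
  if (phase == "recall") channels <- setdiff(channels, "rar")

  cohort <- simulate_cohort(design, cspec, phase = phase)
  analysis <- analyze_cohort(cohort, design, channels = channels)
  report <- calibration_report(analysis$condition_estimates,
                               threshold = threshold, sides = sides)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(analysis$condition_estimates))
      utils::write.table(analysis$condition_estimates[[m]],
                         file.path(config$outdir,
                                   paste0("estimates_", m, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report, file.path(config$outdir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(report = report, analysis = analysis)
}
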