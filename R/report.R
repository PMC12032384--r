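#' Analyse a simulated or imported cohort across channels
#'
#' Runs each channel's preprocessing and estimation stage for every
#' participant and assembles per-participant condition estimates (and
#' trial-level estimates where the channel provides them). Channel labels:
#' `"hpr"` (heart period, condition-wise GLM), `"scr"` (trial-wise
#' constrained GLM, CS−-normalized), `"psr_rf1"` ... `"psr_rf6"` (pupil,
#' trial-wise), `"peak1"`/`"peak2"` (pupil peak scoring), `"rar"`
#' (respiration amplitude, condition-wise GLM; learning phase only by
#' convention).
#'
#' Condition estimates follow the retention rules: nonreinforced CS+ only
#' for HPR, SCR, PSR RF1 and RAR (US-overlapping kernels); all CS+ trials
#' for PSR RF2-6 and peak scoring.
#'
#' @param cohort list of recordings from [simulate_cohort()].
#' @param design the [design_spec()] used.
#' @param channels character vector of channel labels (see Details).
#' @param pupil_zscore z-score pupil series per block (`TRUE`, the default
#'   analysis units) or keep mm (`FALSE`, used for amplitude-recovery
#'   checks).
#' @param pupil_spec a [pupil_preproc_spec()].
#' @return list with `condition_estimates` (named list of data.frames with
#'   `participant`, `csp`, `csm`), `trial_estimates` (named list of
#'   trial-level data.frames), and `pupil_excluded` (named list of logical
#'   vectors).
#' @export
analyze_cohort <- function(cohort, design,
                           channels = c("hpr", "scr", "psr_rf5", "peak1",
                                        "peak2", "rar"),
                           pupil_zscore = TRUE,
                           pupil_spec = pupil_preproc_spec()) {
  cond_est <- list()
  trial_est <- list()
  pupil_excl <- list()
  add_cond <- function(name, p, csp, csm) {
    cond_est[[name]] <<- rbind(cond_est[[name]],
                               data.frame(participant = p, csp = csp,
                                          csm = csm))
  }
  add_trials <- function(name, p, df) {
    df$participant <- p
    trial_est[[name]] <<- rbind(trial_est[[name]], df)
  }
  psr_channels <- grep("^psr_rf", channels, value = TRUE)
  need_pupil <- length(psr_channels) > 0 ||
    any(c("peak1", "peak2") %in% channels)

  for (rec in cohort) {
    p <- rec$participant
    ev <- rec$events
    if ("hpr" %in% channels) {
      ibi <- beats_to_ibi(rec$beats)
      hp <- ibi_to_heart_period(ibi, t_end = rec$t_end)
      est <- estimate_hpr_amplitudes(hp, ev)
      add_cond("hpr", p, est$csp, est$csm)
    }
    if ("scr" %in% channels) {
      sp <- scr_preprocess(rec$scr)
      est <- normalize_by_csminus(estimate_scr_amplitudes(sp, ev,
                                                          soa = design$soa))
      keep <- est$retained & !is.na(est$cs_amplitude)
      nonreinf <- keep & (est$condition == "CS-" | !est$reinforced)
      add_cond("scr", p,
               mean(est$cs_amplitude[nonreinf & est$condition == "CS+"]),
               mean(est$cs_amplitude[nonreinf & est$condition == "CS-"]))
      tdf <- est[nonreinf, c("trial_index", "condition", "reinforced")]
      tdf$amplitude <- est$cs_amplitude[nonreinf]
      add_trials("scr", p, tdf)
    }
    if (need_pupil) {
      pts <- pupil_preprocess(rec$pupil$pupil, rec$pupil$gaze_x,
                              rec$pupil$gaze_y, ev, spec = pupil_spec,
                              zscore = pupil_zscore)
      for (rf_name in psr_channels) {
        rf <- rf_registry(rf_name)
        est <- if (identical(rf_name, "psr_rf1"))
          psr_amplitudes_joint(pts, ev, rf)
        else
          psr_amplitudes(extract_pupil_segments(pts, ev, rf), rf)
        ex <- apply_pupil_exclusions(est)
        pupil_excl[[rf_name]] <- c(pupil_excl[[rf_name]],
                                   ex$participant_excluded)
        est <- ex$estimates
        if (!nrow(est) || ex$participant_excluded) next
        add_cond(rf_name, p,
                 mean(est$amplitude[est$condition == "CS+"], na.rm = TRUE),
                 mean(est$amplitude[est$condition == "CS-"], na.rm = TRUE))
        add_trials(rf_name, p,
                   est[, c("trial_index", "condition", "reinforced",
                           "amplitude")])
      }
      for (pk in intersect(c("peak1", "peak2"), channels)) {
        segs <- extract_pupil_segments(pts, ev, rf = NULL,
                                       window = design$soa)
        est <- peak_score(segs,
                          method = if (pk == "peak1") "finke"
                                   else "pietrock",
                          soa = design$soa)
        ex <- apply_pupil_exclusions(est)
        est <- ex$estimates
        if (!nrow(est) || ex$participant_excluded) next
        add_cond(pk, p,
                 mean(est$amplitude[est$condition == "CS+"], na.rm = TRUE),
                 mean(est$amplitude[est$condition == "CS-"], na.rm = TRUE))
      }
    }
    if ("rar" %in% channels) {
      cyc <- detect_cycles(rec$resp)
      rar <- rar_timeseries(cyc, t_end = rec$t_end)
      est <- estimate_rar_amplitudes(rar, ev, cycles = cyc)
      add_cond("rar", p, est$csp, est$csm)
    }
  }
  list(condition_estimates = cond_est, trial_estimates = trial_est,
       pupil_excluded = pupil_excl)
}

#' Retrodictive-validity calibration report
#'
#' For each measure: group participant exclusion (+/- 3 SD rule, applied to
#' the non-pupil measures), condition means and SDs, the paired t test,
#' Hedges g, and the retained flag at the a priori effect-size threshold
#' (g > 0.5).
#'
#' @param condition_estimates named list of data.frames with `participant`,
#'   `csp`, `csm` (from [analyze_cohort()]).
#' @param threshold effect-size retention threshold.
#' @param sides test sidedness.
#' @param exclude_3sd measures to apply the 3-SD participant exclusion to;
#'   defaults to the non-pupil measures present.
#' @return data.frame with one row per measure: `measure`, `n`,
#'   `n_excluded`, `csp_mean`, `csp_sd`, `csm_mean`, `csm_sd`, `t`, `df`,
#'   `p`, `g`, `retained`.
#' @export
calibration_report <- function(condition_estimates, threshold = 0.5,
                               sides = c("two", "one"),
                               exclude_3sd = NULL) {
  sides <- match.arg(sides)
  if (is.null(exclude_3sd))
    exclude_3sd <- intersect(names(condition_estimates),
                             c("hpr", "scr", "rar"))
  rows <- lapply(names(condition_estimates), function(m) {
    df <- condition_estimates[[m]]
    if (is.null(df) || nrow(df) < 2L) return(NULL)
    keep <- rep(TRUE, nrow(df))
    if (m %in% exclude_3sd && nrow(df) >= 3L)
      keep <- exclude_outliers_3sd(df$csp, df$csm)
    csp <- df$csp[keep]
    csm <- df$csm[keep]
    tt <- paired_ttest(csp, csm, sides = sides)
    data.frame(measure = m, n = tt$n, n_excluded = sum(!keep),
               csp_mean = mean(csp), csp_sd = stats::sd(csp),
               csm_mean = mean(csm), csm_sd = stats::sd(csm),
               t = tt$t, df = tt$df, p = tt$p, g = tt$g,
               retained = tt$g > threshold)
  })
  do.call(rbind, rows)
}
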