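#' Conditioning task design specification
#'
#' Parameters of the two-block differential reward-conditioning session.
#' Defaults reproduce the study protocol: 2 blocks of 24 CS+ and 24 CS−
#' trials (96 trials per phase), 50% reinforcement of CS+, no more than
#' three same-CS trials or three reinforced trials in a row, first CS+ of
#' each block always reinforced, 6-s CS, US at 5 s after CS+ onset, ITI a
#' random integer between 9 and 16 s, swallow cue 2-5 s after CS offset for
#' 2 s.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_condition_per_block CS+ (and CS−) trials per block.
#' @param reinforcement_rate fraction of CS+ trials reinforced in learning.
#' @param max_run_length maximum run of identical CS, and of reinforced
#'   trials, allowed in a row.
#' @param cs_duration CS presentation duration (s).
#' @param soa CS onset to US onset interval (s); must be < `cs_duration`.
#' @param iti_min,iti_max inclusive bounds of the integer ITI draw (s).
#' @param first_csplus_reinforced logical; force the first CS+ of each block
#'   to be reinforced during learning.
#' @param swallow_delay_min,swallow_delay_max bounds of the uniform swallow
#'   cue delay after CS offset (s).
#' @param swallow_duration swallow cue duration (s).
#' @param lead_in,lead_out rest recording before the first CS onset and
#'   after the last trial (s). Zero-phase filters with very low cutoffs
#'   (0.015 Hz) settle over tens of seconds; the rest periods keep those
#'   edge transients away from the trials, as in a real recording that
#'   starts before the task.
#' @return a `design_spec` list.
#' @export
design_spec <- function(n_blocks = 2,
                        trials_per_condition_per_block = 24,
                        reinforcement_rate = 0.5,
                        max_run_length = 3,
                        cs_duration = 6,
                        soa = 5,
                        iti_min = 9, iti_max = 16,
                        first_csplus_reinforced = TRUE,
                        swallow_delay_min = 2, swallow_delay_max = 5,
                        swallow_duration = 2,
                        lead_in = 60, lead_out = 60) {
  spec <- list(n_blocks = as.integer(n_blocks),
               trials_per_condition_per_block =
                 as.integer(trials_per_condition_per_block),
               reinforcement_rate = reinforcement_rate,
               max_run_length = as.integer(max_run_length),
               cs_duration = cs_duration, soa = soa,
               iti_min = as.integer(iti_min), iti_max = as.integer(iti_max),
               first_csplus_reinforced = first_csplus_reinforced,
               swallow_delay_min = swallow_delay_min,
               swallow_delay_max = swallow_delay_max,
               swallow_duration = swallow_duration,
               lead_in = lead_in, lead_out = lead_out)
  stopifnot(spec$trials_per_condition_per_block >= 1L,
            spec$n_blocks >= 1L,
            spec$iti_min <= spec$iti_max,
            spec$reinforcement_rate >= 0, spec$reinforcement_rate <= 1,
            spec$soa < spec$cs_duration,
            spec$max_run_length >= 1L)
  class(spec) <- "design_spec"
  spec
}

# Sample a 0/1 sequence of n_a ones and n_b zeros with no run longer than
# max_run, by rejection; NULL when the budget is exhausted.
sample_no_runs <- function(n_a, n_b, max_run, budget = 10000L) {
  base <- c(rep(1L, n_a), rep(0L, n_b))
  for (i in seq_len(budget)) {
    s <- sample(base)
    r <- rle(s)$lengths
    if (max(r) <= max_run) return(s)
  }
  NULL
}

# Choose reinforced positions among the CS+ slots of one block such that no
# more than max_run reinforced trials occur in a row (across conditions) and,
# optionally, the first CS+ slot is reinforced.
sample_reinforcement <- function(is_csp, n_reinforced, max_run,
                                 first_forced, budget = 10000L) {
  csp_idx <- which(is_csp)
  if (n_reinforced == 0L) return(logical(length(is_csp)))
  for (i in seq_len(budget)) {
    pool <- csp_idx
    chosen <- integer(0)
    if (first_forced) {
      chosen <- csp_idx[1L]
      pool <- setdiff(pool, chosen)
    }
    need <- n_reinforced - length(chosen)
    if (need > length(pool)) return(NULL)
    if (need > 0L) chosen <- c(chosen, sample(pool, need))
    reinf <- seq_along(is_csp) %in% chosen
    runs <- rle(reinf)
    if (max(runs$lengths[runs$values]) <= max_run || !any(reinf)) return(reinf)
  }
  NULL
}

#' Generate a randomized conditioning trial sequence
#'
#' Randomizes trial order per block under the run-length constraint (no more
#' than `max_run_length` same-CS trials, and no more than `max_run_length`
#' reinforced trials, in a row), assigns reinforcement to CS+ trials at the
#' specified rate with the first CS+ of each block reinforced (learning
#' phase), draws integer ITIs, and lays out onset times. In the recall phase
#' no trial is reinforced.
#'
#' @param spec a [design_spec()].
#' @param phase `"learning"` or `"recall"`.
#' @param seed integer seed; the same (spec, phase, seed) reproduces an
#'   identical table.
#' @return a data.frame event table with one row per trial: `trial_index`,
#'   `block`, `condition` (`"CS+"`/`"CS-"`), `reinforced`, `cs_onset`,
#'   `us_onset` (`NA` when not reinforced), `iti_duration`, `swallow_onset`,
#'   all times in seconds from session start.
#' @export
generate_trial_sequence <- function(spec, phase = c("learning", "recall"),
                                    seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "design_spec"))
  n <- spec$trials_per_condition_per_block
  with_seed(seed, {
    rows <- vector("list", spec$n_blocks)
    for (b in seq_len(spec$n_blocks)) {
      cs <- sample_no_runs(n, n, spec$max_run_length)
      if (is.null(cs))
        stop("infeasible design: could not satisfy the same-CS run-length ",
             "constraint within the retry budget")
      is_csp <- cs == 1L
      if (phase == "learning") {
        n_reinf <- round(spec$reinforcement_rate * n)
        reinf <- sample_reinforcement(is_csp, n_reinf, spec$max_run_length,
                                      spec$first_csplus_reinforced)
        if (is.null(reinf))
          stop("infeasible design: could not satisfy the reinforced-run ",
               "constraint within the retry budget")
      } else {
        reinf <- logical(length(is_csp))
      }
      iti <- sample(seq.int(spec$iti_min, spec$iti_max),
                    length(is_csp), replace = TRUE)
      swallow_delay <- stats::runif(length(is_csp), spec$swallow_delay_min,
                                    spec$swallow_delay_max)
      rows[[b]] <- data.frame(
        block = b,
        condition = ifelse(is_csp, "CS+", "CS-"),
        reinforced = reinf,
        iti_duration = iti,
        swallow_delay = swallow_delay,
        stringsAsFactors = FALSE)
    }
    tbl <- do.call(rbind, rows)
    tbl$trial_index <- seq_len(nrow(tbl))
    trial_len <- spec$cs_duration + tbl$iti_duration
    tbl$cs_onset <- spec$lead_in + c(0, cumsum(trial_len))[seq_len(nrow(tbl))]
    tbl$us_onset <- ifelse(tbl$reinforced, tbl$cs_onset + spec$soa, NA_real_)
    tbl$swallow_onset <- tbl$cs_onset + spec$cs_duration + tbl$swallow_delay
    tbl$swallow_delay <- NULL
    tbl[, c("trial_index", "block", "condition", "reinforced", "cs_onset",
            "us_onset", "iti_duration", "swallow_onset")]
  })
}

#' Validate an event table against a design specification
#'
#' Report-only check of the structural constraints a generated sequence must
#' satisfy: condition counts per block, reinforcement counts and the
#' first-CS+ rule (learning), same-CS and reinforced run lengths, CS−
#' never reinforced, US timing, ITI range, and strictly increasing onsets.
#'
#' @param tbl an event table as produced by [generate_trial_sequence()].
#' @param spec the [design_spec()] it should satisfy.
#' @param phase `"learning"` or `"recall"`.
#' @return character vector of violations (with offending row indices);
#'   empty when the table is valid.
#' @export
validate_sequence <- function(tbl, spec, phase = c("learning", "recall")) {
  phase <- match.arg(phase)
  stopifnot(nrow(tbl) > 0L)
  v <- character(0)
  n <- spec$trials_per_condition_per_block
  bad <- which(tbl$condition == "CS-" & tbl$reinforced)
  if (length(bad))
    v <- c(v, paste0("reinforced CS- at rows ", paste(bad, collapse = ",")))
  for (b in unique(tbl$block)) {
    sub <- tbl[tbl$block == b, ]
    if (sum(sub$condition == "CS+") != n)
      v <- c(v, sprintf("block %d: %d CS+ rows, expected %d", b,
                        sum(sub$condition == "CS+"), n))
    if (sum(sub$condition == "CS-") != n)
      v <- c(v, sprintf("block %d: %d CS- rows, expected %d", b,
                        sum(sub$condition == "CS-"), n))
    if (phase == "learning") {
      expect_reinf <- round(spec$reinforcement_rate * n)
      if (sum(sub$reinforced) != expect_reinf)
        v <- c(v, sprintf("block %d: %d reinforced rows, expected %d", b,
                          sum(sub$reinforced), expect_reinf))
      first_csp <- which(sub$condition == "CS+")[1L]
      if (spec$first_csplus_reinforced && expect_reinf > 0 &&
          isFALSE(sub$reinforced[first_csp]))
        v <- c(v, sprintf("block %d: first CS+ (row %d) not reinforced", b,
                          sub$trial_index[first_csp]))
    }
    runs <- rle(sub$condition)
    if (max(runs$lengths) > spec$max_run_length) {
      at <- sub$trial_index[cumsum(runs$lengths)[which.max(runs$lengths)]]
      v <- c(v, sprintf("block %d: same-CS run of %d (ending row %d)", b,
                        max(runs$lengths), at))
    }
    rr <- rle(sub$reinforced)
    if (any(rr$values & rr$lengths > spec$max_run_length))
      v <- c(v, sprintf("block %d: reinforced run exceeds %d", b,
                        spec$max_run_length))
  }
  if (phase == "recall" && any(tbl$reinforced))
    v <- c(v, "recall phase contains reinforced trials")
  us_bad <- which(tbl$reinforced &
                  abs(tbl$us_onset - (tbl$cs_onset + spec$soa)) > 1e-9)
  if (length(us_bad))
    v <- c(v, paste0("us_onset != cs_onset + soa at rows ",
                     paste(us_bad, collapse = ",")))
  if (any(diff(tbl$cs_onset) <= 0))
    v <- c(v, "cs_onset not strictly increasing")
  iti_bad <- which(tbl$iti_duration < spec$iti_min |
                   tbl$iti_duration > spec$iti_max)
  if (length(iti_bad))
    v <- c(v, paste0("iti_duration out of range at rows ",
                     paste(iti_bad, collapse = ",")))
  v
}

# Session end time implied by an event table (end of last trial's ITI
# plus the lead-out rest).
session_end <- function(events, spec) {
  last <- nrow(events)
  events$cs_onset[last] + spec$cs_duration + events$iti_duration[last] +
    spec$lead_out
}
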