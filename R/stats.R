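#' Small-sample-corrected Hedges g for a paired design
#'
#' Converts a paired t statistic into Hedges g:
#' `g = (t / sqrt(n)) * J(n - 1)` with the exact bias-correction factor
#' `J(df) = Gamma(df/2) / (sqrt(df/2) * Gamma((df-1)/2))`, computed on the
#' log scale for numerical stability.
#'
#' @param t paired t statistic (vectorised).
#' @param n number of participants (pairs), >= 2.
#' @return Hedges g (same sign as `t`).
#' @export
hedges_g <- function(t, n) {
  if (any(n < 2)) stop("hedges_g requires n >= 2")
  (t / sqrt(n)) * hedges_correction(n - 1)
}

#' @rdname hedges_g
#' @param df degrees of freedom (`n - 1`).
#' @return `hedges_correction()`: the bias-correction factor J(df) < 1.
#' @export
hedges_correction <- function(df) {
  exp(lgamma(df / 2) - 0.5 * log(df / 2) - lgamma((df - 1) / 2))
}

#' Paired t test with effect size
#'
#' Classical paired t test of CS+ versus CS− per-participant estimates,
#' with Hedges g attached. Two-sided by default: the reported statistics of
#' the study design are two-sided (see the methods vignette).
#'
#' @param csp,csm per-participant condition estimates, equal length >= 2.
#' @param sides `"two"` or `"one"` (one-sided: CS+ > CS−).
#' @return list with `t`, `df`, `n`, `p`, `g`, `mean_diff`, `sides`.
#' @export
paired_ttest <- function(csp, csm, sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(length(csp) == length(csm), length(csp) >= 2L)
  d <- csp - csm
  if (stats::sd(d) == 0) {
    if (all(d == 0))  # identical vectors: a well-defined null result
      return(list(t = 0, df = length(d) - 1L, n = length(d), p = 1,
                  g = 0, mean_diff = 0, sides = sides))
    stop("zero variance of paired differences")
  }
  ht <- stats::t.test(csp, csm, paired = TRUE,
                      alternative = if (sides == "two") "two.sided"
                                    else "greater")
  n <- length(csp)
  list(t = unname(ht$statistic), df = unname(ht$parameter), n = n,
       p = ht$p.value, g = hedges_g(unname(ht$statistic), n),
       mean_diff = mean(d), sides = sides)
}

#' Three-standard-deviation participant exclusion
#'
#' Single-pass rule: a participant is excluded when either condition
#' estimate lies outside mean +/- 3 SD of that condition's group values.
#'
#' @param csp,csm per-participant condition estimates (length >= 3).
#' @return logical keep mask (`FALSE` = excluded).
#' @export
exclude_outliers_3sd <- function(csp, csm) {
  stopifnot(length(csp) == length(csm), length(csp) >= 3L)
  in_band <- function(x) {
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
    x >= mu - 3 * s & x <= mu + 3 * s
  }
  in_band(csp) & in_band(csm) & !is.na(csp) & !is.na(csm)
}

#' Effect-size curve over early-trial subsets
#'
#' For each subset size `n`, averages each participant's first `n` trials
#' per condition (scheme `"standard"`), or the first `n` nonreinforced CS+
#' trials and the first `2n` CS− trials (scheme `"nonreinforced_pairing"`,
#' used when reinforced CS+ trials are discarded, preserving the 1:2 ratio
#' of the design), then runs the paired test. With `skip_first_pair` the
#' first trial of each condition is dropped before counting (the learning
#' variant that probes fast acquisition followed by decay).
#'
#' @param estimates data.frame of trial-level estimates with columns
#'   `participant`, `trial_index`, `condition`, `reinforced`, `amplitude`.
#' @param scheme `"standard"` or `"nonreinforced_pairing"`.
#' @param skip_first_pair drop the first trial per condition first.
#' @param sides test sidedness (see [paired_ttest()]).
#' @return data.frame with one row per subset size: `n_trials`, `t`, `df`,
#'   `n`, `p`, `g`; attribute `scheme`.
#' @export
trial_subset_scan <- function(estimates,
                              scheme = c("standard", "nonreinforced_pairing"),
                              skip_first_pair = FALSE,
                              sides = c("two", "one")) {
  scheme <- match.arg(scheme)
  sides <- match.arg(sides)
  parts <- split(estimates, estimates$participant)
  pick <- function(df) {
    df <- df[order(df$trial_index), ]
    csp <- if (scheme == "nonreinforced_pairing")
      df[df$condition == "CS+" & !df$reinforced, ]
    else df[df$condition == "CS+", ]
    csm <- df[df$condition == "CS-", ]
    if (skip_first_pair) {
      if (nrow(csp) > 1L) csp <- csp[-1L, ]
      if (nrow(csm) > 1L) csm <- csm[-1L, ]
    }
    list(csp = csp$amplitude, csm = csm$amplitude)
  }
  picked <- lapply(parts, pick)
  n_max <- min(vapply(picked, function(z) {
    if (scheme == "nonreinforced_pairing")
      min(length(z$csp), floor(length(z$csm) / 2))
    else min(length(z$csp), length(z$csm))
  }, 0))
  if (n_max < 1L) stop("no trials available for the scan")
  rows <- lapply(seq_len(n_max), function(n) {
    csm_n <- if (scheme == "nonreinforced_pairing") 2L * n else n
    csp <- vapply(picked, function(z) mean(z$csp[seq_len(n)], na.rm = TRUE),
                  0)
    csm <- vapply(picked, function(z) mean(z$csm[seq_len(csm_n)],
                                           na.rm = TRUE), 0)
    tt <- paired_ttest(csp, csm, sides = sides)
    data.frame(n_trials = n, t = tt$t, df = tt$df, n = tt$n, p = tt$p,
               g = tt$g)
  })
  out <- do.call(rbind, rows)
  attr(out, "scheme") <- scheme
  out
}

#' Separate paired tests for the first and second half of a phase
#'
#' Splits each participant's retained trials into the first and second
#' half of the phase (by trial order), averages within condition per half,
#' and runs the paired test per half. Used for measures unavailable on a
#' usable trial-by-trial basis.
#'
#' @inheritParams trial_subset_scan
#' @return list of two [paired_ttest()] results (`first`, `second`).
#' @export
halves_analysis <- function(estimates, sides = c("two", "one")) {
  sides <- match.arg(sides)
  parts <- split(estimates, estimates$participant)
  half_means <- function(df) {
    df <- df[order(df$trial_index), ]
    cut <- stats::median(df$trial_index)
    lapply(list(first = df[df$trial_index <= cut, ],
                second = df[df$trial_index > cut, ]),
           function(h) c(csp = mean(h$amplitude[h$condition == "CS+"],
                                    na.rm = TRUE),
                         csm = mean(h$amplitude[h$condition == "CS-"],
                                    na.rm = TRUE)))
  }
  hm <- lapply(parts, half_means)
  lapply(c(first = "first", second = "second"), function(h) {
    csp <- vapply(hm, function(z) z[[h]][["csp"]], 0)
    csm <- vapply(hm, function(z) z[[h]][["csm"]], 0)
    paired_ttest(csp, csm, sides = sides)
  })
}

#' Holm-Bonferroni step-down correction
#'
#' Standard step-down Holm procedure (via [stats::p.adjust()]) with the
#' rejection set at level `alpha`.
#'
#' @param p numeric p-values.
#' @param alpha family-wise error level.
#' @return list with `adjusted` p-values and logical `reject`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  adj <- stats::p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}
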