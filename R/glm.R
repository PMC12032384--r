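#' Build a convolution design matrix
#'
#' Constructs predicted time courses by convolving unit impulses at CS
#' onsets with a response kernel, one regressor per condition
#' (condition-wise mode) or per retained trial (trial-wise mode). Kernels
#' with negative-time support place mass before the event onset; this is
#' intentional (the zero-phase filtering used in preprocessing makes the
#' analysis acausal).
#'
#' @param events event table (see [generate_trial_sequence()]).
#' @param rf a `pav_rf` kernel.
#' @param rate sampling rate of the modelled series (Hz).
#' @param n_samples number of samples of the modelled series.
#' @param mode `"condition"` or `"trial"`.
#' @param retained integer trial indices entering the named regressors;
#'   defaults to all trials.
#' @param nuisance optional named list of extra onset vectors (s), each
#'   added as one condition-style nuisance regressor (e.g. reinforced CS+
#'   onsets, US onsets).
#' @param intercept include an intercept column.
#' @param normalise normalise the kernel to unit peak absolute value so
#'   betas are in channel units (default TRUE).
#' @return list with `X` (matrix, named columns), `rate`, `intercept`,
#'   `condition_number`, and `names` of the non-nuisance regressors.
#' @export
build_design <- function(events, rf, rate, n_samples,
                         mode = c("condition", "trial"),
                         retained = NULL, nuisance = NULL,
                         intercept = TRUE, normalise = TRUE) {
  mode <- match.arg(mode)
  if (is.null(retained)) retained <- events$trial_index
  ev <- events[events$trial_index %in% retained, ]
  stopifnot(nrow(ev) > 0L)

  kt <- seq(rf$support[1], rf$support[2], by = 1 / rate)
  kv <- rf_evaluate(rf, kt, normalise = normalise)

  col_from_onsets <- function(onsets) {
    x <- numeric(n_samples)
    for (o in onsets) {
      idx <- round((o + kt) * rate) + 1L
      keep <- idx >= 1L & idx <= n_samples
      x[idx[keep]] <- x[idx[keep]] + kv[keep]
    }
    x
  }

  if (mode == "condition") {
    groups <- split(ev$cs_onset, ev$condition)
  } else {
    groups <- as.list(ev$cs_onset)
    names(groups) <- paste0("trial_", ev$trial_index)
  }
  task_names <- names(groups)
  if (!is.null(nuisance)) groups <- c(groups, nuisance)
  X <- vapply(groups, col_from_onsets, numeric(n_samples))
  if (intercept) X <- cbind(X, `(intercept)` = 1)
  sv <- svd(scale(X, center = FALSE,
                  scale = apply(X, 2, function(z) max(abs(z), 1e-12))))$d
  list(X = X, rate = rate, intercept = intercept,
       condition_number = max(sv) / max(min(sv), .Machine$double.xmin),
       names = task_names)
}

#' Invert a general linear convolution model
#'
#' Ordinary least squares estimation of regressor amplitudes. Rows flagged
#' invalid are dropped listwise from both the data and the design. A
#' rank-deficient design is an error (never a silent pseudo-inverse).
#'
#' @param y numeric data vector, or a [pav_ts()] (whose `valid` mask is
#'   honoured).
#' @param design design list from [build_design()], or a plain matrix.
#' @param valid optional logical mask overriding `y$valid`.
#' @return list with `betas` (named), `residual_variance`, `r_squared`,
#'   `dof`, and `fitted`.
#' @export
glm_invert <- function(y, design, valid = NULL) {
  X <- if (is.list(design) && !is.data.frame(design)) design$X else design
  if (inherits(y, "pav_ts")) {
    if (is.null(valid)) valid <- y$valid
    y <- y$values
  }
  stopifnot(length(y) == nrow(X))
  if (is.null(valid)) valid <- rep(TRUE, length(y))
  keep <- valid & !is.na(y)
  yk <- y[keep]
  Xk <- X[keep, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    sv <- svd(Xk)$d
    stop(sprintf(
      "rank-deficient design (rank %d of %d columns, condition number %.3g)",
      qrX$rank, ncol(Xk), max(sv) / max(min(sv), .Machine$double.xmin)))
  }
  betas <- qr.coef(qrX, yk)
  fitted <- drop(Xk %*% betas)
  res <- yk - fitted
  dof <- length(yk) - ncol(Xk)
  tss <- sum((yk - mean(yk))^2)
  full_fit <- drop(X %*% betas)
  list(betas = betas,
       residual_variance = if (dof > 0) sum(res^2) / dof else NA_real_,
       r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
       dof = dof, fitted = full_fit)
}

#' Single-kernel trial amplitude from a segment
#'
#' Least-squares projection of one trial segment onto a kernel sampled on
#' the same grid: `amp = <segment, k> / <k, k>`. Missing samples are
#' dropped listwise; an all-missing segment yields `NA`.
#'
#' @param segment numeric vector (may contain `NA`).
#' @param kernel numeric vector, same length.
#' @return scalar amplitude estimate, `NA` when no valid samples.
#' @export
trialwise_amplitude <- function(segment, kernel) {
  stopifnot(length(segment) == length(kernel))
  v <- !is.na(segment) & !is.na(kernel)
  if (!any(v)) return(NA_real_)
  denom <- sum(kernel[v]^2)
  if (denom == 0) return(NA_real_)
  sum(segment[v] * kernel[v]) / denom
}
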