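#' Response-function (LTI kernel) constructors
#'
#' Each psychophysiological channel is modelled as a linear time-invariant
#' system whose impulse response ("response function", RF) maps a neural
#' input at CS onset to the observed peripheral time course. Four families
#' are supported: gamma probability density, Gaussian, mixture of two
#' gammas, and empirical (stored waveform).
#'
#' For gamma kernels the published parameter tables annotate the
#' time-constant parameter as a rate (1/s), but a single convention cannot
#' place every kernel's peak inside its extraction window; each kernel
#' therefore carries an explicit `convention` flag (`"scale"`: the
#' parameter is the gamma scale in seconds; `"rate"`: the scale is its
#' reciprocal), chosen so that the kernel peak falls inside the declared
#' support. See the methods vignette.
#'
#' @param kappa gamma shape (> 0).
#' @param theta gamma time-constant parameter (> 0); interpreted per
#'   `convention`.
#' @param c output scale in channel units (may be negative).
#' @param t0 temporal offset of the kernel onset relative to the event (s).
#' @param convention `"scale"` or `"rate"` reading of `theta`.
#' @param support numeric length-2: time range (s, event-relative) on which
#'   the kernel is considered nonzero.
#' @param window extraction-window length (s) used when scoring trials with
#'   this kernel (`NA` for condition-wise kernels).
#' @param name optional kernel name.
#' @return an object of class `pav_rf`.
#' @export
rf_gamma <- function(kappa, theta, c = 1, t0 = 0,
                     convention = c("scale", "rate"),
                     support = NULL, window = NA_real_, name = NULL) {
  convention <- match.arg(convention)
  stopifnot(kappa > 0, theta > 0, is.finite(c))
  scale <- if (convention == "scale") theta else 1 / theta
  if (is.null(support)) {
    peak <- t0 + max(kappa - 1, 0) * scale
    support <- c(t0, peak + 6 * sqrt(kappa) * scale)
  }
  structure(list(family = "gamma",
                 params = list(kappa = kappa, theta = theta, c = c, t0 = t0),
                 convention = convention, support = support,
                 window = window, name = name),
            class = "pav_rf")
}

#' @rdname rf_gamma
#' @param mu Gaussian peak time (s).
#' @param sigma Gaussian width (s, > 0).
#' @export
rf_gaussian <- function(mu, sigma, c = 1, support = NULL,
                        window = NA_real_, name = NULL) {
  stopifnot(sigma > 0, is.finite(c))
  if (is.null(support)) support <- c(mu - 5 * sigma, mu + 5 * sigma)
  structure(list(family = "gaussian",
                 params = list(mu = mu, sigma = sigma, c = c),
                 convention = NA_character_, support = support,
                 window = window, name = name),
            class = "pav_rf")
}

#' @rdname rf_gamma
#' @param o1,o2 onset parameters (s) of the two gamma components.
#' @param d1,d2 dispersion parameters (s) of the two components.
#' @param r component ratio; the kernel is
#'   `c * (g1(t - t0) - r * g2(t - t0))` with `gk` a gamma pdf of shape
#'   `ok/dk` and scale `dk` (a documented, swappable convention — the
#'   published table does not define the combination rule).
#' @export
rf_two_gamma <- function(c, o1, o2, d1, d2, r, t0 = 0,
                         support = NULL, window = NA_real_, name = NULL) {
  stopifnot(d1 > 0, d2 > 0, is.finite(c), is.finite(r))
  if (is.null(support)) support <- c(t0, t0 + o1 + 10 * d1)
  structure(list(family = "two_gamma",
                 params = list(c = c, o1 = o1, o2 = o2, d1 = d1, d2 = d2,
                               r = r, t0 = t0),
                 convention = NA_character_, support = support,
                 window = window, name = name),
            class = "pav_rf")
}

#' @rdname rf_gamma
#' @param grid uniform, increasing sample times (s) of a stored waveform.
#' @param values kernel amplitudes at `grid`.
#' @param provenance free-text provenance label of the stored waveform.
#' @export
rf_empirical <- function(grid, values, provenance = "",
                         window = NA_real_, name = NULL) {
  stopifnot(length(grid) == length(values), length(grid) >= 2L,
            all(diff(grid) > 0))
  structure(list(family = "empirical",
                 params = list(grid = grid, values = values,
                               provenance = provenance),
                 convention = NA_character_,
                 support = range(grid), window = window, name = name),
            class = "pav_rf")
}

#' @export
print.pav_rf <- function(x, ...) {
  cat(sprintf("<pav_rf> %s (%s), support [%.2f, %.2f] s%s\n",
              if (is.null(x$name)) "unnamed" else x$name, x$family,
              x$support[1], x$support[2],
              if (is.na(x$window)) "" else sprintf(", window %g s", x$window)))
  invisible(x)
}

#' Evaluate a response function on a time grid
#'
#' Times are event-relative (0 = CS onset). Gamma-family kernels are zero
#' before their onset `t0` by definition; empirical kernels are linearly
#' interpolated and zero outside their stored grid.
#'
#' @param rf a `pav_rf` kernel.
#' @param t numeric vector of times (s).
#' @param normalise logical; rescale so the maximum absolute value over the
#'   kernel support is 1 (sign preserved). Used when building regressors so
#'   that estimated amplitudes are in channel units.
#' @return numeric vector of kernel values at `t`.
#' @export
rf_evaluate <- function(rf, t, normalise = FALSE) {
  stopifnot(inherits(rf, "pav_rf"))
  p <- rf$params
  if (any(!vapply(p[vapply(p, is.numeric, TRUE)],
                  function(z) all(is.finite(z)), TRUE)))
    stop("non-finite response function parameters")
  v <- switch(rf$family,
    gamma = {
      scale <- if (rf$convention == "scale") p$theta else 1 / p$theta
      p$c * stats::dgamma(t - p$t0, shape = p$kappa, scale = scale)
    },
    gaussian = p$c * exp(-(t - p$mu)^2 / (2 * p$sigma^2)),
    two_gamma = {
      x <- t - p$t0
      g1 <- stats::dgamma(x, shape = p$o1 / p$d1, scale = p$d1)
      g2 <- stats::dgamma(x, shape = p$o2 / p$d2, scale = p$d2)
      p$c * (g1 - p$r * g2)
    },
    empirical = stats::approx(p$grid, p$values, xout = t, rule = 1)$y,
    stop("unknown response function family: ", rf$family))
  v[is.na(v)] <- 0
  if (normalise) {
    m <- rf_peak_value(rf)
    if (m == 0) stop("cannot normalise an all-zero kernel")
    v <- v / abs(m)
  }
  v
}

# Dense grid over the kernel support.
rf_grid <- function(rf, rate = 100) {
  seq(rf$support[1], rf$support[2], by = 1 / rate)
}

#' Kernel peak location and value
#'
#' The peak is the maximum-absolute-value point on a dense grid over the
#' declared support.
#'
#' @param rf a `pav_rf` kernel.
#' @param rate grid density in Hz.
#' @return `rf_peak_time()`: time (s) of the peak; `rf_peak_value()`: signed
#'   kernel value at the peak.
#' @export
rf_peak_time <- function(rf, rate = 1000) {
  g <- rf_grid(rf, rate)
  g[which.max(abs(rf_evaluate(rf, g)))]
}

#' @rdname rf_peak_time
#' @export
rf_peak_value <- function(rf, rate = 1000) {
  v <- rf_evaluate(rf, rf_grid(rf, rate))
  v[which.max(abs(v))]
}

# Synthetic stand-in waveforms for the two empirical registry kernels whose
# real waveforms can only be regenerated from the original recordings.
standin_rf4 <- function() {
  rate <- 100
  t <- seq(0, 2.88, by = 1 / rate)
  proto <- rf_two_gamma(c = 12.998, o1 = 1.355, o2 = 0.750, d1 = 0.059,
                        d2 = 0.178, r = 2.715, t0 = 0.439)
  w <- butter_bandpass(rf_evaluate(proto, t), rate, low = 2, order = 2)
  rf_empirical(t, w,
    provenance = paste("synthetic stand-in: 2-Hz bidirectional low-pass of a",
                       "model mean-difference waveform truncated at 2.88 s"),
    window = 3, name = "psr_rf4")
}

standin_rf6 <- function() {
  rate <- 100
  t <- seq(0, 3.5, by = 1 / rate)
  w <- 0.033 * stats::dgamma(t - 0.506, shape = 30.781, scale = 0.042)
  rf_empirical(t, w,
    provenance = paste("synthetic stand-in for the stored Gaussian-process",
                       "mean-difference waveform"),
    window = 3.5, name = "psr_rf6")
}

#' Catalogue of named response kernels
#'
#' Returns the channel kernels with their published parameters:
#' `hprf_rew` (heart period, gamma), `rarf_rew` (respiration amplitude,
#' gamma), and the six pupil kernels `psr_rf1` ... `psr_rf6`. Pupil kernels
#' carry their extraction windows: 15 s (RF1), 3.5 s (RF2, RF6), 3 s
#' (RF3-RF5). `psr_rf4` and `psr_rf6` are shipped as synthetic stand-in
#' empirical waveforms (their real waveforms require the original
#' recordings); see their `provenance` fields.
#'
#' @param name optional kernel name; when given, that single kernel is
#'   returned (error listing valid names otherwise).
#' @return a named list of `pav_rf` kernels, or one kernel when `name` is
#'   given.
#' @export
rf_registry <- function(name = NULL) {
  reg <- list(
    hprf_rew = rf_gamma(kappa = 1.72, theta = 0.14, c = 60.10, t0 = -17.61,
                        convention = "rate", support = c(-18, 30),
                        window = 25, name = "hprf_rew"),
    rarf_rew = rf_gamma(kappa = 40.87, theta = 0.29, c = 0.14, t0 = 2.09,
                        convention = "scale", support = c(0, 30),
                        window = 30, name = "rarf_rew"),
    psr_rf1 = rf_gamma(kappa = 3.534, theta = 1.946, c = -1.183, t0 = 1.712,
                       convention = "scale", support = c(0, 15),
                       window = 15, name = "psr_rf1"),
    psr_rf2 = rf_gamma(kappa = 30.781, theta = 0.042, c = 0.033, t0 = 0.506,
                       convention = "scale", support = c(0, 3.5),
                       window = 3.5, name = "psr_rf2"),
    psr_rf3 = rf_gaussian(mu = 1.784, sigma = 0.246, c = 0.035,
                          support = c(0, 3), window = 3, name = "psr_rf3"),
    psr_rf4 = standin_rf4(),
    psr_rf5 = rf_two_gamma(c = 12.998, o1 = 1.355, o2 = 0.750, d1 = 0.059,
                           d2 = 0.178, r = 2.715, t0 = 0.439,
                           support = c(0, 3), window = 3, name = "psr_rf5"),
    psr_rf6 = standin_rf6()
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stop("unknown kernel '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Fit a parametric response function to a waveform
#'
#' Least-squares fit of a gamma or Gaussian kernel to an empirical waveform
#' (typically the grand-mean CS+ minus CS− difference). Optimisation is
#' Nelder-Mead with optional multistart around the initial values, followed
#' by a polishing restart from the best candidate.
#'
#' @param times,values the waveform (times in s, event-relative).
#' @param family `"gamma"` or `"gaussian"`.
#' @param init named list of initial parameters (gamma: `kappa`, `theta`,
#'   `c`, `t0`; gaussian: `mu`, `sigma`, `c`).
#' @param convention gamma `theta` convention (see [rf_gamma()]).
#' @param n_starts number of jittered restarts (>= 1); deterministic given
#'   `seed`.
#' @param seed integer seed for the restart jitter.
#' @return list with `rf` (fitted `pav_rf`), `params`, `sse`, `r_squared`,
#'   and `converged`.
#' @export
rf_fit <- function(times, values, family = c("gamma", "gaussian"),
                   init, convention = c("scale", "rate"),
                   n_starts = 1L, seed = 1L) {
  family <- match.arg(family)
  convention <- match.arg(convention)
  stopifnot(length(times) == length(values), length(times) >= 8L)
  par_names <- if (family == "gamma") c("kappa", "theta", "c", "t0")
               else c("mu", "sigma", "c")
  stopifnot(all(par_names %in% names(init)))
  p0 <- unlist(init[par_names])

  make_rf <- function(par) {
    par <- as.list(par)
    if (family == "gamma")
      rf_gamma(par$kappa, par$theta, par$c, par$t0, convention = convention,
               support = range(times))
    else
      rf_gaussian(par$mu, par$sigma, par$c, support = range(times))
  }
  obj <- function(par) {
    names(par) <- par_names
    if (family == "gamma" && (par[["kappa"]] <= 0 || par[["theta"]] <= 0))
      return(1e12)
    if (family == "gaussian" && par[["sigma"]] <= 0) return(1e12)
    sum((values - rf_evaluate(make_rf(par), times))^2)
  }

  starts <- list(p0)
  if (n_starts > 1L)
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts - 1L),
      function(i) p0 * stats::runif(length(p0), 0.8, 1.2))))
  fits <- lapply(starts, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 20000, reltol = 1e-14))
  params <- as.list(best$par)
  names(params) <- par_names
  sse <- best$value
  tss <- sum((values - mean(values))^2)
  list(rf = make_rf(best$par), params = params, sse = sse,
       r_squared = if (tss > 0) 1 - sse / tss else NA_real_,
       converged = best$convergence == 0)
}
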