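#' Synthetic cohort specification
#'
#' Parameters of the forward simulator. The statistical core draws one
#' standardized CS+/CS− amplitude difference per participant
#' (`d_i ~ Normal(delta, between_sd^2)`) and per-trial response amplitudes
#' `base + [CS+] * d_i + Normal(0, trial_sd^2)` in standardized units,
#' which each channel converts to its own units via `scale`. Channel
#' waveforms are then built by the channel simulators with autocorrelated
#' (pink) or white measurement noise, pupil blinks/gaze excursions, and
#' optional skin-conductance artifact spikes.
#'
#' Defaults emulate the study conditions: 34 participants (the a priori
#' sample size), a group effect around 0.5-0.6 after trial averaging,
#' resting heart period 0.9 s, skin conductance level 5 uS, pupil 4 mm,
#' breathing at 0.25 Hz.
#'
#' @param n_participants cohort size (>= 2).
#' @param delta group-mean standardized CS+ minus CS− amplitude difference.
#' @param between_sd between-participant SD of the difference.
#' @param trial_sd trial-level SD of amplitudes (standardized units).
#' @param channels per-channel list: `base` (CS− mean amplitude, channel
#'   units), `scale` (channel units per standardized unit), `us_amp`
#'   (US-locked response amplitude, channel units), `noise`
#'   (`list(spectrum, sd)`), `rate` (simulation rate, Hz).
#' @param baseline resting levels: `heart_period_s`, `scl_uS`, `pupil_mm`,
#'   `resp_amp`, `resp_freq_Hz`.
#' @param blink_rate_per_min,blink_duration pupil blink model.
#' @param gaze_excursion_per_min rate of >5 degree gaze excursions.
#' @param scr_spike_per_min rate of fast artifact spikes on the SCR
#'   channel (0 disables).
#' @param seed integer master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 34, delta = 0.6, between_sd = 1,
                        trial_sd = 2,
                        channels = list(
                          heart = list(base = 10, scale = 15, us_amp = 8,
                                       noise = list(spectrum = "pink", sd = 5),
                                       rate = 100),
                          scr = list(base = 0.3, scale = 0.3, us_amp = 0.5,
                                     noise = list(spectrum = "pink",
                                                  sd = 0.02),
                                     rate = 100),
                          pupil = list(base = 0.1, scale = 0.1, us_amp = 0,
                                       noise = list(spectrum = "pink",
                                                    sd = 0.05),
                                       rate = 100),
                          resp = list(base = 0.1, scale = 0.1, us_amp = 0.05,
                                      noise = list(spectrum = "white",
                                                   sd = 0.03),
                                      rate = 20)),
                        baseline = list(heart_period_s = 0.9, scl_uS = 5,
                                        pupil_mm = 4, resp_amp = 1,
                                        resp_freq_Hz = 0.25),
                        blink_rate_per_min = 15,
                        blink_duration = c(0.1, 0.4),
                        gaze_excursion_per_min = 1,
                        scr_spike_per_min = 0,
                        seed = 1L) {
  stopifnot(n_participants >= 2, between_sd >= 0, trial_sd >= 0,
            baseline$heart_period_s >= 0.4, baseline$heart_period_s <= 1.2)
  structure(list(n_participants = as.integer(n_participants), delta = delta,
                 between_sd = between_sd, trial_sd = trial_sd,
                 channels = channels, baseline = baseline,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_duration = blink_duration,
                 gaze_excursion_per_min = gaze_excursion_per_min,
                 scr_spike_per_min = scr_spike_per_min,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

make_noise <- function(n, noise) {
  if (noise$sd == 0) return(numeric(n))
  if (identical(noise$spectrum, "pink")) pink_noise(n, noise$sd)
  else stats::rnorm(n, sd = noise$sd)
}

# Sum of amp[i] * unit-peak kernel at each onset, evaluated on a grid.
inject_responses <- function(t, onsets, amps, rf) {
  y <- numeric(length(t))
  if (!length(onsets)) return(y)
  kt <- seq(rf$support[1], rf$support[2], by = t[2] - t[1])
  kv <- rf_evaluate(rf, kt, normalise = TRUE)
  rate <- 1 / (t[2] - t[1])
  for (i in seq_along(onsets)) {
    idx <- round((onsets[i] - t[1] + kt) * rate) + 1L
    keep <- idx >= 1L & idx <= length(t)
    y[idx[keep]] <- y[idx[keep]] + amps[i] * kv[keep]
  }
  y
}

#' Simulate heart beats by integral pulse frequency modulation
#'
#' Builds the instantaneous heart period
#' `h(t) = baseline + sum(amp * rf(t - cs_onset)) / 1000 + noise` and
#' generates beats by integrating `1/h(t)` until the accumulated phase
#' reaches 1 (the integral-pulse-frequency-modulation convention, which
#' makes the inter-beat-interval analysis consistent by construction). The
#' first beat is at time 0.
#'
#' @param events event table.
#' @param rf heart-period kernel (unit-peak normalised internally).
#' @param trial_amps per-trial CR amplitudes (ms), one per event row.
#' @param baseline_s resting heart period (s).
#' @param noise `list(spectrum, sd)` with `sd` in ms.
#' @param t_end session end (s).
#' @param us_amp US-locked response amplitude (ms) added at `us_onset`.
#' @param rate grid rate for the period process (Hz).
#' @return numeric vector of beat timestamps (s).
#' @export
simulate_heart_beats <- function(events, rf, trial_amps, baseline_s,
                                 noise = list(spectrum = "white", sd = 0),
                                 t_end, us_amp = 0, rate = 100) {
  t <- seq(0, t_end, by = 1 / rate)
  h <- baseline_s + inject_responses(t, events$cs_onset, trial_amps, rf) / 1000
  if (us_amp != 0 && any(events$reinforced))
    h <- h + inject_responses(t, events$us_onset[events$reinforced],
                              rep(us_amp, sum(events$reinforced)), rf) / 1000
  h <- h + make_noise(length(t), noise) / 1000
  if (any(h <= 0.2))
    stop("unphysiological specification: instantaneous heart period <= 0.2 s")
  phase <- c(0, cumsum((1 / h[-length(h)] + 1 / h[-1L]) / 2)) / rate
  n_beats <- floor(phase[length(phase)])
  if (n_beats < 1L) stop("session too short to contain a beat")
  beats <- stats::approx(phase, t, xout = seq_len(n_beats))$y
  c(0, beats)
}

#' Simulate a pupil diameter recording with blinks and gaze
#'
#' `pupil(t) = baseline + sum(amp * rf(t - cs_onset)) + noise`; blinks are
#' inserted as missing gaps at a Poisson rate, and gaze wanders near the
#' screen centre with occasional excursions beyond 5 degrees (to exercise
#' the gaze filter).
#'
#' @param events event table.
#' @param rf pupil kernel.
#' @param trial_amps per-trial amplitudes (mm).
#' @param baseline_mm resting diameter (mm).
#' @param noise `list(spectrum, sd)`, sd in mm.
#' @param t_end session end (s).
#' @param blink_rate_per_min,blink_duration blink model (0 disables).
#' @param gaze_excursion_per_min excursion rate (0 disables).
#' @param rate sampling rate (Hz).
#' @return list with `pupil` ([pav_ts()], `NA` and `valid = FALSE` during
#'   blinks), `gaze_x`, `gaze_y` (degrees).
#' @export
simulate_pupil <- function(events, rf, trial_amps, baseline_mm,
                           noise = list(spectrum = "white", sd = 0), t_end,
                           blink_rate_per_min = 0,
                           blink_duration = c(0.1, 0.4),
                           gaze_excursion_per_min = 0, rate = 100) {
  t <- seq(0, t_end, by = 1 / rate)
  x <- baseline_mm + inject_responses(t, events$cs_onset, trial_amps, rf) +
    make_noise(length(t), noise)
  valid <- rep(TRUE, length(t))
  n_blinks <- stats::rpois(1, blink_rate_per_min * t_end / 60)
  if (n_blinks > 0L) {
    starts <- stats::runif(n_blinks, 0, t_end)
    durs <- stats::runif(n_blinks, blink_duration[1], blink_duration[2])
    for (i in seq_len(n_blinks))
      valid[t >= starts[i] & t <= starts[i] + durs[i]] <- FALSE
  }
  x[!valid] <- NA
  gx <- butter_bandpass(stats::rnorm(length(t), sd = 3), rate, low = 2,
                        order = 2)
  gy <- butter_bandpass(stats::rnorm(length(t), sd = 3), rate, low = 2,
                        order = 2)
  n_exc <- stats::rpois(1, gaze_excursion_per_min * t_end / 60)
  if (n_exc > 0L) {
    starts <- stats::runif(n_exc, 0, t_end)
    for (i in seq_len(n_exc)) {
      idx <- t >= starts[i] & t <= starts[i] + 1
      gx[idx] <- gx[idx] + 7
    }
  }
  list(pupil = pav_ts(x, rate = rate, units = "mm", valid = valid),
       gaze_x = gx, gaze_y = gy)
}

#' Simulate a skin conductance recording
#'
#' Tonic level plus CS-locked and US/omission-locked phasic responses
#' built from the canonical SCR kernel, plus noise and optional fast
#' artifact spikes (slope > 10 uS/s, to exercise the slope filter). Values
#' are kept within the physiological range 0.05-100 uS.
#'
#' @param events event table.
#' @param trial_amps_cs,trial_amps_us per-trial CS and US/omission response
#'   amplitudes (uS), one per event row.
#' @param baseline_uS tonic skin conductance level (uS).
#' @param noise `list(spectrum, sd)` (uS).
#' @param t_end session end (s).
#' @param soa CS onset to US interval (s).
#' @param kernel SCR kernel (default [scr_kernel()]).
#' @param spike_rate_per_min artifact spike rate (0 disables).
#' @param spike_magnitude spike height (uS).
#' @param rate sampling rate (Hz).
#' @return a [pav_ts()] in uS.
#' @export
simulate_scr <- function(events, trial_amps_cs, trial_amps_us, baseline_uS,
                         noise = list(spectrum = "white", sd = 0), t_end,
                         soa = 5, kernel = scr_kernel(),
                         spike_rate_per_min = 0, spike_magnitude = 3,
                         rate = 100) {
  t <- seq(0, t_end, by = 1 / rate)
  x <- baseline_uS +
    inject_responses(t, events$cs_onset, trial_amps_cs, kernel) +
    inject_responses(t, events$cs_onset + soa, trial_amps_us, kernel) +
    make_noise(length(t), noise)
  n_spk <- stats::rpois(1, spike_rate_per_min * t_end / 60)
  if (n_spk > 0L) {
    starts <- stats::runif(n_spk, 0, t_end - 0.3)
    for (s in starts) {
      idx <- which(t >= s & t <= s + 0.2)
      tri <- 1 - abs(seq(-1, 1, length.out = length(idx)))
      x[idx] <- x[idx] + spike_magnitude * tri
    }
  }
  pav_ts(pmin(pmax(x, 0.05), 100), rate = rate, units = "uS")
}

#' Simulate a respiration belt recording
#'
#' A carrier oscillation at the breathing frequency whose peak-to-trough
#' cycle amplitude is `base_amp + sum(amp * rf(t - cs_onset)) + noise`
#' (the carrier is scaled by half that envelope, since a sinusoid's
#' peak-to-trough excursion is twice its amplitude). Amplitudes are thus
#' in the same units the respiration-amplitude analysis estimates.
#'
#' @param events event table.
#' @param rf respiration-amplitude kernel.
#' @param trial_amps per-trial envelope amplitudes (a.u.).
#' @param base_amp resting envelope (a.u.).
#' @param base_freq breathing frequency (Hz).
#' @param noise `list(spectrum, sd)` on the envelope.
#' @param t_end session end (s).
#' @param us_amp US-locked envelope response (a.u.).
#' @param rate sampling rate (Hz).
#' @return a [pav_ts()]; attribute `envelope` holds the injected envelope.
#' @export
simulate_respiration <- function(events, rf, trial_amps, base_amp, base_freq,
                                 noise = list(spectrum = "white", sd = 0),
                                 t_end, us_amp = 0, rate = 20) {
  t <- seq(0, t_end, by = 1 / rate)
  env <- base_amp + inject_responses(t, events$cs_onset, trial_amps, rf)
  if (us_amp != 0 && any(events$reinforced))
    env <- env + inject_responses(t, events$us_onset[events$reinforced],
                                  rep(us_amp, sum(events$reinforced)), rf)
  if (noise$sd > 0)
    env <- env + butter_bandpass(make_noise(length(t), noise), rate,
                                 low = 0.05, order = 2)
  env <- pmax(env, 0.05)
  out <- pav_ts(env / 2 * sin(2 * pi * base_freq * t), rate = rate,
                units = "a.u.")
  attr(out, "envelope") <- env
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws per-participant effects and per-trial amplitudes, then builds all
#' four channel recordings per participant. Ground-truth per-trial
#' amplitudes are stored per channel so every downstream stage can be
#' checked against the injected values. Deterministic given
#' `spec$seed`.
#'
#' @param design a [design_spec()].
#' @param spec a [cohort_spec()].
#' @param phase `"learning"` or `"recall"`.
#' @return list of participant recordings; each has `participant`,
#'   `events`, `d` (the participant's standardized effect), `beats`,
#'   `scr`, `pupil` (list with gaze), `resp`, `cycles_truth` and `truth`
#'   (per-trial injected amplitudes per channel).
#' @export
simulate_cohort <- function(design = design_spec(), spec = cohort_spec(),
                            phase = c("learning", "recall")) {
  phase <- match.arg(phase)
  subseeds <- with_seed(spec$seed,
                        sample.int(.Machine$integer.max - 1L,
                                   spec$n_participants + 1L))
  hprf <- rf_registry("hprf_rew")
  psrf <- rf_registry("psr_rf5")
  rarf <- rf_registry("rarf_rew")
  lapply(seq_len(spec$n_participants), function(p) {
    with_seed(subseeds[p], {
      events <- generate_trial_sequence(design, phase,
                                        seed = subseeds[spec$n_participants
                                                        + 1L] %% 100000L + p)
      t_end <- session_end(events, design)
      d_i <- stats::rnorm(1, spec$delta, spec$between_sd)
      n_tr <- nrow(events)
      csp <- events$condition == "CS+"
      std_amp <- function() (csp * d_i) + stats::rnorm(n_tr, 0, spec$trial_sd)
      ch <- spec$channels
      truth <- data.frame(
        trial_index = events$trial_index, condition = events$condition,
        reinforced = events$reinforced,
        heart = ch$heart$base + ch$heart$scale * std_amp(),
        scr = pmax(ch$scr$base + ch$scr$scale * std_amp(), 0),
        pupil = ch$pupil$base + ch$pupil$scale * std_amp(),
        resp = ch$resp$base + ch$resp$scale * std_amp())
      scr_us <- ifelse(events$reinforced, ch$scr$us_amp, 0.2 * ch$scr$us_amp)
      beats <- simulate_heart_beats(events, hprf, truth$heart,
                                    spec$baseline$heart_period_s,
                                    ch$heart$noise, t_end,
                                    us_amp = ch$heart$us_amp,
                                    rate = ch$heart$rate)
      scr <- simulate_scr(events, truth$scr, scr_us, spec$baseline$scl_uS,
                          ch$scr$noise, t_end, soa = design$soa,
                          spike_rate_per_min = spec$scr_spike_per_min,
                          rate = ch$scr$rate)
      pupil <- simulate_pupil(events, psrf, truth$pupil,
                              spec$baseline$pupil_mm, ch$pupil$noise, t_end,
                              blink_rate_per_min = spec$blink_rate_per_min,
                              blink_duration = spec$blink_duration,
                              gaze_excursion_per_min =
                                spec$gaze_excursion_per_min,
                              rate = ch$pupil$rate)
      resp <- simulate_respiration(events, rarf, truth$resp,
                                   spec$baseline$resp_amp,
                                   spec$baseline$resp_freq_Hz,
                                   ch$resp$noise, t_end,
                                   us_amp = ch$resp$us_amp,
                                   rate = ch$resp$rate)
      list(participant = p, events = events, d = d_i, t_end = t_end,
           beats = beats, scr = scr, pupil = pupil, resp = resp,
           truth = truth, scr_us_truth = scr_us)
    })
  })
}

#' Simulate per-participant condition-mean amplitudes (statistical core)
#'
#' The amplitude layer of the generator without waveform synthesis: per
#' participant, a standardized effect `d_i ~ Normal(delta, between_sd^2)`
#' and per-trial amplitudes with `Normal(0, trial_sd^2)` noise, averaged
#' within condition. Used for statistical calibration (type-I error and
#' power), where waveforms are irrelevant. The true standardized paired
#' effect of the design is
#' `delta / sqrt(between_sd^2 + trial_sd^2 * (1/n_csp + 1/n_csm))`.
#'
#' @param n_participants cohort size.
#' @param delta,between_sd,trial_sd see [cohort_spec()].
#' @param n_csp,n_csm trials per condition entering the averages.
#' @return data.frame with `csp` and `csm` per-participant condition means
#'   (standardized units).
#' @export
simulate_amplitude_cohort <- function(n_participants, delta = 0,
                                      between_sd = 1, trial_sd = 2,
                                      n_csp = 24, n_csm = 48) {
  d <- stats::rnorm(n_participants, delta, between_sd)
  csp <- d + stats::rnorm(n_participants, 0, trial_sd / sqrt(n_csp))
  csm <- stats::rnorm(n_participants, 0, trial_sd / sqrt(n_csm))
  data.frame(csp = csp, csm = csm)
}

#' True paired effect size implied by generator settings
#'
#' Closed form for the standardized effect of the paired CS+/CS− contrast
#' after averaging `n_csp` and `n_csm` trials per condition.
#'
#' @inheritParams simulate_amplitude_cohort
#' @return scalar effect size.
#' @export
true_paired_effect <- function(delta, between_sd = 1, trial_sd = 2,
                               n_csp = 24, n_csm = 48) {
  delta / sqrt(between_sd^2 + trial_sd^2 * (1 / n_csp + 1 / n_csm))
}
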