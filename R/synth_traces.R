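#' Build a stimulus schedule
#'
#' Consecutive stimulus windows with a fixed on-duration and rinse interval,
#' the schedule used for lingual stimulation: each stimulus applied for 30 s
#' and rinsed for 40 s.
#'
#' @param labels stimulus labels, in presentation order.
#' @param first_onset time of the first onset (s).
#' @param duration stimulus duration (s, default 30).
#' @param rinse inter-stimulus rinse (s, default 40).
#' @return data.frame `label`, `onset`, `duration`.
#' @export
stimulus_schedule <- function(labels, first_onset = 40, duration = 30,
                              rinse = 40) {
  data.frame(label = labels,
             onset = first_onset + (seq_along(labels) - 1) * (duration + rinse),
             duration = duration)
}

#' Uniformly sampled recording with a stimulus schedule
#'
#' @param values numeric signal samples; sample `i` is at time `(i-1)/rate`.
#' @param sampling_rate sampling rate (Hz).
#' @param schedule data.frame `label`, `onset`, `duration` (seconds).
#' @param kind `"nerve"` (integrated whole-nerve signal) or `"calcium"`
#'   (dimensionless 340/380 fura-2 ratio).
#' @return object of class `trace_recording`.
#' @export
trace_recording <- function(values, sampling_rate, schedule,
                            kind = c("nerve", "calcium")) {
  kind <- match.arg(kind)
  assert_that(sampling_rate > 0, "sampling_rate must be positive")
  assert_that(all(diff(schedule$onset) > 0), "onsets must be strictly increasing")
  span <- (length(values) - 1) / sampling_rate
  assert_that(all(schedule$onset >= 0) &&
                all(schedule$onset + schedule$duration <= span),
              "stimulus windows must lie within the recording span")
  off <- schedule$onset + schedule$duration
  if (nrow(schedule) > 1) {
    assert_that(all(schedule$onset[-1] >= off[-nrow(schedule)]),
                "stimulus windows overlap")
  }
  structure(list(values = values, sampling_rate = sampling_rate,
                 schedule = schedule, kind = kind),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("<trace_recording> kind '%s', %d samples @ %g Hz, %d stimuli\n",
              x$kind, length(x$values), x$sampling_rate, nrow(x$schedule)))
  invisible(x)
}

#' Parameters for synthetic trace recordings
#'
#' Defaults emulate the recording conditions analyzed downstream: integrated
#' chorda tympani traces sampled at 10 Hz with a 30 s stimulus / 40 s rinse
#' schedule, and fura-2 ratio traces sampled at 1 Hz (dual-excitation
#' ratio imaging is slow) with a >= 15 s pre-stimulus baseline.
#'
#' @param kind `"nerve"` or `"calcium"`.
#' @param sampling_rate Hz; default 10 (nerve) or 1 (calcium).
#' @param baseline_level baseline signal; must be positive.
#' @param drift_slope linear baseline drift (signal units per second).
#' @param amplitudes named numeric: response amplitude per stimulus, in
#'   signal units above baseline.
#' @param rise_tau,decay_tau response kinetics time constants (s); a
#'   `rise_tau` of 0 gives an instantaneous plateau.
#' @param schedule stimulus schedule; default built from `names(amplitudes)`
#'   with [stimulus_schedule()].
#' @param tail_s recording time after the last offset (s).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return validated list of class `trace_sim_params`.
#' @export
trace_sim_params <- function(kind = c("nerve", "calcium"),
                             sampling_rate = NULL,
                             baseline_level = NULL,
                             drift_slope = 0,
                             amplitudes = NULL,
                             rise_tau = NULL, decay_tau = NULL,
                             schedule = NULL, tail_s = 40,
                             noise_sd = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "nerve") {
    sampling_rate <- sampling_rate %||% 10
    baseline_level <- baseline_level %||% 2.0
    amplitudes <- amplitudes %||% c(NH4Cl = 1.0, sucrose = 0.8, NaCl = 0.9,
                                    citric_acid = 1.0)
    rise_tau <- rise_tau %||% 1.5
    decay_tau <- decay_tau %||% 4
    noise_sd <- noise_sd %||% 0.1
  } else {
    sampling_rate <- sampling_rate %||% 1
    baseline_level <- baseline_level %||% 1.0
    amplitudes <- amplitudes %||% c(ATP = 0.5, `5HT` = 0.3, KCl = 0.6)
    rise_tau <- rise_tau %||% 3
    decay_tau <- decay_tau %||% 8
    noise_sd <- noise_sd %||% 0.01
  }
  assert_that(baseline_level > 0, "baseline_level must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  schedule <- schedule %||% stimulus_schedule(names(amplitudes))
  assert_that(nrow(schedule) == length(amplitudes),
              "one schedule entry per amplitude required")
  if (kind == "calcium") {
    assert_that(schedule$onset[1] >= 15,
                "calcium schedules must leave a >= 15 s baseline before the first stimulus")
  }
  structure(list(kind = kind, sampling_rate = sampling_rate,
                 baseline_level = baseline_level, drift_slope = drift_slope,
                 amplitudes = amplitudes, rise_tau = rise_tau,
                 decay_tau = decay_tau, schedule = schedule, tail_s = tail_s,
                 noise_sd = noise_sd, seed = seed),
            class = "trace_sim_params")
}

# Noiseless response waveform on the given sample times.
trace_waveform <- function(p, times) {
  v <- p$baseline_level + p$drift_slope * times
  for (i in seq_len(nrow(p$schedule))) {
    on <- p$schedule$onset[i]
    off <- on + p$schedule$duration[i]
    amp <- p$amplitudes[[i]]
    g <- numeric(length(times))
    during <- times >= on & times < off
    if (p$rise_tau > 0) {
      g[during] <- 1 - exp(-(times[during] - on) / p$rise_tau)
      g_off <- 1 - exp(-p$schedule$duration[i] / p$rise_tau)
    } else {
      g[during] <- 1
      g_off <- 1
    }
    after <- times >= off
    g[after] <- g_off * exp(-(times[after] - off) / p$decay_tau)
    v <- v + amp * g
  }
  v
}

#' Generate a synthetic integrated nerve trace
#'
#' Nonnegative integrated-signal trace: baseline plus optional linear drift,
#' exponential-kinetics responses in each stimulus window, additive Gaussian
#' noise.  The stored truth holds, per stimulus, the generating amplitude and
#' the baseline-normalized response `true_R` recomputed from the noiseless
#' waveform with the same windowing the analysis uses (so recovery tests are
#' self-consistent whatever the kinetics).
#'
#' @param params a [trace_sim_params()] with `kind = "nerve"`.
#' @return list with `trace` ([trace_recording()]) and `truth` (data.frame
#'   `label`, `amplitude`, `true_R`).
#' @export
generate_nerve_trace <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"), params$kind == "nerve")
  p <- params
  n <- ceiling((max(p$schedule$onset + p$schedule$duration) + p$tail_s) *
                 p$sampling_rate) + 1L
  times <- (seq_len(n) - 1) / p$sampling_rate
  clean <- trace_waveform(p, times)
  values <- with_seed(p$seed, {
    v <- clean
    if (p$noise_sd > 0) v <- v + rnorm(n, sd = p$noise_sd)
    pmax(v, 0)
  })
  trace <- trace_recording(values, p$sampling_rate, p$schedule, kind = "nerve")
  clean_trace <- trace_recording(clean, p$sampling_rate, p$schedule,
                                 kind = "nerve")
  truth <- nerve_response(clean_trace)$responses
  truth <- data.frame(label = truth$label,
                      amplitude = unname(p$amplitudes),
                      true_R = truth$R)
  list(trace = trace, truth = truth)
}

#' Generate a synthetic fura-2 ratio trace
#'
#' Dimensionless 340/380 ratio trace with a baseline segment of at least
#' 15 s before the first stimulus.  Truth stores, per stimulus, the
#' generating amplitude and the peak-minus-baseline `true_dR` recomputed
#' from the noiseless waveform.
#'
#' @param params a [trace_sim_params()] with `kind = "calcium"`.
#' @return list with `trace` and `truth` (`label`, `amplitude`, `true_dR`).
#' @export
generate_calcium_trace <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"), params$kind == "calcium")
  p <- params
  n <- ceiling((max(p$schedule$onset + p$schedule$duration) + p$tail_s) *
                 p$sampling_rate) + 1L
  times <- (seq_len(n) - 1) / p$sampling_rate
  clean <- trace_waveform(p, times)
  values <- with_seed(p$seed, {
    v <- clean
    if (p$noise_sd > 0) v <- v + rnorm(n, sd = p$noise_sd)
    pmax(v, 0)
  })
  trace <- trace_recording(values, p$sampling_rate, p$schedule,
                           kind = "calcium")
  base_true <- p$baseline_level
  true_dR <- vapply(seq_len(nrow(p$schedule)), function(i) {
    on <- p$schedule$onset[i]; off <- on + p$schedule$duration[i]
    win <- times >= on & times <= off
    max(clean[win]) - base_true
  }, 0)
  truth <- data.frame(label = p$schedule$label,
                      amplitude = unname(p$amplitudes), true_dR = true_dR)
  list(trace = trace, truth = truth)
}
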