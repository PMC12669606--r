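# Synthetic single-channel recording generator: continuous-time two-state
# Markov gating, ohmic (optionally saturating) open-channel current,
# band-limited Gaussian noise, and the acquisition chain of a bilayer rig
# (4-pole Bessel anti-alias filter, 100 kHz digitization).

#' Generating parameters of a single pore
#'
#' @param conductance_pS Single-channel conductance in pS (>= 0).
#' @param e_rev_mV Reversal potential in mV.
#' @param k_open_s,k_close_s Opening and closing rates of the two-state
#'   Markov gate, per second (> 0). The defaults (50/s each) give mean dwell
#'   times of 20 ms, long relative to the rise time of an 800 Hz analysis
#'   filter, and open probability 1/2.
#' @param baseline_pA Closed-level (baseline) current offset in pA.
#' @param noise_sd_pA Standard deviation of the white (pre-filter) Gaussian
#'   current noise, in pA.
#' @param v_half_mV Optional saturation half-voltage; when set, positive
#'   driving forces follow [saturating_open_current()] instead of the ohmic
#'   line.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(conductance_pS = 18.4, e_rev_mV = 0,
                          k_open_s = 50, k_close_s = 50,
                          baseline_pA = 0, noise_sd_pA = 0.15,
                          v_half_mV = NULL) {
  if (conductance_pS < 0) err_domain("conductance must be >= 0")
  if (k_open_s <= 0 || k_close_s <= 0) err_domain("gating rates must be > 0")
  if (noise_sd_pA < 0) err_domain("noise SD must be >= 0")
  if (!is.null(v_half_mV) && v_half_mV <= 0) {
    err_domain("saturation half-voltage must be > 0")
  }
  structure(list(
    conductance_pS = conductance_pS, e_rev_mV = e_rev_mV,
    k_open_s = k_open_s, k_close_s = k_close_s,
    baseline_pA = baseline_pA, noise_sd_pA = noise_sd_pA,
    v_half_mV = v_half_mV
  ), class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(
    "<channel_model> G = %.3g pS, E_rev = %.3g mV, k_open = %g/s, k_close = %g/s, noise SD = %.3g pA%s\n",
    x$conductance_pS, x$e_rev_mV, x$k_open_s, x$k_close_s, x$noise_sd_pA,
    if (is.null(x$v_half_mV)) "" else sprintf(", V_half = %g mV", x$v_half_mV)
  ))
  invisible(x)
}

#' Acquisition settings of the recording chain
#'
#' Defaults mirror a standard bilayer setup: 100 kHz digitization after a
#' 10 kHz four-pole Bessel anti-alias filter, analyzed at 800 Hz (-3 dB).
#'
#' @param fs_Hz Sampling rate (Hz).
#' @param analog_cutoff_Hz Anti-alias (analog) low-pass -3 dB cutoff (Hz).
#' @param analysis_cutoff_Hz Digital analysis low-pass -3 dB cutoff (Hz).
#' @param duration_s Recording duration in seconds (> 0).
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(fs_Hz = 1e5, analog_cutoff_Hz = 1e4,
                                 analysis_cutoff_Hz = 800, duration_s = 60) {
  if (duration_s <= 0) err_domain("duration must be > 0")
  if (analog_cutoff_Hz >= fs_Hz / 2 || analysis_cutoff_Hz >= fs_Hz / 2) {
    err_config("filter cutoffs must be below Nyquist")
  }
  structure(list(
    fs_Hz = fs_Hz, analog_cutoff_Hz = analog_cutoff_Hz,
    analysis_cutoff_Hz = analysis_cutoff_Hz, duration_s = duration_s
  ), class = "acquisition_settings")
}

#' Sampled current trace with acquisition metadata
#'
#' Container for a current time series. `meta` is a free-form named list;
#' the voltage (`voltage_mV`) is mandatory for downstream analysis.
#'
#' @param current_pA Numeric vector of current samples (pA), finite, length
#'   >= 2.
#' @param dt Sample interval in seconds.
#' @param meta Named list of metadata (holding voltage, solutions, junction
#'   potential, generator provenance, seed, ...).
#' @return An object of class `recording_trace`.
#' @export
recording_trace <- function(current_pA, dt, meta = list()) {
  if (length(current_pA) < 2L) err_format("a trace needs at least 2 samples")
  if (!all(is.finite(current_pA))) err_format("trace contains non-finite samples")
  if (dt <= 0) err_format("sample interval must be > 0")
  structure(list(current_pA = as.numeric(current_pA), dt = dt, meta = meta),
            class = "recording_trace")
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf(
    "<recording_trace> %d samples @ %g kHz (%.3g s)%s\n",
    length(x$current_pA), 1e-3 / x$dt, length(x$current_pA) * x$dt,
    if (!is.null(x$meta$voltage_mV)) sprintf(", V = %g mV", x$meta$voltage_mV)
    else ""
  ))
  invisible(x)
}

#' Simulate two-state Markov gating
#'
#' Continuous-time alternating renewal process: dwell times are exponential
#' with mean `1/k_close` in the open state and `1/k_open` in the closed
#' state. The initial state is drawn from the stationary distribution
#' `P(open) = k_open / (k_open + k_close)`. The sequence spans exactly
#' `duration_s`; the final dwell is truncated.
#'
#' @param model A [channel_model()].
#' @param duration_s Total simulated time in seconds (> 0).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A data.frame with columns `state` ("open"/"closed"), `t_start_s`
#'   and `duration_s`.
#' @export
simulate_gating <- function(model, duration_s, seed = NULL) {
  stopifnot(inherits(model, "channel_model"))
  if (duration_s <= 0) err_domain("duration must be > 0")
  with_seed(seed, {
    p_open <- model$k_open_s / (model$k_open_s + model$k_close_s)
    state <- if (runif(1) < p_open) 1L else 0L
    states <- integer(0); durs <- numeric(0)
    t <- 0
    while (t < duration_s) {
      rate <- if (state == 1L) model$k_close_s else model$k_open_s
      d <- rexp(1, rate)
      d <- min(d, duration_s - t)
      states <- c(states, state); durs <- c(durs, d)
      t <- t + d
      state <- 1L - state
    }
    data.frame(
      state = ifelse(states == 1L, "open", "closed"),
      t_start_s = cumsum(c(0, durs[-length(durs)])),
      duration_s = durs
    )
  })
}

#' Saturating open-channel current
#'
#' One-sided rectangular-hyperbola saturation in the driving force: for
#' `d = voltage - e_rev <= 0` the current is ohmic; for `d > 0` it is
#' `G * d / (1 + d / v_half)`, continuous at `d = 0` and converging to the
#' ohmic value as `v_half` grows. This reproduces current saturation seen
#' only at large positive potentials.
#'
#' @inheritParams ohmic_open_current
#' @param v_half_mV Driving force (mV, > 0) at which the current is half the
#'   ohmic value.
#' @return Current in pA.
#' @export
saturating_open_current <- function(conductance_pS, voltage_mV, e_rev_mV,
                                    v_half_mV) {
  if (any(v_half_mV <= 0)) err_domain("v_half must be > 0")
  d <- voltage_mV - e_rev_mV
  ifelse(d <= 0,
         conductance_pS * d * 1e-3,
         conductance_pS * (d / (1 + d / v_half_mV)) * 1e-3)
}

open_level_pA <- function(model, voltage_mV) {
  i <- if (is.null(model$v_half_mV)) {
    ohmic_open_current(model$conductance_pS, voltage_mV, model$e_rev_mV)
  } else {
    saturating_open_current(model$conductance_pS, voltage_mV,
                            model$e_rev_mV, model$v_half_mV)
  }
  model$baseline_pA + i
}

#' Render a gating sequence into a sampled current trace
#'
#' current = gate x open-channel current + baseline + band-limited noise.
#' White Gaussian noise of SD `model$noise_sd_pA` is added at the sampling
#' rate and passed, together with the signal, through the analog anti-alias
#' filter (4-pole Bessel at `acq$analog_cutoff_Hz`).
#'
#' @param dwells Dwell table from [simulate_gating()]; must span
#'   `acq$duration_s`.
#' @param model A [channel_model()].
#' @param voltage_mV Holding potential in mV.
#' @param acq An [acquisition_settings()].
#' @param seed Integer seed for the noise stream.
#' @param meta Extra metadata merged into the trace metadata.
#' @return A [recording_trace()]; metadata records all generation
#'   parameters.
#' @export
render_trace <- function(dwells, model, voltage_mV, acq, seed = NULL,
                         meta = list()) {
  stopifnot(inherits(model, "channel_model"),
            inherits(acq, "acquisition_settings"))
  span <- sum(dwells$duration_s)
  if (span < acq$duration_s - 1e-9) {
    err_domain("dwell sequence does not cover the acquisition duration")
  }
  n <- round(acq$duration_s * acq$fs_Hz)
  dt <- 1 / acq$fs_Hz
  # per-sample gate: sample i covers time (i-1)*dt; assign by dwell edges
  edges <- cumsum(dwells$duration_s)
  counts <- diff(c(0L, pmin(round(edges * acq$fs_Hz), n)))
  gate <- rep(dwells$state == "open", counts)
  if (length(gate) < n) gate <- c(gate, rep(gate[length(gate)], n - length(gate)))
  open_i <- open_level_pA(model, voltage_mV)
  x <- model$baseline_pA + (open_i - model$baseline_pA) * gate
  if (model$noise_sd_pA > 0) {
    x <- x + with_seed(seed, rnorm(n, sd = model$noise_sd_pA))
  }
  des <- bessel_lowpass_design(acq$analog_cutoff_Hz, acq$fs_Hz)
  x <- iir_filter(x, des)
  md <- modifyList(list(
    voltage_mV = voltage_mV,
    seed = seed,
    generator = "ionpore two-state Markov",
    conductance_pS = model$conductance_pS,
    e_rev_mV = model$e_rev_mV,
    k_open_s = model$k_open_s,
    k_close_s = model$k_close_s,
    baseline_pA = model$baseline_pA,
    noise_sd_pA = model$noise_sd_pA,
    v_half_mV = model$v_half_mV,
    fs_Hz = acq$fs_Hz,
    analog_cutoff_Hz = acq$analog_cutoff_Hz
  ), meta)
  recording_trace(x, dt, md)
}

#' Simulate a complete analysis-ready recording
#'
#' Convenience wrapper: [simulate_gating()], [render_trace()], then the
#' analysis low-pass via [apply_lowpass()]. Gating and noise use seeds
#' derived deterministically from `seed`.
#'
#' @inheritParams render_trace
#' @param seed Integer master seed.
#' @param analysis_filter Apply the analysis low-pass (default TRUE).
#' @return A [recording_trace()].
#' @export
simulate_recording <- function(model, voltage_mV, acq = acquisition_settings(),
                               seed = 1L, meta = list(),
                               analysis_filter = TRUE) {
  dwells <- simulate_gating(model, acq$duration_s, seed = seed)
  tr <- render_trace(dwells, model, voltage_mV, acq,
                     seed = seed + 500009L, meta = meta)
  if (analysis_filter) tr <- apply_lowpass(tr, acq$analysis_cutoff_Hz)
  tr
}
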