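#' Conditioning protocol specification
#'
#' Declarative description of one conditioning paradigm. Closed-loop
#' variants (`spike_triggered`, `spike_triggered_inhibition`,
#' `emg_triggered`, `gamma_triggered`, `cycle_triggered`) detect triggers
#' inside the simulation loop; open-loop variants (`paired_pulse`,
#' `tetanic`) are expanded into a stimulus schedule before the run.
#'
#' @param variant One of `"spike_triggered"`, `"spike_triggered_inhibition"`,
#'   `"emg_triggered"`, `"gamma_triggered"`, `"cycle_triggered"`,
#'   `"paired_pulse"`, `"tetanic"`, `"none"`.
#' @param trigger_unit Trigger unit id for spike-triggered variants
#'   (default 1 = first excitatory unit of column A).
#' @param trigger_column Column supplying the trigger signal (spike/LFP/EMG
#'   source), default `"A"`.
#' @param target_column Column receiving the conditioning stimulus,
#'   default `"B"` (cycle-triggered stimulates `"A"`).
#' @param delay Trigger-to-stimulus delay (ms). For `paired_pulse` this is
#'   the (signed) interval from the A pulse to the B pulse.
#' @param amplitude Stimulus amplitude (mV); negative for inhibition.
#' @param train_pulses Pulses per stimulus (1, 2 or 3).
#' @param train_interval Intra-train interval (ms).
#' @param lockout Minimum inter-trigger interval (ms). Defaults: 0 for
#'   spike triggers, 20 for EMG, 10 for gamma, 35 for cycle triggers.
#' @param band Band edges (Hz) for LFP-derived triggers
#'   (cycle: `c(15, 25)`; gamma default `c(50, 80)`).
#' @param phase Stimulation phase for `cycle_triggered` (degrees; 0 = rising
#'   zero crossing of the band-passed LFP, 180 = falling).
#' @param target_rate Trigger rate (per s) the EMG/gamma threshold is
#'   calibrated to.
#' @param rate Stimulation rate (Hz) for `tetanic`, repetition rate for
#'   `paired_pulse` pairs.
#' @param refractory Imposed refractory period for `tetanic` (ms).
#' @param episode_level_sd Cycle-trigger arming level, as a multiple of the
#'   SD of the band-passed LFP measured during the preconditioning test
#'   period.
#' @param emg_band EMG band-pass edges (Hz) for the EMG trigger path.
#' @return An object of class `protocol_spec`.
#' @export
#' @examples
#' protocol_spec("spike_triggered", delay = 10)
#' protocol_spec("cycle_triggered", phase = -15)
protocol_spec <- function(variant = c("spike_triggered",
                                      "spike_triggered_inhibition",
                                      "emg_triggered", "gamma_triggered",
                                      "cycle_triggered", "paired_pulse",
                                      "tetanic", "none"),
                          trigger_unit = 1,
                          trigger_column = NULL,
                          target_column = NULL,
                          delay = 10,
                          amplitude = NULL,
                          train_pulses = 1,
                          train_interval = 33,
                          lockout = NULL,
                          band = NULL,
                          phase = 0,
                          target_rate = 6,
                          rate = NULL,
                          refractory = 10,
                          episode_level_sd = 2,
                          emg_band = c(100, 2500)) {
  variant <- match.arg(variant)
  if (is.null(trigger_column))
    trigger_column <- if (variant == "cycle_triggered") "B" else "A"
  if (is.null(target_column))
    target_column <- if (variant == "cycle_triggered") "A" else "B"
  if (is.null(amplitude))
    amplitude <- if (variant == "spike_triggered_inhibition") -2 else 2
  if (is.null(lockout))
    lockout <- switch(variant, emg_triggered = 20, gamma_triggered = 10,
                      cycle_triggered = 35, 0)
  if (is.null(band))
    band <- switch(variant, cycle_triggered = c(15, 25),
                   gamma_triggered = c(50, 80), NULL)
  if (is.null(rate))
    rate <- switch(variant, tetanic = 10, paired_pulse = 1.4, NULL)
  if (variant != "paired_pulse" && delay < 0)
    stop("negative delays are only meaningful for paired_pulse")
  stopifnot(train_pulses >= 1, train_interval > 0, lockout >= 0)
  structure(list(variant = variant, trigger_unit = trigger_unit,
                 trigger_column = column_index(trigger_column),
                 target_column = column_index(target_column),
                 delay = delay, amplitude = amplitude,
                 train_pulses = train_pulses,
                 train_interval = train_interval, lockout = lockout,
                 band = band, phase = phase, target_rate = target_rate,
                 rate = rate, refractory = refractory,
                 episode_level_sd = episode_level_sd, emg_band = emg_band),
            class = "protocol_spec")
}

#' Named protocol presets
#'
#' Standard configurations of each conditioning paradigm, including the
#' more active variant used to demonstrate robust spike-triggered
#' inhibition (45% correlated bias, weakening factor 0.5, -3 mV pulses) --
#' for that preset the returned list also carries `bias` and `plast`
#' overrides.
#'
#' @param name Preset name.
#' @return A `protocol_spec` (possibly with `$overrides`).
#' @export
protocol_preset <- function(name = c("spike_triggered", "emg_triggered",
                                     "paired_pulse", "cycle_triggered",
                                     "gamma_triggered", "tetanic",
                                     "inhibition", "inhibition_active",
                                     "disynaptic_pp", "disynaptic_cycle")) {
  name <- match.arg(name)
  switch(name,
    spike_triggered = protocol_spec("spike_triggered", delay = 10),
    emg_triggered = protocol_spec("emg_triggered", delay = 0),
    paired_pulse = protocol_spec("paired_pulse", delay = 10),
    cycle_triggered = protocol_spec("cycle_triggered", phase = 0),
    gamma_triggered = protocol_spec("gamma_triggered", delay = 0),
    tetanic = protocol_spec("tetanic", rate = 10),
    inhibition = protocol_spec("spike_triggered_inhibition", delay = 10),
    inhibition_active = {
      p <- protocol_spec("spike_triggered_inhibition", delay = 10,
                         amplitude = -3)
      p$overrides <- list(correlated_fraction = 0.45, weakening = 0.5)
      p
    },
    disynaptic_pp = {
      p <- protocol_spec("paired_pulse", delay = 12, amplitude = 3)
      p$lesion <- c("A", "B")
      p
    },
    disynaptic_cycle = {
      p <- protocol_spec("cycle_triggered", phase = 0, amplitude = 3.5)
      p$lesion <- c("A", "B")
      p$episode <- episode_spec(cycles = 7)
      p
    })
}

#' Open-loop tetanic stimulation schedule
#'
#' Stimulus times at a nominal Poisson rate with an imposed refractory
#' period: inter-stimulus intervals are the refractory period plus an
#' exponential with mean `1/rate - refractory`, so the mean rate equals the
#' nominal rate and no two stimuli fall closer than the refractory period.
#'
#' @param duration Schedule length (s).
#' @param rate Nominal stimulation rate (Hz).
#' @param refractory Minimum inter-stimulus interval (ms).
#' @return Stimulus times (ms), strictly increasing.
#' @export
schedule_tetanic <- function(duration, rate = 10, refractory = 10) {
  stopifnot(duration > 0, rate >= 0, refractory >= 0)
  if (rate <= 0) return(numeric(0))
  if (rate * refractory >= 1000)
    stop("rate and refractory period are incompatible")
  mean_gap <- 1000 / rate - refractory
  n_guess <- ceiling(duration * rate * 1.5) + 20
  gaps <- refractory + stats::rexp(n_guess, 1 / mean_gap)
  times <- cumsum(gaps)
  while (times[length(times)] < duration * 1000) {
    gaps <- refractory + stats::rexp(n_guess, 1 / mean_gap)
    times <- c(times, times[length(times)] + cumsum(gaps))
  }
  times[times < duration * 1000]
}

#' Open-loop paired-pulse stimulus schedule
#'
#' Pairs (or paired trains) of pulses delivered to two columns at a fixed
#' signed delay, repeating periodically. A negative delay stimulates the
#' second column first.
#'
#' @param duration Schedule length (s).
#' @param spec A `paired_pulse` [protocol_spec()].
#' @param columns The two stimulated columns (first gets the reference
#'   pulse).
#' @return A data.frame `time` (ms), `column` (index), `amplitude` (mV).
#' @export
paired_pulse_schedule <- function(duration, spec = protocol_spec("paired_pulse"),
                                  columns = c("A", "B")) {
  ci <- column_index(columns)
  t0 <- seq(1000 / spec$rate, duration * 1000, by = 1000 / spec$rate)
  train <- (seq_len(spec$train_pulses) - 1) * spec$train_interval
  # keep only repetitions whose complete trains fit inside the period
  last <- max(train) + max(spec$delay, 0)
  t0 <- t0[t0 + last < duration * 1000 & t0 + min(spec$delay, 0) >= 0]
  a_times <- rep(t0, each = length(train)) + train
  b_times <- a_times + spec$delay
  out <- data.frame(
    time = c(a_times, b_times),
    column = rep(ci, each = length(a_times)),
    amplitude = spec$amplitude)
  out[order(out$time), ]
}

#' Spike-trigger detection on a recorded spike train
#'
#' Every spike of the designated unit emits a trigger, subject to the
#' lockout interval.
#'
#' @param spike_times Spike times of the trigger unit (ms).
#' @param lockout Minimum inter-trigger interval (ms).
#' @return Trigger times (ms).
#' @export
detect_spike_trigger <- function(spike_times, lockout = 0) {
  apply_lockout(sort(spike_times), lockout)
}

apply_lockout <- function(times, lockout) {
  if (!length(times) || lockout <= 0) return(times)
  keep <- numeric(length(times)); n <- 0; last <- -Inf
  for (t in times) {
    if (t - last >= lockout) { n <- n + 1; keep[n] <- t; last <- t }
  }
  keep[seq_len(n)]
}

#' Threshold-crossing trigger detection on a sampled signal
#'
#' Finds the steps at which the signal crosses a threshold in the given
#' direction, then suppresses crossings within the lockout of an accepted
#' trigger. This is the offline counterpart of the engine's online
#' detector, used for calibration and analysis.
#'
#' @param signal Signal sampled on the step grid.
#' @param h Sampling step (ms).
#' @param threshold Crossing level; must be finite.
#' @param edge `"rising"` or `"falling"`.
#' @param lockout Minimum inter-trigger interval (ms).
#' @return Trigger times (ms, time of the first sample beyond threshold).
#' @export
detect_threshold_trigger <- function(signal, h, threshold,
                                     edge = c("rising", "falling"),
                                     lockout = 0) {
  edge <- match.arg(edge)
  if (!is.finite(threshold)) stop("threshold must be finite")
  x <- signal
  prev <- c(-Inf, x[-length(x)])
  idx <- if (edge == "rising") which(prev <= threshold & x > threshold)
         else which(prev >= threshold & x < threshold)
  idx <- idx[idx > 1]
  apply_lockout((idx - 1) * h, lockout)
}

#' Calibrate a trigger threshold to a target rate
#'
#' Bisection on the empirical (lockout-respecting) crossing rate of a
#' recorded calibration signal. The calibration window should precede
#' conditioning with plasticity off.
#'
#' @param signal Recorded (already filtered) calibration signal.
#' @param h Sampling step (ms).
#' @param target_rate Desired trigger rate (per s).
#' @param edge Crossing direction.
#' @param lockout Lockout interval (ms).
#' @param tol Acceptable relative error on the rate.
#' @return The calibrated threshold.
#' @export
calibrate_trigger_threshold <- function(signal, h, target_rate = 6,
                                        edge = c("rising", "falling"),
                                        lockout = 0, tol = 0.1) {
  edge <- match.arg(edge)
  stopifnot(target_rate >= 0)
  dur_s <- length(signal) * h / 1000
  if (target_rate == 0) return(max(signal) + 1)
  rate_at <- function(thr)
    length(detect_threshold_trigger(signal, h, thr, edge, lockout)) / dur_s
  lo <- 0; hi <- max(abs(signal))
  if (edge == "falling") { lo <- -hi; hi <- 0 }
  # ensure the bracket actually straddles the target
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (max(r_lo, r_hi) < target_rate * (1 - tol))
    stop("target trigger rate unreachable; achievable at most ",
         signif(max(r_lo, r_hi), 3), "/s")
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) <= tol * target_rate) return(mid)
    # rate decreases as |threshold| grows away from zero
    if (edge == "rising") {
      if (r > target_rate) lo <- mid else hi <- mid
    } else {
      if (r > target_rate) hi <- mid else lo <- mid
    }
  }
  mid
}

#' Cycle-trigger detection on a recorded LFP
#'
#' Offline counterpart of the engine's closed-loop beta-cycle trigger: the
#' signal is band-pass filtered with a causal Butterworth filter; once the
#' filtered trace exceeds the arming level, the next zero crossing of the
#' requested type fires a trigger at the crossing plus the phase offset.
#'
#' @param lfp Raw LFP samples on the step grid.
#' @param h Sampling step (ms).
#' @param band Band edges (Hz).
#' @param level Arming level (same units as the filtered signal).
#' @param phase Stimulation phase (degrees).
#' @param lockout Minimum inter-trigger interval (ms).
#' @param frequency Nominal oscillation frequency (Hz), sets the period used
#'   to convert phase to a delay.
#' @return Trigger (stimulus) times in ms.
#' @export
detect_cycle_trigger <- function(lfp, h, band = c(15, 25), level,
                                 phase = 0, lockout = 35, frequency = 20) {
  bf <- butter_band(band, h)
  y <- as.numeric(signal::filter(bf, lfp))
  ph <- phase_to_crossing(phase, period = 1000 / frequency)
  armed <- FALSE; last <- -Inf; out <- numeric(0)
  prev <- 0
  for (i in seq_along(y)) {
    if (y[i] > level) armed <- TRUE
    crossed <- if (ph$cross == "rising") prev <= 0 && y[i] > 0
               else prev >= 0 && y[i] < 0
    if (armed && crossed) {
      t <- (i - 1) * h
      if (t - last >= lockout) {
        out <- c(out, t + ph$extra_ms); last <- t
      }
      armed <- FALSE
    }
    prev <- y[i]
  }
  out
}

# Map a stimulation phase (degrees) to a zero-crossing type plus a fixed
# delay, assuming the nominal oscillation period: phases in [0, 180) anchor
# on the rising crossing, [180, 360) on the falling crossing.
phase_to_crossing <- function(phase, period = 50) {
  ph <- phase %% 360
  if (ph < 180) list(cross = "rising", extra_ms = ph / 360 * period)
  else list(cross = "falling", extra_ms = (ph - 180) / 360 * period)
}

# Causal 2nd-order Butterworth band-pass on the step grid.
butter_band <- function(band, h) {
  fs <- 1000 / h
  if (band[2] >= fs / 2)
    stop("band edge at or above the Nyquist frequency for this step size")
  signal::butter(2, band / (fs / 2), type = "pass")
}
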