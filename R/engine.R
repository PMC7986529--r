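#' Compile a network into a simulation engine
#'
#' Builds the C++ stepping engine for a network: connectivity in compressed
#' form, bias-input generators for each column, the motoneuron drive, and
#' (optionally) an oscillatory bias envelope on one column. The engine owns
#' all dynamic state (potentials, traces, spike ring buffers, pending
#' deliveries) and persists it across [engine_run()] calls, so a long run
#' can be split into blocks without any discontinuity.
#'
#' @param network A [build_network()] result (possibly lesioned or with
#'   fixed intracolumn connections).
#' @param bias A [bias_config()] applied to every column. If the network
#'   was configured with `remove_correlated_bias`, the full rate is
#'   delivered uncorrelated.
#' @param envelope Optional list `list(column =, spec = episode_spec())`
#'   modulating that column's bias probabilities.
#' @param motor_drive_rate Uncorrelated external drive to each motoneuron
#'   (events/s), standing in for all non-cortical motoneuron input.
#' @param motor_drive_strength PSP maximum of one motor drive event (uV).
#' @return An object of class `network_engine`.
#' @export
compile_network <- function(network, bias = bias_config(), envelope = NULL,
                            motor_drive_rate = 1500,
                            motor_drive_strength = 350) {
  stopifnot(inherits(network, "spiking_network"))
  sim <- network$sim; plast <- network$plast
  u <- network$units; e <- network$edges
  frac <- if (isTRUE(network$correlated_bias_removed)) 0 else
    bias$correlated_fraction
  env_col <- 0L; env <- list(depth = 0, frequency = 20, cycles = 6,
                             episodes_per_block = 4)
  if (!is.null(envelope)) {
    env_col <- column_index(envelope$column)
    env <- envelope$spec
  }
  cfg <- list(
    h = sim$h, tau_s = sim$tau_s, tau_f = sim$tau_f,
    d_cort_steps = as.integer(round(sim$d_cortical / sim$h)),
    d_mot_steps = as.integer(round(sim$d_motor / sim$h)),
    r = plast$r, c = plast$c, a_s = plast$a_s, a_f = plast$a_f,
    b_s = plast$b_s, b_f = plast$b_f,
    w_min = plast$w_min, w_max = plast$w_max,
    block_s = sim$block_length,
    column = as.integer(u$column),
    is_moto = u$type == "m",
    threshold = u$threshold * 1000,
    muap_w = weight_from_strength(u$muap * 1000, plast),
    edge_src = as.integer(e$src), edge_dst = as.integer(e$dst),
    edge_w = e$weight, edge_plastic = e$plastic,
    bias_corr_rate = rep(bias$total_rate * frac, 3),
    bias_uncorr_rate = rep(bias$total_rate * (1 - frac), 3),
    bias_amp_w = rep(weight_from_strength(bias$event_strength, plast), 3),
    bias_jitter_ms = rep(bias$jitter_sd, 3),
    moto_rate = motor_drive_rate,
    moto_amp_w = weight_from_strength(motor_drive_strength, plast),
    env_col = as.integer(env_col),
    env_depth = env$depth, env_freq = env$frequency,
    env_cycles = env$cycles,
    env_episodes_per_block = as.integer(env$episodes_per_block))
  structure(list(ptr = .net_create(cfg), network = network, bias = bias,
                 envelope = envelope, sim = sim, plast = plast),
            class = "network_engine")
}

#' Advance the simulation
#'
#' Runs the engine for `duration` seconds of simulated time with a given
#' plasticity flag, optional closed-loop protocol, and optional open-loop
#' stimulus schedule. Randomness is drawn from R's RNG stream: call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param engine A [compile_network()] handle.
#' @param duration Simulated time to advance (s).
#' @param plasticity Apply STDP weight updates during this segment.
#' @param protocol A closed-loop [protocol_spec()] (spike-, EMG-, gamma- or
#'   cycle-triggered), already calibrated where needed (fields
#'   `threshold_value` / `level_value`), or NULL. Open-loop protocols are
#'   passed as `stim` schedules instead.
#' @param stim Optional data.frame `time` (ms, relative to segment start),
#'   `column`, `amplitude` (mV): stimulus pulses applied to all cortical
#'   units of the column.
#' @param forced Optional data.frame `time`, `unit`: unconditionally fire
#'   the unit at that step (testing facility for prescribed spike trains).
#' @param record Character vector among `"spikes"`, `"lfp"`, `"emg"`,
#'   `"filt"`.
#' @param v_unit Record the membrane potential of this unit id (0 = none).
#' @return A list: `spikes` (data.frame unit/time), `lfp` (matrix, uV),
#'   `emg` (matrix, mV), `v` (uV), `filt`, `triggers` (ms), `stim_log`,
#'   `truncated`.
#' @export
engine_run <- function(engine, duration, plasticity = TRUE, protocol = NULL,
                       stim = NULL, forced = NULL, record = "spikes",
                       v_unit = 0) {
  stopifnot(inherits(engine, "network_engine"))
  h <- engine$sim$h
  n_steps <- as.integer(round(duration * 1000 / h))

  if (is.null(stim)) {
    sstep <- integer(0); scol <- integer(0); samp <- numeric(0)
  } else {
    ord <- order(stim$time)
    stim <- stim[ord, , drop = FALSE]
    sstep <- as.integer(round(stim$time / h))
    scol <- as.integer(column_index(stim$column))
    samp <- stim$amplitude * 1000
    ok <- sstep >= 0 & sstep < n_steps
    sstep <- sstep[ok]; scol <- scol[ok]; samp <- samp[ok]
  }
  if (is.null(forced)) {
    fstep <- integer(0); funit <- integer(0)
  } else {
    ord <- order(forced$time)
    fstep <- as.integer(round(forced$time[ord] / h))
    funit <- as.integer(forced$unit[ord])
  }

  opts <- list(
    plasticity = isTRUE(plasticity),
    record_lfp = "lfp" %in% record,
    record_emg = "emg" %in% record,
    record_spikes = "spikes" %in% record,
    record_filt = "filt" %in% record,
    record_v_unit = as.integer(v_unit),
    stim_step = sstep, stim_col = scol, stim_amp = samp,
    forced_step = fstep, forced_unit = funit,
    protocol = if (is.null(protocol)) NULL else
      compile_protocol(protocol, engine))

  out <- .net_run(engine$ptr, n_steps, opts)
  list(
    spikes = data.frame(unit = out$spike_unit, time = out$spike_step * h),
    lfp = out$lfp,
    emg = out$emg / 1000,
    v = out$v,
    filt = out$filt,
    triggers = out$trigger_step * h,
    stim_log = data.frame(time = out$stim_step * h, column = out$stim_col,
                          amplitude = out$stim_amp / 1000),
    truncated = out$truncated)
}

# Translate a closed-loop protocol_spec into the engine's internal form.
compile_protocol <- function(p, engine) {
  stopifnot(inherits(p, "protocol_spec"))
  h <- engine$sim$h
  variant <- switch(p$variant,
                    spike_triggered = 1L, spike_triggered_inhibition = 1L,
                    emg_triggered = 2L, cycle_triggered = 3L,
                    gamma_triggered = 4L,
                    stop("protocol '", p$variant,
                         "' is open-loop; pass it as a stimulus schedule"))
  if (variant == 1L) {
    u <- engine$network$units
    if (p$trigger_unit > nrow(u) || u$type[p$trigger_unit] == "m")
      stop("spike trigger unit does not exist or is not cortical")
    if (u$type[p$trigger_unit] != "e")
      warning("spike trigger unit is not excitatory")
  }
  filt_b <- 1; filt_a <- 1
  if (variant == 2L) {
    bf <- butter_band(p$emg_band, h)
  } else if (variant >= 3L) {
    bf <- butter_band(p$band, h)
  }
  if (variant >= 2L) { filt_b <- bf$b; filt_a <- bf$a }
  freq <- 20
  if (!is.null(engine$envelope)) freq <- engine$envelope$spec$frequency
  ph <- phase_to_crossing(p$phase, period = 1000 / freq)
  threshold <- if (!is.null(p$threshold_value)) p$threshold_value else 0
  level <- if (!is.null(p$level_value)) p$level_value else 0
  if (variant %in% c(2L, 4L) && is.null(p$threshold_value))
    stop("EMG/gamma protocols need a calibrated `threshold_value` ",
         "(see calibrate_trigger_threshold)")
  if (variant == 3L && is.null(p$level_value))
    stop("cycle-triggered protocols need an episode arming `level_value`")
  edge <- if (p$variant == "gamma_triggered") -1L else 1L
  if (!is.null(p$edge)) edge <- if (identical(p$edge, "falling")) -1L else 1L
  list(variant = variant,
       trigger_unit = as.integer(p$trigger_unit),
       source_col = as.integer(p$trigger_column),
       target_col = as.integer(p$target_column),
       delay_steps = as.integer(round(p$delay / h)),
       amp_uv = p$amplitude * 1000,
       train_n = as.integer(p$train_pulses),
       train_interval_steps = as.integer(round(p$train_interval / h)),
       lockout_steps = as.integer(round(p$lockout / h)),
       threshold = threshold,
       edge = edge,
       level = level,
       cross_type = if (ph$cross == "rising") 0L else 1L,
       phase_steps = as.integer(round(ph$extra_ms / h)),
       filt_b = as.numeric(filt_b), filt_a = as.numeric(filt_a))
}

#' Read or replace the engine's connection weights
#'
#' Weights are returned in the edge order of the network the engine was
#' compiled from. `engine_set_weights` enforces sign preservation, so a
#' snapshot from a matched run (e.g. an intact twin of a lesioned network)
#' can be restored exactly.
#'
#' @param engine A [compile_network()] handle.
#' @param w Replacement weight vector.
#' @return `engine_weights`: numeric vector of weights.
#' @export
engine_weights <- function(engine) .net_get_weights(engine$ptr)

#' @rdname engine_weights
#' @export
engine_set_weights <- function(engine, w) {
  .net_set_weights(engine$ptr, w)
  invisible(engine)
}

#' Internal engine state snapshot
#'
#' Potentials and plasticity traces, mainly for diagnostics and tests.
#'
#' @param engine A [compile_network()] handle.
#' @return A list of state vectors.
#' @export
engine_state <- function(engine) .net_state(engine$ptr)
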