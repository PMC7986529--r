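#' Run a full conditioning experiment
#'
#' Executes the standard four-period schedule: preconditioning (plasticity
#' on, no stimulation, the network settles to its unconditioned steady
#' state), preconditioning testing (plasticity off, test pulses measure
#' baseline evoked potentials), conditioning (plasticity on, the protocol
#' active), and postconditioning testing (plasticity off). Threshold-based
#' protocols (EMG, gamma) are calibrated on signals recorded during the
#' preconditioning test period; cycle-triggered runs get their episode
#' arming level from the same window.
#'
#' A single master seed drives independent substreams for topology,
#' each period, and calibration, so e.g. intact and lesioned twins built
#' from the same seed share every common connection.
#'
#' @param protocol A [protocol_spec()], a preset name for
#'   [protocol_preset()], or NULL for an unconditioned control run.
#' @param seed Master seed.
#' @param periods Length of the four periods (s); a scalar is recycled.
#' @param topology,sim,plast,bias Parameter objects; see
#'   [topology_spec()], [sim_params()], [plasticity_params()],
#'   [bias_config()].
#' @param envelope Optional bias envelope (defaults to 20-Hz episodes on
#'   column B for cycle-triggered protocols).
#' @param network Optionally a pre-built [build_network()] object (e.g. a
#'   lesioned twin); otherwise built from `topology` and the seed.
#' @param test_interval Time between successive tests of the same directed column pair (s); one column is stimulated every `test_interval`/3.
#' @param test_amplitude Test stimulus amplitude (mV).
#' @param snapshot_blocks Record mean A->B strength at every block boundary
#'   of the conditioning period.
#' @param record_conditioning Additionally record spikes during
#'   conditioning (for trigger-aligned histograms).
#' @return A `conditioning_result`: pre/post EP matrices (uV; rows =
#'   test-stimulated column, columns = recorded column), the EP increase
#'   matrix (%), weight snapshots, trigger/stimulus counts, and a manifest.
#' @export
#' @examples
#' \donttest{
#' res <- run_conditioning("spike_triggered", seed = 1, periods = 20)
#' res$ep_increase["A", "B"]
#' }
run_conditioning <- function(protocol = NULL, seed = 1, periods = 500,
                             topology = topology_spec(),
                             sim = sim_params(),
                             plast = plasticity_params(sim = sim),
                             bias = bias_config(),
                             envelope = NULL, network = NULL,
                             test_interval = 1.2, test_amplitude = 3,
                             snapshot_blocks = FALSE,
                             record_conditioning = FALSE) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  periods <- rep_len(periods, 4)
  if (!is.null(protocol) && !is.null(protocol[["overrides"]])) {
    ov <- protocol[["overrides"]]
    if (!is.null(ov$correlated_fraction))
      bias$correlated_fraction <- ov$correlated_fraction
    if (!is.null(ov$weakening)) plast$c <- ov$weakening
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 6)

  if (is.null(network)) {
    network <- build_network(topology, sim, plast, seed = seeds[1])
    if (!is.null(protocol[["lesion"]]))
      network <- lesion_connections(network, protocol[["lesion"]][1],
                                    protocol[["lesion"]][2])
  }
  if (is.null(envelope) && !is.null(protocol) &&
      protocol$variant == "cycle_triggered") {
    ep <- if (!is.null(protocol[["episode"]])) protocol[["episode"]] else
      episode_spec()
    envelope <- list(column = "B", spec = ep)
  }
  engine <- compile_network(network, bias = bias, envelope = envelope)
  w0 <- engine_weights(engine)

  closed_loop <- !is.null(protocol) && protocol$variant %in%
    c("spike_triggered", "spike_triggered_inhibition", "emg_triggered",
      "gamma_triggered", "cycle_triggered")

  # --- period 1: preconditioning settle ---
  set.seed(seeds[2])
  engine_run(engine, periods[1], plasticity = TRUE, record = character(0))
  w_pre <- engine_weights(engine)

  # --- period 2: preconditioning testing ---
  sched_pre <- test_schedule(periods[2], sim$block_length,
                             cycle = identical(protocol$variant,
                                               "cycle_triggered"),
                             interval = test_interval,
                             amplitude = test_amplitude)
  need_emg <- identical(protocol$variant, "emg_triggered")
  set.seed(seeds[3])
  rec_pre <- engine_run(engine, periods[2], plasticity = FALSE,
                        stim = sched_pre,
                        record = c("lfp", if (need_emg) "emg"))
  pre_ep <- ep_matrix(rec_pre$lfp, sched_pre, sim$h)

  # --- calibration for threshold-based protocols ---
  protocol <- calibrate_protocol(protocol, rec_pre, engine)

  # --- period 3: conditioning ---
  set.seed(seeds[4])
  stim_cond <- NULL
  if (!is.null(protocol) && protocol$variant == "tetanic") {
    stim_cond <- data.frame(
      time = schedule_tetanic(periods[3], protocol$rate,
                              protocol$refractory),
      column = protocol$target_column, amplitude = protocol$amplitude)
  } else if (!is.null(protocol) && protocol$variant == "paired_pulse") {
    stim_cond <- paired_pulse_schedule(periods[3], protocol)
  }
  snapshots <- NULL
  rec_cond <- NULL
  if (snapshot_blocks) {
    nb <- ceiling(periods[3] / sim$block_length)
    snapshots <- data.frame(block = seq_len(nb), mean_AB = NA_real_)
    trig_n <- 0; stim_n <- 0
    for (b in seq_len(nb)) {
      len <- min(sim$block_length, periods[3] - (b - 1) * sim$block_length)
      off <- (b - 1) * sim$block_length * 1000
      sb <- NULL
      if (!is.null(stim_cond)) {
        sel <- stim_cond$time >= off & stim_cond$time < off + len * 1000
        sb <- stim_cond[sel, ]; sb$time <- sb$time - off
      }
      r <- engine_run(engine, len, plasticity = TRUE,
                      protocol = if (closed_loop) protocol,
                      stim = sb, record = character(0))
      trig_n <- trig_n + length(r$triggers)
      stim_n <- stim_n + nrow(r$stim_log)
      snapshots$mean_AB[b] <-
        weight_summaries(network, engine_weights(engine))["A", "B"]
    }
    rec_cond <- list(triggers = numeric(trig_n), stim_log_n = stim_n)
    n_triggers <- trig_n; n_stim <- stim_n
  } else {
    rec_cond <- engine_run(engine, periods[3], plasticity = TRUE,
                           protocol = if (closed_loop) protocol,
                           stim = stim_cond,
                           record = if (record_conditioning) "spikes"
                                    else character(0))
    n_triggers <- length(rec_cond$triggers)
    n_stim <- nrow(rec_cond$stim_log)
  }
  w_cond <- engine_weights(engine)

  # --- period 4: postconditioning testing ---
  sched_post <- sched_pre
  set.seed(seeds[5])
  rec_post <- engine_run(engine, periods[4], plasticity = FALSE,
                         stim = sched_post, record = "lfp")
  post_ep <- ep_matrix(rec_post$lfp, sched_post, sim$h)

  ep_inc <- ep_increase_percent(pre_ep, post_ep)

  structure(list(
    pre_ep = pre_ep, post_ep = post_ep, ep_increase = ep_inc,
    weights_initial = w0, weights_settled = w_pre,
    weights_conditioned = w_cond,
    strength_settled = weight_summaries(network, w_pre),
    strength_conditioned = weight_summaries(network, w_cond),
    snapshots = snapshots,
    n_triggers = n_triggers, n_stimuli = n_stim,
    conditioning = if (record_conditioning) rec_cond,
    protocol = protocol, network = network, engine = engine,
    manifest = list(seed = seed, substream_seeds = seeds,
                    periods = periods, h = sim$h,
                    n_triggers = n_triggers, n_stimuli = n_stim,
                    variant = if (is.null(protocol)) "none"
                              else protocol$variant)),
    class = "conditioning_result")
}

#' @export
print.conditioning_result <- function(x, ...) {
  cat("conditioning_result:",
      if (is.null(x$protocol)) "no conditioning" else x$protocol$variant,
      "\n  triggers:", x$n_triggers, " stimuli:", x$n_stimuli, "\n")
  cat("  EP increase (%) [test-stimulated -> recorded]:\n")
  print(round(x$ep_increase, 1))
  invisible(x)
}

# Test-stimulus schedule for a testing period. Standard runs test one
# column every `interval`/3 seconds, rotating A, B, C, so each directed
# pair is probed every `interval` seconds. Cycle-triggered runs instead
# use fixed per-block times chosen to fall outside the oscillatory
# episodes (10 per block, rotating columns).
test_schedule <- function(duration, block_s = 10, cycle = FALSE,
                          interval = 2, amplitude = 3) {
  if (cycle) {
    offs <- c(1.8, 2.3, 2.8, 3.3, 4.3, 4.8, 5.3, 5.8,
              6.8, 7.3, 7.8, 8.3, 9.3, 9.8) * block_s / 10
    nb <- floor(duration / block_s)
    times <- sort(as.numeric(outer(offs, (seq_len(nb) - 1) * block_s, "+")))
  } else {
    times <- seq(interval / 4, duration - 0.1, by = interval / 3)
  }
  data.frame(time = times * 1000,
             column = rep_len(1:3, length(times)),
             amplitude = amplitude)
}

# Mean EP matrix (stimulated column x recorded column) from a testing-period
# LFP recording and its stimulus schedule.
ep_matrix <- function(lfp, sched, h) {
  m <- matrix(NA_real_, 3, 3, dimnames = list(COLUMNS, COLUMNS))
  for (sc in 1:3) {
    st <- sched$time[sched$column == sc]
    if (!length(st)) next
    for (rc in setdiff(1:3, sc)) {
      m[sc, rc] <- measure_ep(lfp[, rc], st, h)$ep
    }
  }
  m
}

# Calibrate thresholds/arming levels from the preconditioning test
# recordings.
calibrate_protocol <- function(protocol, rec, engine) {
  if (is.null(protocol)) return(NULL)
  h <- engine$sim$h
  if (protocol$variant == "emg_triggered") {
    bf <- butter_band(protocol$emg_band, h)
    sig <- as.numeric(signal::filter(bf, rec$emg[, protocol$trigger_column]))
    protocol$threshold_value <- calibrate_trigger_threshold(
      sig, h, target_rate = protocol$target_rate, edge = "rising",
      lockout = protocol$lockout)
  } else if (protocol$variant == "gamma_triggered") {
    bf <- butter_band(protocol$band, h)
    sig <- as.numeric(signal::filter(bf, rec$lfp[, protocol$trigger_column]))
    edge <- if (identical(protocol$edge, "rising")) "rising" else "falling"
    protocol$threshold_value <- calibrate_trigger_threshold(
      sig, h, target_rate = protocol$target_rate, edge = edge,
      lockout = protocol$lockout)
  } else if (protocol$variant == "cycle_triggered") {
    src <- if (!is.null(engine$envelope))
      column_index(engine$envelope$column) else 2L
    bf <- butter_band(protocol$band, h)
    sig <- as.numeric(signal::filter(bf, rec$lfp[, src]))
    protocol$level_value <- protocol$episode_level_sd * stats::sd(sig)
    protocol$trigger_column <- src
  }
  protocol
}

#' Track mean connection strength across blocks
#'
#' Advances the engine block by block and records the mean strength of a
#' directed column pair after each block, e.g. to watch conditioned weights
#' build up and decay.
#'
#' @param engine A [compile_network()] handle.
#' @param duration Total time (s).
#' @param from,to Column pair to summarize.
#' @param block Block length (s).
#' @param plasticity,protocol,stim Passed to [engine_run()] per block
#'   (`stim` times are absolute over `duration`).
#' @return data.frame `time` (s, block end), `mean_strength` (uV).
#' @export
track_weights <- function(engine, duration, from = "A", to = "B",
                          block = NULL, plasticity = TRUE, protocol = NULL,
                          stim = NULL) {
  if (is.null(block)) block <- engine$sim$block_length
  nb <- ceiling(duration / block)
  out <- data.frame(time = numeric(nb), mean_strength = numeric(nb))
  fi <- column_index(from); ti <- column_index(to)
  for (b in seq_len(nb)) {
    len <- min(block, duration - (b - 1) * block)
    off <- (b - 1) * block * 1000
    sb <- NULL
    if (!is.null(stim)) {
      sel <- stim$time >= off & stim$time < off + len * 1000
      if (any(sel)) { sb <- stim[sel, ]; sb$time <- sb$time - off }
    }
    engine_run(engine, len, plasticity = plasticity, protocol = protocol,
               stim = sb, record = character(0))
    out$time[b] <- (b - 1) * block + len
    out$mean_strength[b] <- weight_summaries(
      engine$network, engine_weights(engine))[fi, ti]
  }
  out
}

#' Write a run manifest as JSON
#'
#' @param result A [run_conditioning()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
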