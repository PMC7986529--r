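#' Sweep the stimulation phase of cycle-triggered conditioning
#'
#' Repeats cycle-triggered conditioning at a series of stimulation phases
#' and measures the A->B and B->A evoked-potential changes at each phase.
#' Within one seed the network is built, settled, and baseline-tested once;
#' every phase then conditions from the same settled weight state, so the
#' phase comparison is matched exactly. The phase tuning of the A->B
#' increase peaks near the phase at which stimulated column-A volleys reach
#' column B just before the oscillatory depolarization fires the B units.
#'
#' @param phases Stimulation phases to test (degrees).
#' @param seeds One master seed per replicate network.
#' @param periods Length of the settle / baseline-test / conditioning /
#'   post-test segments (s); scalar or length 4.
#' @param topology,sim,plast,bias Parameter objects.
#' @param episode Episode specification for the column-B bias envelope.
#' @param amplitude Conditioning stimulus amplitude (mV).
#' @param progress Print one line per completed seed.
#' @return A data.frame with one row per (seed, phase): the pre and post
#'   EPs and the percent EP increase for A->B and B->A.
#' @export
cycle_phase_sweep <- function(phases = seq(-180, 165, by = 15),
                              seeds = 1:3, periods = 100,
                              topology = topology_spec(),
                              sim = sim_params(),
                              plast = plasticity_params(sim = sim),
                              bias = bias_config(),
                              episode = episode_spec(),
                              amplitude = 2, progress = FALSE) {
  periods <- rep_len(periods, 4)
  out <- NULL
  for (seed in seeds) {
    set.seed(seed)
    sub <- sample.int(.Machine$integer.max - 1, 4 + length(phases))
    network <- build_network(topology, sim, plast, seed = sub[1])
    engine <- compile_network(network, bias = bias,
                              envelope = list(column = "B", spec = episode))
    set.seed(sub[2])
    engine_run(engine, periods[1], plasticity = TRUE, record = character(0))
    w_settled <- engine_weights(engine)

    sched <- test_schedule(periods[2], sim$block_length, cycle = TRUE)
    set.seed(sub[3])
    rec_pre <- engine_run(engine, periods[2], plasticity = FALSE,
                          stim = sched, record = "lfp")
    pre <- ep_matrix(rec_pre$lfp, sched, sim$h)
    bf <- butter_band(c(15, 25), sim$h)
    level <- 2 * stats::sd(as.numeric(signal::filter(bf, rec_pre$lfp[, 2])))

    for (i in seq_along(phases)) {
      proto <- protocol_spec("cycle_triggered", phase = phases[i],
                             amplitude = amplitude)
      proto$level_value <- level
      engine_set_weights(engine, w_settled)
      set.seed(sub[4 + i])
      engine_run(engine, periods[3], plasticity = TRUE, protocol = proto,
                 record = character(0))
      rec_post <- engine_run(engine, periods[4], plasticity = FALSE,
                             stim = sched, record = "lfp")
      post <- ep_matrix(rec_post$lfp, sched, sim$h)
      out <- rbind(out, data.frame(
        seed = seed, phase = phases[i],
        pre_AB = pre["A", "B"], post_AB = post["A", "B"],
        inc_AB = ep_increase_percent(pre["A", "B"], post["A", "B"]),
        pre_BA = pre["B", "A"], post_BA = post["B", "A"],
        inc_BA = ep_increase_percent(pre["B", "A"], post["B", "A"])))
    }
    if (progress)
      message("seed ", seed, " done (", length(phases), " phases)")
  }
  rownames(out) <- NULL
  out
}

#' Optimal phases from a phase sweep
#'
#' Averages the EP increases over seeds and returns the phase maximizing
#' each direction.
#'
#' @param sweep A [cycle_phase_sweep()] result.
#' @return A list with `best_AB`, `best_BA` (degrees) and the per-phase
#'   mean curves.
#' @export
phase_sweep_optimum <- function(sweep) {
  agg <- stats::aggregate(sweep[c("inc_AB", "inc_BA")],
                          by = list(phase = sweep$phase), FUN = mean)
  # phases are circular; report the canonical representative in (-180, 180]
  canon <- function(p) {
    p <- ((p + 180) %% 360) - 180
    if (p == -180) 180 else p
  }
  list(best_AB = canon(agg$phase[which.max(agg$inc_AB)]),
       best_BA = canon(agg$phase[which.max(agg$inc_BA)]),
       curves = agg)
}
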