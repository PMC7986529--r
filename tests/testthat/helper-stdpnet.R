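# Miniature hand-built networks for engine-level oracle tests.

# A spiking_network with explicitly given cortical units and edges.
# thresholds in mV; "passive" units get an unreachably high threshold.
manual_network <- function(n_units = 2, edges = NULL,
                           thresholds = rep(1e6, n_units),
                           sim = sim_params(),
                           plast = plasticity_params(sim = sim)) {
  units <- data.frame(id = seq_len(n_units), column = 1L,
                      type = "e", threshold = thresholds, muap = 0,
                      stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(src = integer(0), dst = integer(0),
                        weight = numeric(0), plastic = logical(0))
  structure(list(units = units, edges = edges, spec = NULL, sim = sim,
                 plast = plast, seed = NA,
                 correlated_bias_removed = FALSE),
            class = "spiking_network")
}

# Engine over a manual network with all external drive silenced.
quiet_engine <- function(network, ...) {
  compile_network(network,
                  bias = bias_config(total_rate = 0),
                  motor_drive_rate = 0, ...)
}

# Plasticity parameters with effectively unbounded weights, so clipping
# never interferes with oracle comparisons.
open_plast <- function(sim = sim_params(), ...) {
  plasticity_params(w_min = 1e-9, max_strength = 1e9, sim = sim, ...)
}

# Euler-discretized PSP kernel value k steps after arrival (k >= 0),
# per unit weight: ds^k - df^k with ds = 1 - h/tau_s etc.
euler_kernel <- function(k, sim = sim_params()) {
  ds <- 1 - sim$h / sim$tau_s
  df <- 1 - sim$h / sim$tau_f
  ds^k - df^k
}

# V trace predicted by superposing Euler kernels for spikes of a source
# unit at the given times (ms), through one connection of weight w,
# arriving after the cortical conduction delay. Returns the trace sampled
# like engine_run()$v (state after each step's update).
superposed_v <- function(spike_times, w, n_steps, sim = sim_params()) {
  h <- sim$h
  arr <- round(spike_times / h) + round(sim$d_cortical / h)
  v <- numeric(n_steps)
  for (a in arr) {
    k <- seq(0, n_steps - 1 - a)
    if (length(k)) v[a + 1 + k] <- v[a + 1 + k] + w * euler_kernel(k, sim)
  }
  v
}

forced_df <- function(times, unit) data.frame(time = times, unit = unit)
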