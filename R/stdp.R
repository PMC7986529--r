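#' Spike-timing-dependent plasticity curve
#'
#' Weight change for a single (presynaptic arrival, postsynaptic spike) pair
#' separated by `delta_t` = post spike time minus presynaptic arrival time
#' (ms). Positive intervals potentiate, negative intervals depress; both
#' sides are differences of exponentials and the curve is zero at
#' `delta_t = 0`. The same curve applies to excitatory and inhibitory
#' connections (it scales the weight magnitude; signs never flip).
#'
#' @param delta_t Numeric vector of intervals (ms).
#' @param params A [plasticity_params()] object.
#' @return Weight changes (weight units), same length as `delta_t`.
#' @export
stdp_curve <- function(delta_t, params = plasticity_params()) {
  stopifnot(is.numeric(delta_t), all(is.finite(delta_t)))
  out <- numeric(length(delta_t))
  pos <- delta_t >= 0
  out[pos] <- params$r *
    (exp(-delta_t[pos] / params$a_s) - exp(-delta_t[pos] / params$a_f))
  out[!pos] <- -params$c * params$r *
    (exp(delta_t[!pos] / params$b_s) - exp(delta_t[!pos] / params$b_f))
  out
}

#' Areas under the two sides of the STDP curve
#'
#' Analytic integrals: potentiation area `r (a_s - a_f)` and depression area
#' `c r (b_s - b_f)`. With default parameters depression has the larger
#' area, which drives unconditioned weights toward the floor.
#'
#' @inheritParams stdp_curve
#' @return Named numeric vector `c(strengthening, weakening)`.
#' @export
stdp_areas <- function(params = plasticity_params()) {
  c(strengthening = params$r * (params$a_s - params$a_f),
    weakening = params$c * params$r * (params$b_s - params$b_f))
}

#' Clip a weight to its allowed band
#'
#' Excitatory weights live in `[w_min, w_max]`, inhibitory weights in
#' `[-w_max, -w_min]`. The floor at `w_min > 0` means no update sequence can
#' flip a connection's sign.
#'
#' @param w Weights to clip.
#' @param sign `+1` for excitatory, `-1` for inhibitory (scalar or vector).
#' @inheritParams stdp_curve
#' @return Clipped weights.
#' @export
clip_weight <- function(w, sign, params = plasticity_params()) {
  if (any(sign == 0)) stop("connection sign must be +1 or -1, never 0")
  stopifnot(all(sign %in% c(-1, 1)))
  pmin(pmax(w * sign, params$w_min), params$w_max) * sign
}

#' Pairwise STDP oracle: brute-force sum over spike pairs
#'
#' Reference computation of the total weight change on one connection from
#' explicit presynaptic and postsynaptic spike times, summing
#' [stdp_curve()] over every (post spike, pre arrival) pair. Pre spikes
#' arrive at the target `d_cortical` ms after they are fired. Used to
#' validate the engine's trace-based incremental updates; the engine's
#' Euler-discretized traces converge to this sum as `h` decreases.
#'
#' @param pre_times,post_times Spike times (ms) of source and target unit.
#' @param params A [plasticity_params()] object.
#' @param sim A [sim_params()] object (supplies the conduction delay).
#' @param sign Connection sign (+1 or -1).
#' @return Total weight change (weight units).
#' @export
stdp_pairwise_sum <- function(pre_times, post_times,
                              params = plasticity_params(),
                              sim = sim_params(), sign = 1) {
  if (!length(pre_times) || !length(post_times)) return(0)
  arrivals <- pre_times + sim$d_cortical
  dt <- outer(post_times, arrivals, "-")
  sign * sum(stdp_curve(as.numeric(dt), params))
}
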