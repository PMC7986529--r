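#' Simulation parameters for the integrate-and-fire engine
#'
#' Time constants and delays of the twin leaky-integrator unit model. Each
#' unit's potential is \eqn{V(t) = V^s(t) - V^f(t)}, where the slow and fast
#' accumulators decay with `tau_s` and `tau_f` and both receive the same
#' synaptic input, so one presynaptic spike evokes a PSP shaped as the
#' difference of two exponentials. A unit fires when `V` strictly exceeds
#' `theta` and both accumulators reset to zero on the next step.
#'
#' @param h Time step in ms. Restricted to the supported set
#'   0.1, 0.05, 0.025, 0.02, 0.01 unless `validate_h = FALSE`.
#' @param theta Cortical firing threshold (mV).
#' @param tau_s,tau_f Slow and fast PSP decay constants (ms); must satisfy
#'   `tau_s > tau_f > 0` and `h < tau_f` for Euler stability.
#' @param d_cortical Conduction delay between cortical units (ms).
#' @param d_motor Conduction delay from cortex to motoneurons (ms).
#' @param block_length Simulation block length (s).
#' @param validate_h Set `FALSE` to allow non-standard step sizes.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' sp <- sim_params()
#' psp_peak_factor(sp)
sim_params <- function(h = 0.1, theta = 5, tau_s = 3.2, tau_f = 0.8,
                       d_cortical = 3, d_motor = 10, block_length = 10,
                       validate_h = TRUE) {
  stopifnot(h > 0, tau_s > tau_f, tau_f > 0, theta > 0,
            d_cortical >= 0, d_motor >= 0, block_length > 0)
  if (h >= tau_f)
    stop("h must be smaller than tau_f (Euler stability)")
  if (validate_h && !any(abs(h - c(0.1, 0.05, 0.025, 0.02, 0.01)) < 1e-12))
    stop("h must be one of 0.1, 0.05, 0.025, 0.02, 0.01 ms ",
         "(use validate_h = FALSE to override)")
  for (d in c(d_cortical, d_motor)) {
    k <- d / h
    if (abs(k - round(k)) > 1e-9)
      stop("delays must be integer multiples of h")
  }
  structure(list(h = h, theta = theta, tau_s = tau_s, tau_f = tau_f,
                 d_cortical = d_cortical, d_motor = d_motor,
                 block_length = block_length),
            class = "sim_params")
}

#' Peak of the PSP kernel
#'
#' The PSP evoked by one spike through a connection of weight `w` is
#' \eqn{w (e^{-t/\tau_s} - e^{-t/\tau_f})}. Its maximum occurs at
#' \eqn{t^* = \tau_s \tau_f / (\tau_s - \tau_f) \cdot \log(\tau_s/\tau_f)}
#' and has height \eqn{k^* w} with
#' \eqn{k^* = e^{-t^*/\tau_s} - e^{-t^*/\tau_f}}. The factor `k` converts
#' between the internal weight and the connection *strength* (PSP maximum in
#' microvolts), which is how connections are specified and reported.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `t_peak` (ms) and `k` (peak height per unit
#'   weight).
#' @export
psp_peak_factor <- function(params = sim_params()) {
  ts <- params$tau_s; tf <- params$tau_f
  if (ts <= tf) stop("degenerate PSP kernel: tau_s must exceed tau_f")
  t_peak <- ts * tf / (ts - tf) * log(ts / tf)
  k <- exp(-t_peak / ts) - exp(-t_peak / tf)
  list(t_peak = t_peak, k = k)
}

#' Plasticity (STDP) parameters
#'
#' The STDP curve is a difference of exponentials on each side: potentiation
#' `r (exp(-dt/a_s) - exp(-dt/a_f))` for a postsynaptic spike `dt >= 0` after
#' presynaptic arrival, and depression `-c r (exp(dt/b_s) - exp(dt/b_f))` for
#' `dt < 0`. With the defaults the depression side is shallower but wider,
#' with larger total area, which keeps unconditioned weights small.
#'
#' Weight bounds are specified as PSP strengths in microvolts and converted
#' to internal weight units through the continuous-time kernel peak factor
#' (see [psp_peak_factor()]), so they do not depend on the step size.
#'
#' @param r Training factor (scales both sides of the curve).
#' @param c Weakening factor (relative amplitude of the depression side).
#' @param a_s,a_f Potentiation-side decay constants (ms).
#' @param b_s,b_f Depression-side decay constants (ms).
#' @param w_min Minimum absolute weight (weight units).
#' @param max_strength Maximum connection strength (uV); `w_max` is
#'   `max_strength / k`.
#' @param squash Graded weight-change squashing near the bounds. Only the
#'   hard-clipping mode (`FALSE`) is implemented; the flag is accepted so
#'   configurations can state it explicitly.
#' @param sim [sim_params()] used for the strength/weight conversion.
#' @return An object of class `plasticity_params` with derived field `w_max`.
#' @export
#' @examples
#' pp <- plasticity_params()
#' pp$w_max                      # about 1058.3
#' stdp_curve(c(-10, 0, 10), pp) # about -40.36, 0, 51.56
plasticity_params <- function(r = 100, c = 0.55, a_s = 15.4, a_f = 2,
                              b_s = 33.3, b_f = 2, w_min = 1,
                              max_strength = 500, squash = FALSE,
                              sim = sim_params()) {
  stopifnot(r > 0, c >= 0, a_s > a_f, a_f > 0, b_s > b_f, b_f > 0,
            w_min > 0, max_strength > 0)
  if (isTRUE(squash))
    stop("graded weight-change squashing is not implemented; ",
         "only hard clipping is available")
  k <- psp_peak_factor(sim)$k
  w_max <- max_strength / k
  if (w_min >= w_max) stop("w_min must be smaller than w_max")
  structure(list(r = r, c = c, a_s = a_s, a_f = a_f, b_s = b_s, b_f = b_f,
                 w_min = w_min, w_max = w_max, max_strength = max_strength,
                 squash = FALSE, k = k),
            class = "plasticity_params")
}

#' Convert between connection weight and PSP strength
#'
#' Strength is the PSP maximum in microvolts produced by one spike through
#' the connection; it equals `|w| * k` with `k` from [psp_peak_factor()].
#'
#' @param w Signed or unsigned weights (weight units).
#' @param strength PSP maxima (uV).
#' @param params A [plasticity_params()] object (carries `k`).
#' @return `strength_from_weight`: strengths in uV; `weight_from_strength`:
#'   absolute weights.
#' @export
strength_from_weight <- function(w, params = plasticity_params()) {
  abs(w) * params$k
}

#' @rdname strength_from_weight
#' @export
weight_from_strength <- function(strength, params = plasticity_params()) {
  stopifnot(all(strength >= 0))
  strength / params$k
}
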