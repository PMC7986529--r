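#' External bias input configuration
#'
#' Each cortical unit receives excitatory background drive at `total_rate`
#' events/s, split into a correlated share (column-wide events, delivered to
#' every unit of the column at a Gaussian-jittered time) and an uncorrelated
#' share (independent per unit). All deliveries evoke the standard PSP
#' waveform with strength `event_strength`.
#'
#' @param total_rate Combined mean bias rate per unit (events/s).
#' @param correlated_fraction Fraction of the rate carried by correlated
#'   column events.
#' @param jitter_sd SD of the per-unit delivery jitter around each
#'   correlated column event (ms).
#' @param event_strength PSP maximum of one bias event (uV).
#' @return An object of class `bias_config`.
#' @export
bias_config <- function(total_rate = 1800, correlated_fraction = 0.30,
                        jitter_sd = 3, event_strength = 350) {
  stopifnot(total_rate >= 0, correlated_fraction >= 0,
            correlated_fraction <= 1, jitter_sd >= 0, event_strength > 0)
  structure(list(total_rate = total_rate,
                 correlated_fraction = correlated_fraction,
                 jitter_sd = jitter_sd, event_strength = event_strength),
            class = "bias_config")
}

#' Oscillatory episode specification
#'
#' Episodes of sinusoidal rate modulation of one column's bias input,
#' emulating spontaneous beta oscillations. Episodes recur at evenly spaced
#' onsets within each simulation block.
#'
#' @param frequency Oscillation frequency (Hz).
#' @param cycles Cycles per episode.
#' @param episodes_per_block Episodes per simulation block.
#' @param depth Modulation depth (fraction of the baseline rate; the
#'   multiplier is floored at zero).
#' @return An object of class `episode_spec`.
#' @export
episode_spec <- function(frequency = 20, cycles = 6,
                         episodes_per_block = 4, depth = 0.5) {
  stopifnot(frequency > 0, cycles >= 1, episodes_per_block >= 1)
  if (depth < 0) stop("modulation depth must be non-negative")
  structure(list(frequency = frequency, cycles = cycles,
                 episodes_per_block = episodes_per_block, depth = depth),
            class = "episode_spec")
}

#' Episode onset times within one block
#'
#' Onsets are evenly spaced: episode k of n starts at
#' `block_length * (2k - 1) / (2n)` seconds into the block.
#'
#' @param spec An [episode_spec()].
#' @param block_length Block length (s).
#' @return Onset times in seconds.
#' @export
episode_onsets <- function(spec, block_length = 10) {
  n <- spec$episodes_per_block
  block_length * (2 * seq_len(n) - 1) / (2 * n)
}

#' Rate-modulation envelope
#'
#' Multiplier applied to the bias event probabilities:
#' `1 + depth * sin(2 pi f (t - onset))` during an episode, 1 elsewhere,
#' floored at 0.
#'
#' @param spec An [episode_spec()].
#' @param t Times (s), interpreted modulo the block length.
#' @param block_length Block length (s).
#' @return Multipliers, same length as `t`.
#' @export
oscillatory_envelope <- function(spec, t, block_length = 10) {
  tb <- t %% block_length
  onsets <- episode_onsets(spec, block_length)
  dur <- spec$cycles / spec$frequency
  m <- rep(1, length(t))
  for (on in onsets) {
    inside <- tb >= on & tb < on + dur
    m[inside] <- pmax(0, 1 + spec$depth *
                        sin(2 * pi * spec$frequency * (tb[inside] - on)))
  }
  m
}

#' Generate an external bias event stream for one column
#'
#' Draws the correlated column events (Bernoulli per step at
#' `total_rate * correlated_fraction * h`), expands each into one jittered
#' delivery per unit, and draws uncorrelated deliveries independently per
#' unit. This is the same generative scheme the simulation engine runs
#' internally; the standalone version supports rate and jitter diagnostics.
#'
#' @param config A [bias_config()].
#' @param n_units Units in the column.
#' @param duration Window length (s).
#' @param h Time step (ms).
#' @return A list: `counts` (deliveries per unit), `rate_per_unit`
#'   (events/s), `corr_events` (column event times, ms), and `deliveries`, a
#'   data.frame of correlated deliveries (`event`, `unit`, `time` ms).
#' @export
#' @examples
#' set.seed(1)
#' s <- bias_event_stream(bias_config(), n_units = 80, duration = 2)
#' mean(s$rate_per_unit)  # close to 1800
bias_event_stream <- function(config, n_units = 80, duration = 20, h = 0.1) {
  stopifnot(n_units >= 1, duration > 0, h > 0)
  steps <- round(duration * 1000 / h)
  p_corr <- config$total_rate * config$correlated_fraction * h / 1000
  p_unc <- config$total_rate * (1 - config$correlated_fraction) * h / 1000
  if (p_corr > 1 || p_unc > 1)
    stop("event probability per step exceeds 1; reduce the rate or h")

  corr_steps <- which(stats::runif(steps) < p_corr)
  n_ev <- length(corr_steps)
  deliveries <- data.frame(event = integer(0), unit = integer(0),
                           time = numeric(0))
  if (n_ev > 0) {
    jit <- stats::rnorm(n_ev * n_units, 0, config$jitter_sd)
    jit <- pmin(pmax(jit, -4 * config$jitter_sd), 4 * config$jitter_sd)
    deliveries <- data.frame(
      event = rep(seq_len(n_ev), each = n_units),
      unit = rep(seq_len(n_units), times = n_ev),
      time = rep((corr_steps - 1) * h, each = n_units) +
        round(jit / h) * h)
  }
  counts_corr <- tabulate(deliveries$unit, nbins = n_units)
  counts_unc <- stats::rbinom(n_units, steps, p_unc)
  counts <- counts_corr + counts_unc
  list(counts = counts,
       rate_per_unit = counts / duration,
       corr_events = (corr_steps - 1) * h,
       deliveries = deliveries)
}
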