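#' Reconstruct an LFP from a PSP delivery log
#'
#' The simulated local field potential of a column is the superposition of
#' all PSPs arriving at the column's cortical units. Given a log of
#' deliveries (arrival time and signed strength), this rebuilds the trace
#' with the same Euler-discretized difference-of-exponentials kernel the
#' engine integrates, so it serves as an exact reference for the engine's
#' online LFP and for small hand-built examples.
#'
#' @param times Delivery (arrival) times, ms.
#' @param strengths Signed PSP maxima, uV.
#' @param duration Trace length, ms.
#' @param sim A [sim_params()].
#' @param plast A [plasticity_params()] (for the strength-to-weight factor).
#' @return Numeric LFP trace sampled at `sim$h`, in uV.
#' @export
#' @examples
#' lfp <- compute_lfp(5, 350, 30)
#' max(lfp)  # close to 350
compute_lfp <- function(times, strengths, duration, sim = sim_params(),
                        plast = plasticity_params(sim = sim)) {
  stopifnot(length(times) == length(strengths) || length(strengths) == 1)
  h <- sim$h
  n <- round(duration / h)
  x <- numeric(n)
  idx <- floor(times / h) + 1
  ok <- idx >= 1 & idx <= n
  w <- rep_len(strengths, length(times)) / plast$k
  for (i in which(ok)) x[idx[i]] <- x[idx[i]] + w[i]
  s <- stats::filter(x, 1 - h / sim$tau_s, method = "recursive")
  f <- stats::filter(x, 1 - h / sim$tau_f, method = "recursive")
  as.numeric(s - f)
}

#' Measure evoked potentials around test stimuli
#'
#' The EP for one test stimulus is the signed extremum of the LFP in the
#' post-stimulus peak window minus the mean LFP over the pre-stimulus
#' baseline window. "Signed extremum" is the sample with the largest
#' absolute deviation from the baseline mean, so inhibition-dominated
#' responses measure negative.
#'
#' The average EP is obtained by first averaging the stimulus-aligned LFP
#' segments over all test stimuli (each segment baseline-subtracted), then
#' taking the extremum of the averaged trace. Averaging before the peak
#' pick is essential: single-trial LFP fluctuations from the correlated
#' background drive are far larger than a typical EP.
#'
#' @param lfp LFP trace on the step grid (uV).
#' @param stim_times Test stimulus times (ms).
#' @param h Sampling step (ms).
#' @param baseline Baseline window relative to the stimulus (ms), used for
#'   the mean.
#' @param peak Peak-search window relative to the stimulus (ms); the default
#'   starts just past the cortical conduction delay.
#' @return A list with `ep` (average EP amplitude, uV), `n` (stimuli
#'   averaged), and `trace` (the averaged, baseline-subtracted LFP from
#'   `baseline[1]` to `peak[2]` ms around the stimulus).
#' @export
measure_ep <- function(lfp, stim_times, h, baseline = c(-20, 0),
                       peak = c(3, 18)) {
  stopifnot(baseline[1] < baseline[2], peak[1] < peak[2])
  if (baseline[2] > peak[1])
    stop("baseline and peak windows overlap")
  n <- length(lfp)
  o1 <- ceiling(baseline[1] / h); o2 <- floor(peak[2] / h)
  rel <- o1:o2
  acc <- numeric(length(rel)); m <- 0
  for (tst in stim_times) {
    s <- round(tst / h) + 1
    if (s + o1 < 1 || s + o2 > n) next
    seg <- lfp[s + rel]
    base <- mean(seg[rel >= ceiling(baseline[1] / h) &
                     rel < floor(baseline[2] / h)])
    acc <- acc + (seg - base)
    m <- m + 1
  }
  if (m == 0) return(list(ep = NA_real_, n = 0, trace = NULL))
  avg <- acc / m
  win <- rel > floor(peak[1] / h) & rel <= o2
  seg <- avg[win]
  list(ep = seg[which.max(abs(seg))], n = m,
       trace = data.frame(t = rel * h, lfp = avg))
}

#' Percent change of the average evoked potential
#'
#' `100 * (post - pre) / pre`. Undefined (NA with a warning) when the
#' preconditioning mean is zero.
#'
#' @param pre,post Mean EP amplitudes before and after conditioning.
#' @return Percent increase.
#' @export
ep_increase_percent <- function(pre, post) {
  out <- 100 * (post - pre) / pre
  if (any(pre == 0, na.rm = TRUE)) {
    warning("preconditioning mean EP is zero; increase undefined")
    out[pre == 0] <- NA_real_
  }
  out
}

#' Synthesize multiunit EMG from motoneuron spikes
#'
#' Each motoneuron spike contributes a muscle-unit potential with the
#' standard difference-of-exponentials shape scaled to that unit's
#' amplitude; the multiunit EMG is their superposition, optionally
#' band-pass filtered (zero-phase, for offline analysis).
#'
#' @param spike_times Motoneuron spike times (ms).
#' @param amplitudes Per-spike muscle unit potential amplitudes (mV).
#' @param duration Trace length (ms).
#' @param sim A [sim_params()].
#' @param band Band-pass edges (Hz), or NULL for the raw trace only.
#' @return A list with `raw` and `filtered` traces (mV) on the step grid.
#' @export
synthesize_emg <- function(spike_times, amplitudes, duration,
                           sim = sim_params(), band = c(100, 2500)) {
  raw <- compute_lfp(spike_times, amplitudes * 1000, duration, sim) / 1000
  filtered <- NULL
  if (!is.null(band)) {
    bf <- butter_band(band, sim$h)
    filtered <- as.numeric(signal::filtfilt(bf, raw))
  }
  list(raw = raw, filtered = filtered)
}

#' Trigger-aligned population firing histogram
#'
#' Counts population spikes in bins around each trigger and normalizes to a
#' firing rate per unit.
#'
#' @param spike_times Spike times (ms) of the population.
#' @param trigger_times Trigger times (ms).
#' @param window Alignment window around each trigger (ms).
#' @param bin Bin width (ms).
#' @param n_units Number of units in the population (for the rate scale).
#' @return A data.frame with `t` (bin centers, ms), `count`, and `rate`
#'   (spikes/s per unit).
#' @export
trigger_aligned_histogram <- function(spike_times, trigger_times,
                                      window = c(-50, 50), bin = 1,
                                      n_units = 1) {
  breaks <- seq(window[1], window[2], by = bin)
  centers <- breaks[-1] - bin / 2
  counts <- numeric(length(centers))
  if (length(trigger_times)) {
    st <- sort(spike_times)
    for (tr in trigger_times) {
      rel <- st[st >= tr + window[1] & st < tr + window[2]] - tr
      if (length(rel))
        counts <- counts + graphics::hist(rel, breaks = breaks,
                                          right = FALSE,
                                          plot = FALSE)$counts
    }
  }
  rate <- counts / max(length(trigger_times), 1) / n_units / (bin / 1000)
  data.frame(t = centers, count = counts, rate = rate)
}

#' Mean intercolumn connection strengths
#'
#' Summarizes a weight state as mean PSP strengths (uV) between columns.
#' By default only cortical connections from excitatory sources enter, the
#' quantity the conditioning protocols target; set `sources` to include
#' inhibitory ones.
#'
#' @param network A [build_network()] result.
#' @param weights Edge weight vector (defaults to the weights stored in the
#'   network; pass a snapshot from [engine_weights()] to summarize a run).
#' @param sources `"e"`, `"i"`, or `c("e", "i")`.
#' @return A 3x3 matrix (rows = source column, cols = target column) of
#'   mean signed strengths in uV (inhibitory sources contribute
#'   negatively).
#' @export
weight_summaries <- function(network, weights = NULL, sources = "e") {
  e <- network$edges
  if (is.null(weights)) weights <- e$weight
  stopifnot(length(weights) == nrow(e))
  u <- network$units
  cortical <- u$type != "m"
  keep <- cortical[e$src] & cortical[e$dst] & u$type[e$src] %in% sources
  m <- matrix(NA_real_, 3, 3, dimnames = list(COLUMNS, COLUMNS))
  s <- weights * network$plast$k  # signed strength (uV)
  for (a in 1:3) for (b in 1:3) {
    sel <- keep & u$column[e$src] == a & u$column[e$dst] == b
    if (any(sel)) m[a, b] <- mean(s[sel])
  }
  m
}
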