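test_that("LFP reconstruction reproduces single-PSP kernels", {
  sim <- sim_params()
  lfp <- compute_lfp(5, 350, 40, sim)
  # peak close to the nominal 350-uV strength, at the kernel peak time
  # forward-Euler integration overshoots the continuous peak by ~3% at
  # h = 0.1 ms
  expect_equal(max(lfp), 350, tolerance = 0.035)
  expect_equal((which.max(lfp) - 1) * sim$h - 5,
               psp_peak_factor(sim)$t_peak, tolerance = 0.1)
  expect_true(all(lfp[seq_len(50)] == 0))
  # inhibitory PSP deflects negative; superposition is linear
  expect_equal(compute_lfp(5, -350, 40, sim), -lfp, tolerance = 1e-12)
  both <- compute_lfp(c(5, 5), c(350, -350), 40, sim)
  expect_true(all(abs(both) < 1e-9))
  expect_identical(compute_lfp(numeric(0), numeric(0), 10, sim),
                   rep(0, 100))
})

test_that("engine LFP equals the delivery-log reconstruction", {
  # one spike of a source unit; the column LFP must be the PSP kernel
  sim <- sim_params()
  net <- manual_network(
    2, edges = data.frame(src = 1, dst = 2, weight = 200, plastic = FALSE),
    sim = sim)
  eng <- quiet_engine(net)
  r <- engine_run(eng, 0.05, forced = forced_df(2, 1), record = "lfp")
  pp <- plasticity_params(sim = sim)
  ref <- compute_lfp(2 + sim$d_cortical, strength_from_weight(200, pp),
                     50, sim)
  expect_equal(r$lfp[, 1], ref, tolerance = 1e-10)
})

test_that("EP measurement recovers amplitude and sign on known traces", {
  h <- 0.1
  flat <- rep(0, 5000)
  expect_equal(measure_ep(flat, c(100, 200), h)$ep, 0)
  # synthetic EP: kernel riding on a DC offset
  lfp <- 50 + compute_lfp(c(105, 205), c(120, 120), 500)
  m <- measure_ep(lfp, c(100, 200), h)
  expect_equal(m$n, 2L)
  expect_equal(m$ep, 120, tolerance = 0.04)
  # negative deflections give negative EPs
  mneg <- measure_ep(50 + compute_lfp(105, -120, 500), 100, h)
  expect_equal(mneg$ep, -120, tolerance = 0.04)
  expect_error(measure_ep(flat, 100, h, baseline = c(-20, 5)), "overlap")
})

test_that("EP percent change follows the defining arithmetic", {
  expect_equal(ep_increase_percent(100, 250), 150)
  expect_equal(ep_increase_percent(100, 80), -20)
  expect_equal(ep_increase_percent(150, 150), 0)
  expect_warning(out <- ep_increase_percent(0, 10), "zero")
  expect_true(is.na(out))
  # antisymmetry: swapping pre/post maps x% to -100x/(100+x)%
  x <- ep_increase_percent(120, 300)
  y <- ep_increase_percent(300, 120)
  expect_equal(y, -100 * x / (100 + x))
})

test_that("EMG synthesis applies the size principle and removes DC", {
  sim <- sim_params()
  e <- synthesize_emg(c(10, 100), c(1.5, 0.5), 300, sim)
  expect_equal(max(e$raw), 1.5, tolerance = 0.04)
  seg <- e$raw[round(100 / sim$h):round(140 / sim$h)]
  expect_equal(max(seg), 0.5, tolerance = 0.04)
  # band-pass removes the DC component
  expect_lt(abs(mean(e$filtered)), abs(mean(e$raw)) / 50)
  silent <- synthesize_emg(numeric(0), numeric(0), 100, sim)
  expect_true(all(silent$raw == 0))
  expect_error(synthesize_emg(1, 1, 10, sim, band = c(100, 6000)),
               "Nyquist")
})

test_that("trigger-aligned histograms count and normalize correctly", {
  trig <- c(100, 200, 300)
  # aligning a spike train on itself: all mass in the zero bin
  hh <- trigger_aligned_histogram(trig, trig, window = c(-10, 10), bin = 1)
  expect_equal(sum(hh$count), 3)
  expect_equal(hh$count[abs(hh$t - 0.5) < 1e-9], 3)
  # normalization: rate * bin * triggers * units = total counted spikes
  set.seed(8)
  spk <- runif(5000, 0, 1000)
  h2 <- trigger_aligned_histogram(spk, trig, window = c(-50, 50), bin = 2,
                                  n_units = 4)
  expect_equal(sum(h2$rate * 2 / 1000 * 3 * 4), sum(h2$count))
  # independent spikes vs triggers: flat within sampling error
  expect_lt(max(abs(h2$rate - mean(h2$rate))) / mean(h2$rate), 0.6)
  empty <- trigger_aligned_histogram(spk, numeric(0))
  expect_true(all(empty$count == 0))
})

test_that("weight summaries average strengths by column pair", {
  net <- build_network(seed = 6)
  pp <- net$plast
  w <- rep(pp$w_min, nrow(net$edges)) * sign(net$edges$weight)
  m <- weight_summaries(net, w)
  expect_true(all(abs(m - pp$w_min * pp$k) < 1e-9))
  # with both source types, inhibitory weights pull the mean down
  m2 <- weight_summaries(net, w, sources = c("e", "i"))
  expect_true(all(diag(m2) < diag(m)))
})
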