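test_that("a silent network with zero state stays silent", {
  net <- manual_network(3, thresholds = rep(5, 3))
  eng <- quiet_engine(net)
  r <- engine_run(eng, 1, record = "spikes", v_unit = 1)
  expect_identical(nrow(r$spikes), 0L)
  expect_true(all(r$v == 0))
})

test_that("passive-unit potential equals superposed Euler PSP kernels", {
  sim <- sim_params()
  for (case in 1:3) {
    set.seed(100 + case)
    n_spk <- sample(1:20, 1)
    times <- sort(sample(seq(0, 80, by = sim$h), n_spk))
    w <- stats::runif(1, -800, 800)
    if (abs(w) < 1) w <- 350
    net <- manual_network(
      2, edges = data.frame(src = 1, dst = 2, weight = w, plastic = FALSE),
      sim = sim)
    eng <- quiet_engine(net)
    r <- engine_run(eng, 0.12, forced = forced_df(times, 1),
                    record = character(0), v_unit = 2)
    expect_equal(r$v, superposed_v(times, w, length(r$v), sim),
                 tolerance = 1e-12)
  }
})

test_that("spiking resets both accumulators to exactly zero", {
  net <- manual_network(1, thresholds = 5)
  eng <- quiet_engine(net)
  # 10-mV stimulus drives V far over threshold; unit spikes next step
  r <- engine_run(eng, 0.05,
                  stim = data.frame(time = 0, column = 1, amplitude = 10),
                  record = "spikes", v_unit = 1)
  expect_identical(nrow(r$spikes), 1L)
  s <- round(r$spikes$time[1] / 0.1) + 1
  expect_identical(r$v[s], 0)           # reset on the spike step update
  expect_true(all(r$v[s:length(r$v)] == 0))  # no pre-spike history survives
})

test_that("threshold comparison is strict", {
  sim <- sim_params()
  net <- manual_network(1, thresholds = 5, sim = sim)
  eng <- quiet_engine(net)
  # stimulus step of exactly theta: V == theta, never above
  r <- engine_run(eng, 0.05,
                  stim = data.frame(time = 0, column = 1, amplitude = 5),
                  record = "spikes", v_unit = 1)
  expect_identical(nrow(r$spikes), 0L)
  expect_equal(max(r$v), 5000)
  eng2 <- quiet_engine(manual_network(1, thresholds = 5, sim = sim))
  r2 <- engine_run(eng2, 0.05,
                   stim = data.frame(time = 0, column = 1, amplitude = 5.001),
                   record = "spikes")
  expect_identical(nrow(r2$spikes), 1L)
})

test_that("stimulus steps V immediately and decays with tau_s", {
  sim <- sim_params()
  net <- manual_network(1)
  eng <- quiet_engine(net)
  r <- engine_run(eng, 0.1,
                  stim = data.frame(time = 0.5, column = 1, amplitude = 2),
                  record = character(0), v_unit = 1)
  s <- round(0.5 / sim$h) + 1
  expect_equal(r$v[s], 2000)
  ds <- 1 - sim$h / sim$tau_s
  k <- 1:100
  expect_equal(r$v[s + k], 2000 * ds^k, tolerance = 1e-12)
  # negative amplitude deflects away from threshold
  eng2 <- quiet_engine(manual_network(1))
  r2 <- engine_run(eng2, 0.05,
                   stim = data.frame(time = 0, column = 1, amplitude = -2),
                   record = character(0), v_unit = 1)
  expect_equal(r2$v[1], -2000)
})

test_that("decay example: one Euler step of the slow accumulator", {
  # (1 - 0.1/3.2) * 10 mV = 9.6875 mV
  expect_equal((1 - 0.1 / 3.2) * 10, 9.6875)
  sim <- sim_params()
  net <- manual_network(1)
  eng <- quiet_engine(net)
  r <- engine_run(eng, 0.01,
                  stim = data.frame(time = 0, column = 1, amplitude = 10),
                  record = character(0), v_unit = 1)
  expect_equal(r$v[2] / 1000, 9.6875, tolerance = 1e-12)
})

test_that("trajectory error vs the continuous kernel shrinks at order h", {
  times <- seq(0, 40, by = 2)  # representable on both grids
  w <- 500
  errs <- sapply(c(0.1, 0.05), function(h) {
    sim <- sim_params(h = h)
    net <- manual_network(
      2, edges = data.frame(src = 1, dst = 2, weight = w, plastic = FALSE),
      sim = sim, plast = plasticity_params(sim = sim))
    eng <- quiet_engine(net)
    r <- engine_run(eng, 0.08, forced = forced_df(times, 1),
                    record = character(0), v_unit = 2)
    tt <- (seq_along(r$v) - 1) * h
    cont <- numeric(length(tt))
    for (ta in times + sim$d_cortical) {
      on <- tt >= ta
      cont[on] <- cont[on] +
        w * (exp(-(tt[on] - ta) / sim$tau_s) - exp(-(tt[on] - ta) / sim$tau_f))
    }
    max(abs(r$v - cont))
  })
  ratio <- errs[1] / errs[2]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("input summation is linear over delayed spikes and bias events", {
  # two sources with weights 200 and -100 onto one target: A = 100
  sim <- sim_params()
  net <- manual_network(
    3, edges = data.frame(src = c(1, 2), dst = c(3, 3),
                          weight = c(200, -100), plastic = FALSE),
    sim = sim)
  eng <- quiet_engine(net)
  r <- engine_run(eng, 0.02, forced = forced_df(c(1, 1), c(1, 2)),
                  record = character(0), v_unit = 3)
  arr <- round((1 + sim$d_cortical) / sim$h) + 1
  k <- seq(0, length(r$v) - arr)
  expect_equal(r$v[arr + k], 100 * euler_kernel(k, sim), tolerance = 1e-12)
})
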