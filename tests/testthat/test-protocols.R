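test_that("tetanic schedule honors rate and refractory period", {
  set.seed(1)
  times <- schedule_tetanic(500, rate = 10, refractory = 10)
  expect_true(all(diff(times) >= 10))
  n <- length(times)
  expect_lt(abs(n - 5000), 3 * sqrt(5000))
  expect_identical(schedule_tetanic(10, rate = 0), numeric(0))
  expect_error(schedule_tetanic(10, rate = 200, refractory = 10),
               "incompatible")
})

test_that("paired-pulse schedules deliver the documented stimulus counts", {
  p <- protocol_spec("paired_pulse", delay = 10)
  sched <- paired_pulse_schedule(500, p)
  # 1.4 Hz over 500 s: about 700 pairs, each a complete A/B pulse pair
  n_pairs <- sum(sched$column == 1)
  expect_true(n_pairs %in% 699:700)
  expect_identical(nrow(sched), 2L * n_pairs)
  a <- sched[sched$column == 1, ]; b <- sched[sched$column == 2, ]
  expect_equal(b$time - a$time, rep(10, n_pairs))
  # negative delay reverses the order
  pn <- protocol_spec("paired_pulse", delay = -30)
  sn <- paired_pulse_schedule(20, pn)
  expect_true(all(sn$time[sn$column == 2][1] <
                    sn$time[sn$column == 1][1]))
  # triplets: three pulses per column per repetition at 33-ms spacing
  p3 <- protocol_spec("paired_pulse", delay = 10, train_pulses = 3)
  s3 <- paired_pulse_schedule(20, p3)
  a3 <- s3$time[s3$column == 1][1:3]
  expect_equal(diff(a3), c(33, 33))
  expect_identical(nrow(s3) %% 6L, 0L)
  expect_true((nrow(s3) / 6) %in% 27:28)
})

test_that("spike triggers respect the lockout", {
  st <- c(0, 1, 5, 12, 13, 40)
  expect_identical(detect_spike_trigger(st, lockout = 0), st)
  expect_identical(detect_spike_trigger(st, lockout = 10), c(0, 12, 40))
  expect_identical(detect_spike_trigger(numeric(0)), numeric(0))
})

test_that("threshold-crossing detection finds directed crossings only", {
  h <- 1
  x <- c(0, 1, 3, 2, 0.5, -1, 2.5, 3, 1)
  expect_equal(detect_threshold_trigger(x, h, 2, "rising"), c(2, 6))
  expect_equal(detect_threshold_trigger(x, h, 2, "falling"), c(4, 8))
  expect_equal(detect_threshold_trigger(x, h, 2, "rising", lockout = 10), 2)
  expect_identical(detect_threshold_trigger(rep(1, 100), h, 2, "rising"),
                   numeric(0))
  expect_error(detect_threshold_trigger(x, h, Inf), "finite")
})

test_that("threshold calibration reaches a target crossing rate", {
  set.seed(5)
  h <- 0.5
  x <- as.numeric(stats::filter(rnorm(40000), rep(1, 20), sides = 1))
  x[is.na(x)] <- 0
  thr <- calibrate_trigger_threshold(x, h, target_rate = 6, "rising")
  got <- length(detect_threshold_trigger(x, h, thr, "rising")) /
    (length(x) * h / 1000)
  expect_lt(abs(got - 6) / 6, 0.1)
  # doubling the target rate shortens the median inter-trigger interval
  thr2 <- calibrate_trigger_threshold(x, h, target_rate = 12, "rising")
  iv1 <- diff(detect_threshold_trigger(x, h, thr, "rising"))
  iv2 <- diff(detect_threshold_trigger(x, h, thr2, "rising"))
  expect_lt(median(iv2), median(iv1))
  # unreachable target errors with the achievable bound
  expect_error(calibrate_trigger_threshold(rep(0, 1000), h, 6, "rising"),
               "unreachable")
  # zero target puts the threshold above the signal
  expect_gt(calibrate_trigger_threshold(x, h, 0, "rising"), max(x))
})

test_that("cycle triggers fire at the armed zero crossing plus phase delay", {
  h <- 0.1
  t <- seq(0, 2000, by = h)
  lfp <- 100 * sin(2 * pi * 20 * t / 1000)
  # pure 20-Hz tone: filtered copy keeps the frequency; rising zero
  # crossings of the filtered trace recur with a 50-ms period
  tr0 <- detect_cycle_trigger(lfp, h, level = 30, phase = 0)
  expect_gt(length(tr0), 20)
  expect_true(all(abs(diff(tr0)[-(1:2)] - 50) < 0.25))
  tr90 <- detect_cycle_trigger(lfp, h, level = 30, phase = 90)
  expect_true(all(abs(diff(tr90)[-(1:2)] - 50) < 0.25))
  # 90 degrees = a quarter period after the rising crossing
  off <- (tr90[10] - tr0[10]) %% 50
  expect_equal(off, 12.5, tolerance = 0.05)
  # 180 degrees anchors on the falling crossing: half a period away
  tr180 <- detect_cycle_trigger(lfp, h, level = 30, phase = 180)
  off180 <- (tr180[10] - tr0[10]) %% 50
  expect_equal(off180, 25, tolerance = 0.05)
  # a flat signal never arms
  expect_identical(detect_cycle_trigger(rep(0, 1e4), h, level = 30),
                   numeric(0))
})

test_that("protocol presets carry the documented defaults", {
  p <- protocol_preset("spike_triggered")
  expect_identical(p$delay, 10)
  expect_identical(p$amplitude, 2)
  expect_identical(p$target_column, 2L)
  pi <- protocol_preset("inhibition")
  expect_identical(pi$amplitude, -2)
  pa <- protocol_preset("inhibition_active")
  expect_identical(pa$amplitude, -3)
  expect_equal(pa$overrides$correlated_fraction, 0.45)
  expect_equal(pa$overrides$weakening, 0.5)
  pc <- protocol_preset("cycle_triggered")
  expect_identical(pc$target_column, 1L)  # stimulates A
  expect_equal(pc$band, c(15, 25))
  pd <- protocol_preset("disynaptic_cycle")
  expect_identical(pd[["episode"]]$cycles, 7)
  expect_error(protocol_spec("spike_triggered", delay = -5), "negative")
})
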