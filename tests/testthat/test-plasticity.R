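# Engine-level plasticity: the trace-based incremental rule must agree with
# the brute-force pairwise STDP sum on prescribed spike trains.

engine_delta_w <- function(pre, post, h = 0.1, w0 = 5000, sign = 1,
                           c_override = NULL) {
  sim <- sim_params(h = h)
  plast <- open_plast(sim)
  if (!is.null(c_override)) plast$c <- c_override
  net <- manual_network(
    2, edges = data.frame(src = 1, dst = 2, weight = sign * w0,
                          plastic = TRUE),
    sim = sim, plast = plast)
  eng <- quiet_engine(net)
  horizon <- (max(pre, post) + 150) / 1000
  engine_run(eng, horizon, plasticity = TRUE,
             forced = data.frame(time = c(pre, post),
                                 unit = rep(c(1, 2), c(length(pre),
                                                       length(post)))),
             record = character(0))
  engine_weights(eng) - sign * w0
}

test_that("trace-based updates equal the pairwise STDP sum within 1%", {
  sim <- sim_params()
  pp <- open_plast(sim)
  for (case in 1:4) {
    set.seed(200 + case)
    pre <- sort(sample(seq(0, 60, by = 0.1), sample(2:10, 1)))
    post <- sort(sample(seq(0, 60, by = 0.1), sample(2:10, 1)))
    oracle <- stdp_pairwise_sum(pre, post, pp, sim)
    # discretization error is bounded relative to the gross (unsigned)
    # pairwise magnitude, which stays meaningful under cancellation
    gross <- sum(abs(stdp_curve(
      as.numeric(outer(post, pre + sim$d_cortical, "-")), pp)))
    got <- engine_delta_w(pre, post, h = 0.1)
    expect_lt(abs(got - oracle), 0.01 * gross)
  }
})

test_that("trace/pairwise agreement tightens as h decreases", {
  set.seed(42)
  pre <- sort(sample(seq(0, 40, by = 0.2), 6))
  post <- sort(sample(seq(0, 40, by = 0.2), 6))
  errs <- sapply(c(0.1, 0.05, 0.025), function(h) {
    sim <- sim_params(h = h)
    oracle <- stdp_pairwise_sum(pre, post, open_plast(sim), sim)
    abs(engine_delta_w(pre, post, h = h) - oracle) / abs(oracle)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1], 0.01)
})

test_that("an isolated pre-post pair reproduces the curve on both sides", {
  sim <- sim_params()
  pp <- open_plast(sim)
  # post 10 ms after arrival -> potentiation value of the curve
  got <- engine_delta_w(pre = 5, post = 5 + sim$d_cortical + 10)
  expect_equal(got, stdp_curve(10, pp), tolerance = 0.01)
  # post 10 ms before arrival -> depression value
  got2 <- engine_delta_w(pre = 20, post = 20 + sim$d_cortical - 10)
  expect_equal(got2, stdp_curve(-10, pp), tolerance = 0.01)
})

test_that("inhibitory connections strengthen in magnitude like excitatory", {
  sim <- sim_params()
  pp <- open_plast(sim)
  dpos <- engine_delta_w(pre = 5, post = 5 + sim$d_cortical + 10, sign = 1)
  dneg <- engine_delta_w(pre = 5, post = 5 + sim$d_cortical + 10, sign = -1)
  expect_equal(dneg, -dpos, tolerance = 1e-10)  # |w| grows for both
})

test_that("weights pin at the bounds under clipping", {
  sim <- sim_params()
  plast <- plasticity_params(sim = sim)
  net <- manual_network(
    2, edges = data.frame(src = 1, dst = 2, weight = plast$w_max,
                          plastic = TRUE),
    sim = sim, plast = plast)
  eng <- quiet_engine(net)
  # repeated potentiation pairings cannot push w beyond w_max
  times <- seq(5, 300, by = 25)
  engine_run(eng, 0.4, plasticity = TRUE,
             forced = data.frame(time = c(times, times + sim$d_cortical + 5),
                                 unit = rep(c(1, 2), each = length(times))),
             record = character(0))
  expect_identical(engine_weights(eng), plast$w_max)
  # and repeated depression cannot push w below w_min
  net2 <- manual_network(
    2, edges = data.frame(src = 1, dst = 2, weight = plast$w_min,
                          plastic = TRUE),
    sim = sim, plast = plast)
  eng2 <- quiet_engine(net2)
  engine_run(eng2, 0.4, plasticity = TRUE,
             forced = data.frame(time = c(times, times - 10),
                                 unit = rep(c(1, 2), each = length(times))),
             record = character(0))
  expect_identical(engine_weights(eng2), plast$w_min)
})

test_that("no update sequence flips a weight's sign", {
  set.seed(77)
  sim <- sim_params()
  plast <- plasticity_params(sim = sim)
  net <- manual_network(
    3, edges = data.frame(src = c(1, 2), dst = c(3, 3),
                          weight = c(plast$w_min, -plast$w_min),
                          plastic = TRUE),
    sim = sim, plast = plast)
  eng <- quiet_engine(net)
  sp <- data.frame(time = sort(sample(seq(0, 400, by = 0.1), 120)),
                   unit = sample(1:3, 120, replace = TRUE))
  engine_run(eng, 0.5, plasticity = TRUE, forced = sp,
             record = character(0))
  w <- engine_weights(eng)
  expect_gte(w[1], plast$w_min)
  expect_lte(w[2], -plast$w_min)
})

test_that("non-plastic connections never change", {
  sim <- sim_params()
  net <- manual_network(
    2, edges = data.frame(src = 1, dst = 2, weight = 400, plastic = FALSE),
    sim = sim)
  eng <- quiet_engine(net)
  times <- seq(5, 200, by = 20)
  engine_run(eng, 0.3, plasticity = TRUE,
             forced = data.frame(time = c(times, times + 8),
                                 unit = rep(c(1, 2), each = length(times))),
             record = character(0))
  expect_identical(engine_weights(eng), 400)
})

test_that("with plasticity off the weight state is bit-identical", {
  net <- build_network(seed = 5)
  eng <- compile_network(net)
  set.seed(9)
  engine_run(eng, 2, plasticity = TRUE, record = character(0))
  w1 <- engine_weights(eng)
  engine_run(eng, 3, plasticity = FALSE, record = character(0))
  expect_identical(engine_weights(eng), w1)
})
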