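test_that("unit layout matches the standard three-column topology", {
  net <- build_network(seed = 1)
  u <- net$units
  expect_identical(nrow(u), 360L)
  expect_identical(as.integer(table(u$type)), c(120L, 120L, 120L))
  # motor pool size principle: threshold 5 + (k-1)/39, amplitude 0.5 + ...
  m <- u[u$type == "m" & u$column == 1, ]
  k <- seq_len(40) - 1
  expect_equal(m$threshold, 5 + k / 39)
  expect_equal(m$muap, 0.5 + k / 39)
  expect_true(all(diff(m$threshold) > 0 & diff(m$muap) > 0))
})

test_that("connection counts follow the per-class probabilities", {
  n_ab <- n_inh_out <- numeric(25)
  for (s in 1:25) {
    net <- build_network(seed = 1000 + s)
    u <- net$units; e <- net$edges
    exc_a <- u$id[u$type == "e" & u$column == 1]
    in_b <- u$id[u$column == 2 & u$type != "m"]
    n_ab[s] <- sum(e$src %in% exc_a & e$dst %in% in_b)
    inh1 <- u$id[u$type == "i"][1]
    n_inh_out[s] <- sum(e$src == inh1)
  }
  # Ae -> column B: Binomial(40*80, 1/6), expectation 533.3
  expect_lt(abs(mean(n_ab) - 40 * 80 / 6),
            4 * sqrt(40 * 80 * (1 / 6) * (5 / 6) / 25))
  # inhibitory out-degree: Binomial(79, 1/3), expectation 26.3
  expect_lt(abs(mean(n_inh_out) - 79 / 3),
            4 * sqrt(79 * (1 / 3) * (2 / 3) / 25))
})

test_that("no self-connections and signs follow the source type", {
  net <- build_network(seed = 2)
  e <- net$edges; u <- net$units
  expect_true(all(e$src != e$dst))
  expect_true(all(e$weight[u$type[e$src] == "e"] > 0))
  expect_true(all(e$weight[u$type[e$src] == "i"] < 0))
  # corticomotoneuronal edges are fixed, from parent-column excitatory units
  cm <- e[u$type[e$dst] == "m", ]
  expect_true(all(!cm$plastic))
  expect_true(all(u$type[cm$src] == "e"))
  expect_true(all(u$column[cm$src] == u$column[cm$dst]))
  # initial cortical strengths span 20-60% of the maximum
  cort <- e[u$type[e$dst] != "m", ]
  s <- strength_from_weight(cort$weight, net$plast)
  expect_true(all(s >= 100 - 1e-9 & s <= 300 + 1e-9))
})

test_that("the build is a pure function of spec and seed", {
  expect_identical(build_network(seed = 7), build_network(seed = 7))
  expect_false(identical(build_network(seed = 7)$edges,
                         build_network(seed = 8)$edges))
})

test_that("lesioning removes a pathway and preserves the rest exactly", {
  net <- build_network(seed = 3)
  les <- lesion_connections(net, "A", "B")
  u <- net$units
  colpair <- function(e) paste(u$column[e$src], u$column[e$dst])
  expect_false(any(colpair(les$edges) %in% c("1 2", "2 1") &
                     u$type[les$edges$dst] != "m"))
  # surviving edges identical to the intact twin
  key <- function(e) paste(e$src, e$dst)
  shared <- net$edges[key(net$edges) %in% key(les$edges), ]
  expect_equal(shared$weight, les$edges$weight)
  # idempotent
  expect_identical(lesion_connections(les, "A", "B"), les)
  expect_error(lesion_connections(net, "B", "B"), "itself")
})

test_that("fixed intracolumn connectivity is complete, bounded and frozen", {
  net <- build_network(seed = 4)
  fic <- configure_fic(net, strength_range = c(200, 300))
  u <- fic$units; e <- fic$edges
  intra <- u$column[e$src] == u$column[e$dst] & u$type[e$src] != "m" &
    u$type[e$dst] != "m"
  expect_identical(sum(intra), 3L * 80L * 79L)
  expect_true(all(!e$plastic[intra]))
  s <- strength_from_weight(e$weight[intra], fic$plast)
  expect_true(all(s >= 200 & s <= 300))
  expect_true(fic$correlated_bias_removed)
  # STDP leaves every intracolumn weight untouched
  eng <- compile_network(fic)
  w0 <- engine_weights(eng)
  set.seed(31)
  engine_run(eng, 2, plasticity = TRUE, record = character(0))
  w1 <- engine_weights(eng)
  expect_identical(w1[!e$plastic], w0[!e$plastic])
  expect_false(identical(w1[e$plastic], w0[e$plastic]))
})
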