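test_that("gate sampling follows the stretched-clipped sigmoid closed form", {
  cfg <- gate_config()
  s <- gate_state(alpha = c(0, -5, 10), beta = 0.67)
  z <- sample_gates(s, cfg, u = rep(0.5, 3))$z
  # at u = 0.5 the noise term vanishes: sigma(0)*1.2 - 0.1 = 0.5
  expect_equal(z[1], 0.5)
  # alpha = -5 pre-clip value sigma(-5/0.67)*1.2 - 0.1 < 0 -> exact 0
  expect_identical(z[2], 0)
  # alpha = +10 pre-clip > 1 -> exact 1
  expect_identical(z[3], 1)
  # against an independently evaluated scalar: alpha=-5, beta=0.67, u=0.5
  raw <- plogis(-5 / 0.67) * 1.2 - 0.1
  expect_lt(raw, 0)
})

test_that("noise at the boundary of (0,1) is rejected", {
  s <- gate_state(0, 0.67)
  expect_error(sample_gates(s, gate_config(), u = 0), "invalid noise")
  expect_error(sample_gates(s, gate_config(), u = 1), "invalid noise")
  expect_error(sample_gates(s, gate_config(), u = c(0.5, 0.5)), "length")
})

test_that("retention probability matches sigma(alpha - beta*log(-gamma/zeta))", {
  cfg <- gate_config()
  expect_equal(retention_probability(0, 0.67, cfg),
               plogis(0.67 * log(11)), tolerance = 1e-12)
  expect_equal(retention_probability(0, 0.67, cfg), 0.8330,
               tolerance = 1e-3)
  expect_equal(retention_probability(-50, 0.67, cfg), 0, tolerance = 1e-12)
  expect_equal(retention_probability(50, 0.67, cfg), 1, tolerance = 1e-12)
  expect_equal(retention_probability(0, 0, cfg), 0.5)
  # strictly increasing in alpha
  grid <- seq(-4, 4, by = 0.5)
  p <- retention_probability(grid, 0.3, cfg)
  expect_true(all(diff(p) > 0))
  # for alpha < 0, increasing beta pulls the probability toward 0.5
  p_beta <- vapply(c(0.1, 0.3, 0.67), function(b)
    retention_probability(-2, b, cfg), numeric(1))
  expect_true(all(diff(p_beta) > 0))
  expect_true(all(p_beta < 0.5))
})

test_that("expected L0 is the sum of retention probabilities", {
  cfg <- gate_config()
  s8 <- gate_state(rep(0, 8), 0.67)
  expect_equal(expected_l0(s8, cfg), 8 * plogis(0.67 * log(11)),
               tolerance = 1e-12)
  expect_equal(expected_l0(s8, cfg), 6.664, tolerance = 1e-2)
  expect_equal(expected_l0(gate_state(-60, 0.3), cfg), 0, tolerance = 1e-9)
  s <- gate_state(c(-1.3, 0.4, 2.2), 0.4)
  expect_equal(expected_l0(s, cfg),
               sum(retention_probability(s$alpha, s$beta, cfg)))
})

test_that("expected L0 gradient matches finite differences", {
  cfg <- gate_config()
  alpha <- c(-2, -0.5, 0, 1.5)
  s <- gate_state(alpha, 0.4)
  g <- sparseviews:::expected_l0_grad(s, cfg)
  eps <- 1e-6
  for (i in seq_along(alpha)) {
    ap <- alpha; am <- alpha
    ap[i] <- ap[i] + eps; am[i] <- am[i] - eps
    num <- (expected_l0(gate_state(ap, 0.4), cfg) -
              expected_l0(gate_state(am, 0.4), cfg)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("boundary probabilities have the closed forms and symmetry", {
  cfg <- gate_config()
  bp <- boundary_probabilities(0, 0.67, cfg)
  # with zeta=1.1, gamma=-0.1 both log terms are log(11): symmetric at 0
  expect_equal(bp$p_zero, bp$p_one)
  expect_equal(bp$p_zero, plogis(-0.67 * log(11)), tolerance = 1e-12)
  expect_equal(bp$p_zero, 0.1670, tolerance = 1e-3)
  # complementary events: P(z=0) + P(z>0) = 1
  for (a in c(-3, -1, 0, 1, 3)) {
    bp <- boundary_probabilities(a, 0.3, cfg)
    expect_equal(bp$p_zero + retention_probability(a, 0.3, cfg), 1,
                 tolerance = 1e-12)
  }
  expect_lt(boundary_probabilities(10, 0.67, cfg)$p_zero, 1e-4)
  expect_error(
    boundary_probabilities(0, 0.5, gate_config(zeta = 1.0001))$p_one,
    NA)
})

test_that("Monte-Carlo boundary masses match the closed forms on a grid", {
  cfg <- gate_config()
  n <- 1e5
  k <- 0
  for (a in c(-3, -1, 0, 1, 3)) {
    for (b in c(0.67, 0.3, 0.1)) {
      k <- k + 1
      set.seed(1000 + k)
      z <- sample_gates(gate_state(rep(a, n), b), cfg, u = runif(n))$z
      bp <- boundary_probabilities(a, b, cfg)
      p_open <- retention_probability(a, b, cfg)
      for (chk in list(c(mean(z == 0), bp$p_zero),
                       c(mean(z == 1), bp$p_one),
                       c(mean(z > 0), p_open))) {
        se <- sqrt(chk[2] * (1 - chk[2]) / n)
        expect_lt(abs(chk[1] - chk[2]), 3 * se + 1e-9)
      }
    }
  }
})

test_that("samples stay in [0,1]; degenerate stretch removes boundary mass", {
  set.seed(4)
  cfg <- gate_config()
  z <- sample_gates(gate_state(rnorm(5000), 0.3), cfg, u = runif(5000))$z
  expect_true(all(z >= 0 & z <= 1))
  expect_gt(mean(z == 0), 0)
  expect_gt(mean(z == 1), 0)
  # gamma -> 0-, zeta -> 1+: plain binary concrete, no exact boundary mass
  cfg0 <- gate_config(zeta = 1 + 1e-12, gamma = -1e-12)
  z0 <- sample_gates(gate_state(rep(0, 5000), 0.67), cfg0,
                     u = runif(5000))$z
  expect_equal(mean(z0 == 0), 0)
  expect_equal(mean(z0 == 1), 0)
})

test_that("temperature annealing is linear between the endpoints", {
  cfg <- gate_config()
  expect_equal(anneal_beta(0, 300, cfg), 0.67)
  expect_equal(anneal_beta(299, 300, cfg), 0.1)
  expect_equal(anneal_beta(1, 3, cfg), 0.385)
  b <- anneal_beta(0:49, 50, cfg)
  expect_true(all(diff(b) < 0))
  expect_equal(anneal_beta(0, 1, cfg), 0.67)
  expect_error(anneal_beta(5, 5, cfg), "epoch")
  expect_error(anneal_beta(0, 0, cfg), "total_epochs")
})

test_that("deterministic mask thresholds the retention probability", {
  cfg <- gate_config()
  expect_false(any(deterministic_mask(gate_state(rep(-30, 4), 0.1), cfg)))
  expect_identical(
    unname(deterministic_mask(gate_state(c(5, -5), 0.1), cfg)),
    c(TRUE, FALSE))
  # alpha = 0 at beta = 0.67 retains: p = 0.833 > 0.5
  expect_true(deterministic_mask(gate_state(0, 0.67), cfg))
  m <- deterministic_mask(gate_state(c(1, -1), 0.3,
                                     view_names = c("wing", "head")), cfg)
  expect_named(m, c("wing", "head"))
})

test_that("gate config invariants are enforced", {
  expect_error(gate_config(gamma = 0.1), "gamma")
  expect_error(gate_config(zeta = 0.9), "zeta")
  expect_error(gate_config(beta_end = 0.8, beta_start = 0.67), "beta")
  expect_error(gate_config(selection_threshold = 1.2), "threshold")
})
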