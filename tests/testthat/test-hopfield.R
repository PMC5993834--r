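test_that("local fields sum weights over existing edges only", {
  net <- worked_net3()
  W <- worked_W3()
  expect_equal(local_fields(net, W, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(local_fields(sp_network(matrix(integer(0), ncol = 2), 3), W,
                            c(1, 1, 1)), c(0, 0, 0))
  # hand-summed: s = (1, 0, 1); the 0.9 entry has no edge and must not leak
  expect_equal(local_fields(net, W, c(1, 0, 1)), c(0, 0.25, 0))
})

test_that("thresholds are half the incident weight sums", {
  net <- worked_net3()
  W <- worked_W3()
  expect_equal(thresholds(net, W), c(0.25, 0.125, -0.125))
  # isolated node and exact cancellation
  net2 <- sp_network(rbind(c(1L, 2L), c(1L, 3L)), 4)
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 0.1
  W2[1, 3] <- W2[3, 1] <- -0.1
  expect_equal(thresholds(net2, W2), c(0, 0.05, -0.05, 0))
})

test_that("thresholds equal k/(2 kappa_inf) when neighbours share the pattern value", {
  # star whose hub and leaves are all active in the single balanced pattern
  xi <- structure(matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 1),
                  a0 = 0.5, class = c("pattern_set", "matrix", "array"))
  W <- hebbian_weights(xi, kappa_inf = 10)
  net <- sp_network(cbind(1L, 2:4), 8)
  th <- thresholds(net, W)
  expect_equal(th[1], 3 / (2 * 10))
})

test_that("state updates follow the stochastic threshold rule", {
  set.seed(20)
  # beta = 0 (T = Inf) fires with probability 1/2
  s <- replicate(300, update_states(c(0, 0), c(1, -1), c(0, 0), T = Inf))
  expect_lt(abs(mean(s) - 0.5), 3 * 0.5 / sqrt(600))
  # h = theta is a fair coin at any T
  s <- replicate(300, update_states(0L, 0.3, 0.3, T = 0.5))
  expect_lt(abs(mean(s) - 0.5), 3 * 0.5 / sqrt(300))
  # T = 0 sign rule is deterministic off ties
  expect_equal(update_states(c(0L, 1L), c(0.3, -0.1), c(0, 0), T = 0), c(1L, 0L))
})

test_that("overlap is 1 at the pattern, -1 at its complement, ~0 for noise", {
  xi <- half_pattern(200)
  s <- as.integer(xi[1, ])
  expect_equal(overlap(s, xi[1, ], 0.5), 1)
  expect_equal(overlap(1L - s, xi[1, ], 0.5), -1)
  set.seed(21)
  m <- replicate(200, overlap(rbinom(200, 1, 0.5), xi[1, ], 0.5))
  expect_lt(abs(mean(m)), 3 * sd(m) / sqrt(200))
})

test_that("overlap is invariant under consistent relabeling", {
  set.seed(22)
  xi <- generate_patterns(50, 1, 0.4)
  s <- rbinom(50, 1, 0.5)
  perm <- sample.int(50)
  expect_equal(overlap(s[perm], xi[1, perm], 0.4), overlap(s, xi[1, ], 0.4))
})

test_that("mean activity and currents behave as defined", {
  expect_equal(mean_activity(c(0, 0, 0)), 0)
  expect_equal(mean_activity(c(1, 1, 1)), 1)
  expect_equal(currents(c(1, 2), c(1, 5)), c(0, 3))
})

test_that("one engine sweep matches the reference R implementation exactly", {
  set.seed(23)
  xi <- generate_patterns(120, 1, 0.5)
  W <- hebbian_weights(xi, 8)
  net <- initial_network(120, 8, "homogeneous")
  s0 <- as.integer(xi[1, ])
  set.seed(99)
  hR <- local_fields(net, W, s0)
  thR <- thresholds(net, W)
  sR <- update_states(s0, hR, thR, T = 0.7)
  set.seed(99)
  run <- run_hopfield(W, xi, network = net, states0 = s0, T = 0.7, n_sweeps = 1)
  expect_identical(run$states, sR)
  expect_equal(run$thresholds, thR)
})

test_that("a stored pattern is a fixed point at T = 0 on random graphs", {
  set.seed(24)
  for (rep in 1:10) {
    xi <- half_pattern(100)
    W <- hebbian_weights(xi, 8)
    repeat {  # stub pairing can leave isolated nodes; the claim needs none
      net <- initial_network(100, 8, "homogeneous")
      if (all(degrees(net) > 0)) break
    }
    run <- run_hopfield(W, xi, network = net, states0 = as.integer(xi[1, ]),
                        T = 0, n_sweeps = 20)
    expect_equal(min(run$trajectory$m.1), 1)
  }
})

test_that("currents track degrees in the single-pattern memory state", {
  set.seed(25)
  cfg <- sim_config(N = 400, T = 0.5, alpha = 1, gamma = 1, n = 10, h_s = 10,
                    kappa_inf = 10, kappa0 = 10, mode = "coupled",
                    neural_init = "pattern", t_max = 2000, seed = 26)
  run <- run_coevolution(cfg)
  expect_gt(tail(run$trajectory$m_best, 1), 0.8)  # memory state reached
  expect_gt(cor(run$currents, degrees(run$network)), 0.9)
})

test_that("steepest_drop locates the fall of a sigmoid curve", {
  x <- seq(0, 2, 0.05)
  y <- 1 / (1 + exp((x - 1.3) / 0.05))
  expect_lt(abs(steepest_drop(x, y) - 1.3), 0.05)
})
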