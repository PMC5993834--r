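test_that("global probabilities interpolate between growth and loss", {
  gp <- global_probs(kappa = 10, n = 10, N = 800, kappa_inf = 10)
  expect_equal(unname(gp), c(10 / 1600, 10 / 1600))  # u = d = n/(2N) at kappa_inf
  gp0 <- global_probs(0, 10, 800, 10)
  expect_equal(unname(gp0), c(10 / 800, 0))
  gp2 <- global_probs(20, 10, 800, 10)
  expect_equal(unname(gp2), c(0, 10 / 800))
  # above 2 kappa_inf the growth probability is clipped at zero
  expect_equal(unname(global_probs(25, 10, 800, 10)["u"]), 0)
  # transient growth factor adds a exp(-t/tau_g)
  gpg <- global_probs(10, 10, 800, 10, t = 5, growth_a = 0.02, growth_tau = 10)
  expect_equal(unname(gpg["u"]), 10 / 1600 + 0.02 * exp(-0.5))
})

test_that("local probabilities match hand-evaluated cases", {
  # all currents and degrees equal: pi = eta = 1/N
  lp <- local_probs(rep(2, 4), rep(3L, 4), alpha = 1.7, gamma = 1)
  expect_equal(lp$pi, rep(1 / 4, 4))
  expect_equal(lp$eta, rep(1 / 4, 4))
  expect_equal(lp$pi_tilde, rep(1 / 4, 4))   # alpha-independent when I equal
  # N = 2, I = (1, 2), alpha = 1: effective weights I_i / sum(I)
  lp2 <- local_probs(c(1, 2), c(1L, 1L), alpha = 1, gamma = 1)
  expect_equal(lp2$pi_tilde, c(1 / 3, 2 / 3))
  expect_equal(lp2$pi_sel, c(1 / 6, 5 / 6))
  # fully silent network: uniform gains, degree-proportional losses
  lp3 <- local_probs(c(0, 0, 0), c(2L, 1L, 1L), alpha = 1, gamma = 1)
  expect_equal(lp3$pi_sel, rep(1 / 3, 3))
  expect_equal(lp3$eta_sel, c(0.5, 0.25, 0.25))
})

test_that("R and C++ selection weights agree (dual route)", {
  set.seed(30)
  for (case in 1:5) {
    N <- 50
    I <- c(rep(0, 5), rexp(N - 5))
    deg <- rpois(N, 8)
    if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
    E <- sum(deg) / 2
    for (ea in c(FALSE, TRUE)) {
      lp <- local_probs(I, deg, alpha = 1.3, gamma = 0.8, eta_approx = ea)
      cw <- synprune:::cpp_local_weights(I, as.integer(deg), E, 1.3, 0.8, ea)
      expect_equal(cw$pi_sel, lp$pi_sel, tolerance = 1e-12)
      expect_equal(cw$eta_sel, lp$eta_sel, tolerance = 1e-12)
    }
  }
})

test_that("selection weights sum to one after clipping and renormalization", {
  set.seed(31)
  for (case in 1:20) {
    N <- sample(10:100, 1)
    I <- rexp(N)^sample(1:3, 1)
    deg <- rpois(N, 6) + 1L
    lp <- local_probs(I, deg, alpha = runif(1, 0.3, 2), gamma = runif(1, 0.3, 2))
    expect_equal(sum(lp$pi_sel), 1)
    expect_equal(sum(lp$eta_sel), 1)
    expect_equal(sum(lp$pi_tilde), 1)
    expect_equal(sum(lp$eta_tilde), 1)
    expect_true(all(lp$pi_sel >= 0) && all(lp$eta_sel >= 0))
  }
})

test_that("structural step is inert when u = d = 0 and skips impossible losses", {
  set.seed(32)
  net <- initial_network(50, 6, "homogeneous")
  lp <- local_probs(rep(1, 50), degrees(net))
  st <- structural_step(net, lp$pi_sel, lp$eta_sel, 0, 0)
  ekey <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_equal(ekey(st$network$edges), ekey(net$edges))
  # empty graph: losses are all skipped, no removals
  empty <- initial_network(50, 0)
  lp0 <- local_probs(rep(1, 50), degrees(empty))
  st0 <- structural_step(empty, lp0$pi_sel, lp0$eta_sel, 0, 0.5)
  expect_equal(st0$report$removed, 0)
  expect_equal(nrow(st0$network$edges), 0L)
})

test_that("expected edge change per step is N(u - d)", {
  set.seed(33)
  net <- initial_network(200, 10, "homogeneous")
  u <- 0.03; d <- 0.01
  deltas <- replicate(300, {
    lp <- local_probs(rep(1, 200), degrees(net))
    st <- structural_step(net, lp$pi_sel, lp$eta_sel, u, d)
    st$report$added - st$report$removed
  })
  expected <- 200 * (u - d)
  expect_lt(abs(mean(deltas) - expected), 3 * sd(deltas) / sqrt(300))
})

test_that("gamma = 1 removes edges uniformly in the topological limit", {
  set.seed(34)
  net <- initial_network(30, 4, "homogeneous")
  E <- nrow(net$edges)
  key <- paste(net$edges[, 1], net$edges[, 2])
  counts <- setNames(numeric(E), key)
  trials <- 4000
  for (tr in seq_len(trials)) {
    k <- degrees(net)
    lp <- local_probs(as.numeric(k), k, alpha = 1, gamma = 1)
    st <- structural_step(net, lp$pi_sel, lp$eta_sel, 0, 1 / 30)  # ~1 loss/step
    gone <- setdiff(key, paste(st$network$edges[, 1], st$network$edges[, 2]))
    counts[gone] <- counts[gone] + 1
  }
  # each edge equally likely: counts ~ Binomial(removals, 1/E)
  p <- counts / sum(counts)
  se <- sqrt((1 / E) * (1 - 1 / E) / sum(counts))
  expect_lt(max(abs(p - 1 / E)), 5 * se)
})

test_that("mean degree is stationary at kappa_inf with < 2% drift", {
  cfg <- sim_config(N = 400, mode = "topological", alpha = 1, gamma = 1,
                    n = 10, kappa_inf = 10, kappa0 = 10, t_max = 10000, seed = 35)
  run <- run_coevolution(cfg)
  first <- run$trajectory$kappa[run$trajectory$t <= 5000]
  second <- run$trajectory$kappa[run$trajectory$t > 5000]
  expect_lt(abs(mean(first) - mean(second)) / 10, 0.02)
  expect_lt(abs(mean(second) - 10) / 10, 0.02)
})

test_that("identical seeds give identical trajectories", {
  cfg <- sim_config(N = 100, T = 0.8, mode = "coupled", kappa_inf = 6,
                    kappa0 = 12, t_max = 300, seed = 36)
  r1 <- run_coevolution(cfg)
  r2 <- run_coevolution(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$network$edges, r2$network$edges)
  expect_identical(r1$states, r2$states)
  cfg$seed <- 37L
  r3 <- run_coevolution(cfg)
  expect_false(identical(r1$trajectory$kappa, r3$trajectory$kappa))
})

test_that("simulated kappa(t) follows the pruning closed form", {
  # degenerate case: kappa0 = kappa_inf stays within noise
  cfg <- sim_config(N = 400, mode = "topological", n = 10, kappa_inf = 10,
                    kappa0 = 10, t_max = 2000, seed = 38)
  expect_lt(kappa_trajectory_check(run_coevolution(cfg)), 0.05)
  # tau_p arithmetic
  expect_equal(tau_pruning(1600, 10, 5), 1600)
  # decay-constant recovery within 10%
  cfg2 <- sim_config(N = 800, mode = "topological", n = 10, kappa_inf = 30,
                     kappa0 = 60, t_max = 6000, seed = 39)
  run <- run_coevolution(cfg2)
  tau <- tau_pruning(800, 30, 10)
  fit <- nls(kappa ~ (60 - ki) * exp(-t / tp) + ki,
             data = run$trajectory, start = list(ki = 30, tp = tau))
  expect_lt(abs(coef(fit)["tp"] - tau) / tau, 0.1)
})

test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(N = 100, kappa0 = 200))
  expect_error(sim_config(N = 100, T = -1))
  expect_error(sim_config(N = 100, a0 = 1))
  expect_error(sim_config(N = 100, ic_kind = "nonsense"))
})
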