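test_that("pruning closed form hits its limits and time constant", {
  expect_equal(kappa_linear(0, 60, 30, 1600), 60)
  expect_equal(kappa_linear(1e9, 60, 30, 1600), 30)
  expect_equal(kappa_linear(1600, 60, 30, 1600), 30 + 30 / exp(1))
})

test_that("growth closed form satisfies its constraint pair", {
  kinf <- 30; a <- 1.7; tg <- 4; tp <- 1  # overgrowth regime (tau_g > 2 tau_p)
  k0 <- kappa_growth_kappa0(kinf, a, tg, tp)
  expect_lt(abs(kappa_growth(0, kinf, a, tg, tp) - k0), 1e-8)
  expect_equal(kappa_growth(1e9, kinf, a, tg, tp), kinf)
  expect_error(kappa_growth(1, kinf, a, 2.2, 2.2), "degenerate")
  # interior maximum: numerical derivative vanishes at the optimum
  tstar <- optimize(function(t) -kappa_growth(t, kinf, a, tg, tp), c(0, 30),
                    tol = 1e-10)$minimum
  h <- 1e-5
  dk <- (kappa_growth(tstar + h, kinf, a, tg, tp) -
         kappa_growth(tstar - h, kinf, a, tg, tp)) / (2 * h)
  expect_lt(abs(dk), 1e-6)
  expect_gt(kappa_growth(tstar, kinf, a, tg, tp), k0)  # genuine overshoot
})

test_that("the linear closed form solves d kappa/dt = 2N(u - d)/N on a grid", {
  # kappa must stay below 2 kappa_inf, where u(kappa) is not clipped
  N <- 1600; kinf <- 10; n <- 5
  tau <- tau_pruning(N, kinf, n)
  tt <- seq(0, 5000, by = 50)
  kap <- kappa_linear(tt, 18, kinf, tau)
  h <- 1e-3
  dnum <- (kappa_linear(tt + h, 18, kinf, tau) -
           kappa_linear(tt - h, 18, kinf, tau)) / (2 * h)
  drate <- sapply(kap, function(k) {
    gp <- global_probs(k, n, N, kinf)
    2 * (gp["u"] - gp["d"])
  })
  expect_lt(max(abs(dnum - drate)), 1e-6)
})

test_that("noise-free series are fitted to machine accuracy", {
  tt <- seq(0, 8000, by = 250)
  series <- simulate_density_series(tt, "linear",
                                    list(kappa0 = 59.1, kappa_inf = 30.7,
                                         tau_p = 1600))
  fit <- fit_density(series, "linear")
  expect_lt(fit$resid_norm, 1e-9)
  expect_equal(unname(fit$coef["tau_p"]), 1600, tolerance = 1e-6)
})

test_that("pruning time constant is recovered within 1 s.e. from 2% noise", {
  set.seed(60)
  tt <- seq(0, 8000, by = 200)
  series <- simulate_density_series(tt, "linear",
                                    list(kappa0 = 59.1, kappa_inf = 30.7,
                                         tau_p = 1600), noise = 0.02)
  fit <- fit_density(series, "linear")
  expect_lt(abs(fit$coef["tau_p"] - 1600), 2 * fit$se["tau_p"])
})

test_that("an early overshoot favours the growth model over the linear one", {
  set.seed(61)
  tt <- seq(0.25, 30, by = 0.5)
  series <- simulate_density_series(tt, "growth",
                                    list(kappa_inf = 1.64, a = 1.7,
                                         tau_g = 4.0, tau_p = 2.2),
                                    noise = 0.02)
  f_lin <- fit_density(series, "linear")
  f_gro <- fit_density(series, "growth")
  expect_lt(f_gro$resid_norm, f_lin$resid_norm)
})

test_that("fits are equivariant under rescaling of the density", {
  set.seed(62)
  tt <- seq(0, 6000, by = 200)
  series <- simulate_density_series(tt, "linear",
                                    list(kappa0 = 60, kappa_inf = 30,
                                         tau_p = 1500), noise = 0.01)
  f1 <- fit_density(series, "linear")
  series2 <- series
  series2$rho <- series$rho * 7.3
  series2$sd <- series$sd * 7.3
  f2 <- fit_density(series2, "linear")
  expect_equal(unname(f2$coef["tau_p"]), unname(f1$coef["tau_p"]),
               tolerance = 1e-6)
  expect_equal(unname(f2$coef["kappa0"] / f1$coef["kappa0"]), 7.3,
               tolerance = 1e-6)
})

test_that("exclusions and input validation are honoured", {
  tt <- seq(0, 4000, by = 400)
  series <- simulate_density_series(tt, "linear",
                                    list(kappa0 = 60, kappa_inf = 30, tau_p = 1500))
  # corrupt two points, then exclude them: exact fit restored
  series$rho[c(3, 7)] <- series$rho[c(3, 7)] * 3
  fit <- fit_density(series, "linear", exclude = c(3, 7))
  expect_lt(fit$resid_norm, 1e-8)
  expect_error(fit_density(series[1:3, ], "linear"), "at least")
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t = series$t, rho = abs(series$rho)), f, row.names = FALSE)
  s2 <- read_density_series(f)
  expect_s3_class(s2, "density_series")
  expect_equal(s2$t, series$t)
})
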