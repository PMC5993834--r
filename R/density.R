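#' Closed-form mean-degree (synaptic density) trajectories
#'
#' `kappa_linear()` is the pure pruning solution
#' `kappa(t) = (kappa0 - kappa_inf) exp(-t/tau_p) + kappa_inf`, the mean
#' degree decaying from the initial overgrowth `kappa0` to the adult value
#' `kappa_inf` with time constant `tau_p = N kappa_inf/(2n)`.
#'
#' `kappa_growth()` adds a transient growth factor `a exp(-t/tau_g)` to the
#' gain probability, giving
#' `kappa(t) = kappa_inf [1 + b exp(-t/tau_g) - a exp(-t/tau_p)]` with
#' `b = a tau_g / (tau_g - tau_p)`; the initial density implied by the
#' constraint pair is `kappa(0) = kappa_inf (1 - a + b)`. This form
#' reproduces the early overshoot and maximum of developmental density data.
#'
#' @param t time (same units as the tau's).
#' @param kappa0 initial mean degree.
#' @param kappa_inf stationary mean degree.
#' @param tau_p pruning time constant (> 0).
#' @param a growth-factor amplitude (dimensionless).
#' @param tau_g growth time constant; must differ from `tau_p`.
#' @return mean degree at `t`.
#' @export
kappa_linear <- function(t, kappa0, kappa_inf, tau_p) {
  stopifnot(tau_p > 0)
  (kappa0 - kappa_inf) * exp(-t / tau_p) + kappa_inf
}

#' @rdname kappa_linear
#' @export
kappa_growth <- function(t, kappa_inf, a, tau_g, tau_p) {
  stopifnot(tau_p > 0, tau_g > 0)
  if (abs(tau_g - tau_p) < 1e-12 * max(tau_g, tau_p))
    stop("tau_g = tau_p is degenerate for the two-exponential solution")
  b <- a * tau_g / (tau_g - tau_p)
  kappa_inf * (1 + b * exp(-t / tau_g) - a * exp(-t / tau_p))
}

#' Initial density implied by the growth-model constraints
#' @inheritParams kappa_linear
#' @export
kappa_growth_kappa0 <- function(kappa_inf, a, tau_g, tau_p) {
  b <- a * tau_g / (tau_g - tau_p)
  kappa_inf * (1 - a + b)
}

#' Synthetic density series (fixture generator)
#'
#' Evaluates one of the closed forms on a time grid and adds multiplicative
#' Gaussian noise; used to exercise the fitting machinery.
#'
#' @param t time grid.
#' @param model `"linear"` or `"growth"`.
#' @param params named list of closed-form parameters (see [kappa_linear()]).
#' @param noise relative noise s.d. (e.g. 0.02 for 2%).
#' @return a `density_series` data.frame with columns `t`, `rho`, `sd`.
#' @export
simulate_density_series <- function(t, model = c("linear", "growth"),
                                    params, noise = 0) {
  model <- match.arg(model)
  rho <- if (model == "linear")
    kappa_linear(t, params$kappa0, params$kappa_inf, params$tau_p)
  else
    kappa_growth(t, params$kappa_inf, params$a, params$tau_g, params$tau_p)
  sdv <- noise * abs(rho)
  if (noise > 0) rho <- rho + rnorm(length(t), 0, sdv)
  structure(data.frame(t = t, rho = rho, sd = sdv),
            class = c("density_series", "data.frame"))
}

#' Read a density series from CSV
#'
#' Expects two or three columns: time, density, and optionally per-point
#' standard deviations.
#' @param path CSV file path.
#' @export
read_density_series <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",")
  names(d)[1:2] <- c("t", "rho")
  if (ncol(d) >= 3) names(d)[3] <- "sd"
  stopifnot(!is.unsorted(d$t, strictly = TRUE), all(d$rho >= 0))
  structure(d, class = c("density_series", "data.frame"))
}

#' Fit a closed-form density model to an observed series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt, multi-start over
#' decade-spaced time constants, since the two-exponential model is
#' ill-conditioned when `tau_g` approaches `tau_p`). Densities are fitted in
#' their own units: because `rho(t)` is proportional to `kappa(t)`, the
#' amplitude parameters (`kappa0`, `kappa_inf`) absorb the proportionality
#' constant, and the fit is equivariant under rescaling of `rho`. For the
#' `"linear"` model, time is measured from the pruning onset `t0` (the
#' density maximum); the `"growth"` model uses absolute time.
#'
#' @param series data.frame with `t`, `rho` and optional `sd` (weights
#'   `1/sd^2`).
#' @param model `"linear"` or `"growth"`.
#' @param t0 pruning-onset time offset for the linear model.
#' @param exclude integer indices of points to exclude from the fit.
#' @return a `density_fit`: list with `model`, `coef`, `se`, `resid_norm`,
#'   `excluded`, `t0`, and the fitted `curve` function of t.
#' @export
fit_density <- function(series, model = c("linear", "growth"), t0 = 0,
                        exclude = integer(0)) {
  model <- match.arg(model)
  use <- setdiff(seq_len(nrow(series)), exclude)
  d <- series[use, , drop = FALSE]
  need <- if (model == "linear") 4 else 6
  if (nrow(d) < need)
    stop(sprintf("need at least %d non-excluded points for the %s model",
                 need, model))
  w <- if ("sd" %in% names(d) && all(d$sd > 0)) 1 / d$sd^2 else rep(1, nrow(d))
  tt <- if (model == "linear") d$t - t0 else d$t
  span <- max(tt) - min(tt[tt >= 0], 0)
  tau_starts <- span / c(0.5, 2, 8, 32)
  best <- NULL
  for (tp in tau_starts) {
    fit <- NULL
    if (model == "linear") {
      st <- list(kappa0 = max(d$rho), kappa_inf = min(d$rho), tau_p = tp)
      fit <- tryCatch(
        minpack.lm::nlsLM(rho ~ kappa_linear(tt, kappa0, kappa_inf, tau_p),
                          data = data.frame(rho = d$rho, tt = tt),
                          start = st, weights = w,
                          lower = c(0, 0, span * 1e-4),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) best <- keep_best(best, fit)
    } else {
      for (tg in tau_starts) {
        if (abs(tg - tp) < 1e-6 * span) next
        st <- list(kappa_inf = min(d$rho), a = 1, tau_g = tg, tau_p = tp)
        fit <- tryCatch(
          minpack.lm::nlsLM(rho ~ kappa_growth(tt, kappa_inf, a, tau_g, tau_p),
                            data = data.frame(rho = d$rho, tt = tt),
                            start = st, weights = w,
                            lower = c(0, 0, span * 1e-4, span * 1e-4),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (!is.null(fit)) best <- keep_best(best, fit)
      }
    }
  }
  if (is.null(best)) stop("density fit did not converge from any start")
  cf <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, length(cf)))
  resid_norm <- sqrt(sum(w * residuals(best)^2))
  curve_fun <- if (model == "linear")
    function(t) kappa_linear(t - t0, cf["kappa0"], cf["kappa_inf"], cf["tau_p"])
  else
    function(t) kappa_growth(t, cf["kappa_inf"], cf["a"], cf["tau_g"], cf["tau_p"])
  structure(list(model = model, coef = cf, se = setNames(se, names(cf)),
                 resid_norm = resid_norm, excluded = exclude, t0 = t0,
                 curve = curve_fun, fit = best),
            class = "density_fit")
}

#' @noRd
keep_best <- function(best, fit) {
  if (is.null(best)) return(fit)
  if (deviance(fit) < deviance(best)) fit else best
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("density_fit (%s model), residual norm %.4g\n", x$model, x$resid_norm))
  for (nm in names(x$coef))
    cat(sprintf("  %-10s %.6g (se %.3g)\n", nm, x$coef[nm], x$se[nm]))
  if (length(x$excluded)) cat("  excluded points:", x$excluded, "\n")
  invisible(x)
}

#' @importFrom stats deviance residuals vcov
NULL
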