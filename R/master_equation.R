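#' Degree-distribution container
#'
#' A probability vector over degrees `k = 0 .. N-1`, as produced by the
#' master-equation integrator or extracted from a simulated network.
#'
#' @param p non-negative numeric vector summing to 1 (within 1e-10).
#' @param t time associated with the distribution.
#' @param params optional list of generating parameters.
#' @return a `degree_distribution` object with fields `k`, `p`, `t`, `params`.
#' @export
degree_distribution <- function(p, t = 0, params = list()) {
  stopifnot(all(p >= -1e-12), abs(sum(p) - 1) < 1e-10)
  p <- pmax(p, 0)
  structure(list(k = seq_along(p) - 1L, p = as.numeric(p), t = t,
                 params = params),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  kap <- sum(x$k * x$p)
  cat(sprintf("degree_distribution: support 0..%d, t = %g, kappa = %.3f, g = %.3f\n",
              max(x$k), x$t, kap, homogeneity(x)))
  invisible(x)
}

#' Delta initial distribution
#' @param N support size (degrees `0..N-1`).
#' @param k0 location of the unit mass.
#' @export
delta_distribution <- function(N, k0) {
  p <- numeric(N)
  p[round(k0) + 1] <- 1
  degree_distribution(p, t = 0)
}

#' Per-node transition rates of the topological limit
#'
#' In the topological limit the degree distribution obeys a one-step master
#' equation whose per-node rates combine the two channels of the structural
#' update: gains through selection by the clipped `pi(k)` plus the uniform
#' random-partner channel, and losses through selection by the clipped
#' `eta(k)` plus the random-neighbour channel (proportional to `k/kappa`),
#' i.e. the effective weights `pi~` and `eta~` of the model scaled by the
#' global probabilities. Moments `<k^alpha>`, `<k^gamma>` are computed
#' self-consistently from the current distribution. Rates are per structural
#' step of the whole network; moves that would leave `[0, N-1]` have zero
#' rate.
#'
#' Two rate variants are available: `"powerlaw"` (default) uses the literal
#' one-step rates of the model's master equation -- effective weights
#' proportional to `k^alpha` and `k^gamma`, with the uniform random-partner
#' channel as a floor at low degree -- while `"mc"` is the mean-field image
#' of the stochastic simulation (clipped selection weights renormalised as
#' sampled, saturated nodes excluded), which is the variant to use when
#' validating the integrator against Monte Carlo runs.
#'
#' @param dist a [degree_distribution].
#' @param kappa_inf,n,alpha,gamma model parameters.
#' @param rates `"powerlaw"` or `"mc"` (see Details).
#' @return list with `gain` and `loss` rate vectors over `k = 0..N-1`, and
#'   the global probabilities `u`, `d`.
#' @export
topo_rates <- function(dist, kappa_inf, n, alpha = 1, gamma = 1,
                       rates = c("powerlaw", "mc")) {
  rates <- match.arg(rates)
  k <- dist$k; p <- dist$p; N <- length(p)
  kappa <- sum(k * p)
  if (kappa <= 0) {
    return(list(gain = numeric(N), loss = numeric(N), u = 0, d = 0,
                degenerate = TRUE))
  }
  mka <- sum(k^alpha * p); mkg <- sum(k^gamma * p)
  gp <- global_probs(kappa, n, N, kappa_inf)
  u <- unname(gp["u"]); d <- unname(gp["d"])
  if (rates == "powerlaw") {
    # literal master-equation rates: weights ~ k^alpha, k^gamma, with the
    # uniform random-partner channel as a floor (keeps k = 0 non-absorbing)
    gain <- if (mka > 0) pmax(2 * u * k^alpha / mka, u) else rep(u, N)
    loss <- if (mkg > 0) 2 * d * k^gamma / mkg else rep(0, N)
  } else {
    # MC-faithful mean field: clipped selection weights renormalised as
    # sampled (S = N sum_k p w plays the role of sum_i w_i); each node also
    # gains through the random-partner channel (rate u) and loses through
    # the random-neighbour channel (rate d k / kappa); total
    # degree-increment rate 2Nu gives tau_p = N kappa_inf/(2n). Saturated
    # nodes (k = N-1) are resampled by the MC, hence excluded from the gain
    # normalisations.
    pi_sel <- pmax(2 * k^alpha / (mka * N) - 1 / N, 0)
    S_pi <- N * sum((p * pi_sel)[-N])
    u_partner <- if (p[N] < 1) u / (1 - p[N]) else 0
    gain_sel <- if (S_pi > 0) N * u * pi_sel / S_pi else rep(u_partner, N)
    gain <- gain_sel + u_partner
    eta_sel <- pmax(2 * k^gamma / (mkg * N) - k / (kappa * N), 0)
    S_eta <- N * sum(p * eta_sel)
    loss_nbr <- d * k / kappa
    loss_sel <- if (S_eta > 0) N * d * eta_sel / S_eta else loss_nbr
    loss <- loss_sel + loss_nbr
  }
  gain[N] <- 0  # k = N-1 cannot gain
  loss[1] <- 0  # k = 0 cannot lose
  list(gain = unname(gain), loss = unname(loss),
       u = unname(gp["u"]), d = unname(gp["d"]), degenerate = FALSE)
}

#' Integrate the degree-distribution master equation
#'
#' Explicit Euler integration with an adaptive step bounded by the fastest
#' transition rate (and halved further if any probability would turn
#' negative). Integration stops at `t_end` or as soon as the L1 norm of
#' `dp/dt` falls below `tol`. Normalisation is conserved exactly up to
#' floating-point round-off (the master equation telescopes).
#'
#' @param p0 a [degree_distribution] (or probability vector).
#' @param kappa_inf,n,alpha,gamma model parameters.
#' @param t_end integration horizon in structural steps.
#' @param tol stationarity tolerance on `||dp/dt||_1` (set 0 to integrate to
#'   `t_end` exactly).
#' @param safety Euler step is `safety / max(gain + loss)`.
#' @param max_iter iteration budget.
#' @param rates rate variant, see [topo_rates()].
#' @return list with the final `dist` (a `degree_distribution`), `converged`,
#'   `l1` (final `||dp/dt||_1`), `iterations`, and the sampled mean-degree
#'   trajectory `kappa_traj` (data.frame `t`, `kappa`).
#' @export
integrate_master <- function(p0, kappa_inf, n, alpha = 1, gamma = 1,
                             t_end = Inf, tol = 0, safety = 0.45,
                             max_iter = 5e6, rates = c("powerlaw", "mc")) {
  rates <- match.arg(rates)
  p <- if (inherits(p0, "degree_distribution")) p0$p else as.numeric(p0)
  if (abs(sum(p) - 1) > 1e-8) stop("initial distribution is not normalised")
  if (!is.finite(t_end) && tol <= 0)
    stop("either a finite t_end or a positive tol is required")
  res <- cpp_master(p, kappa_inf, n, alpha, gamma,
                    if (is.finite(t_end)) t_end else 1e300,
                    tol, safety, max_iter, 64L, rates == "mc")
  dist <- degree_distribution(res$p, t = res$t,
                              params = list(kappa_inf = kappa_inf, n = n,
                                            alpha = alpha, gamma = gamma,
                                            rates = rates))
  list(dist = dist, converged = res$converged, l1 = res$l1,
       iterations = res$iterations,
       kappa_traj = data.frame(t = res$t_samples, kappa = res$kappa_samples))
}

#' Stationary degree distribution of the topological limit
#'
#' Integrates the master equation from a delta initial condition until the
#' fixed-point criterion `||dp/dt||_1 < tol` is met, and reports the
#' stationary distribution together with its homogeneity and mean degree.
#'
#' @param N support size.
#' @param kappa_inf,n,alpha,gamma model parameters.
#' @param kappa0 initial mean degree (delta initial condition).
#' @param tol stationarity tolerance.
#' @param max_iter iteration budget; exceeded budget raises an error with
#'   diagnostics.
#' @param rates rate variant, see [topo_rates()].
#' @return list with `dist`, `g`, `kappa`, `l1`, `iterations`.
#' @export
stationary_distribution <- function(N, kappa_inf, n, alpha = 1, gamma = 1,
                                    kappa0 = kappa_inf, tol = 1e-9,
                                    max_iter = 5e6, rates = c("powerlaw", "mc")) {
  p0 <- delta_distribution(N, kappa0)
  res <- integrate_master(p0, kappa_inf, n, alpha, gamma,
                          t_end = Inf, tol = tol, max_iter = max_iter,
                          rates = rates)
  if (!res$converged)
    stop(sprintf(paste0("master equation did not reach ||dp/dt||_1 < %g ",
                        "within %g iterations (final l1 = %.3g, t = %.3g)"),
                 tol, max_iter, res$l1, res$dist$t))
  list(dist = res$dist, g = homogeneity(res$dist),
       kappa = sum(res$dist$k * res$dist$p), l1 = res$l1,
       iterations = res$iterations)
}
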