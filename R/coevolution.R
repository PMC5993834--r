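#' Simulation configuration
#'
#' Collects the parameters of a co-evolution run. Defaults follow the model's
#' reference values: `n = 10` rewired edges and `h_s = 10` neural sweeps per
#' structural step, stationary mean degree `kappa_inf = 10`, single balanced
#' pattern. The pruning timescale is `tau_p = N kappa_inf / (2 n)` structural
#' steps; by default runs last `10 tau_p` and stationary averages are taken
#' over the final quarter of the run.
#'
#' @param N neurons.
#' @param T noise level (temperature). `T = 0` is the deterministic limit.
#' @param alpha growth exponent of the local gain probability.
#' @param gamma loss exponent of the local loss probability.
#' @param n edges added/removed per structural step (rate of the process).
#' @param h_s neural sweeps (MCS) between structural steps.
#' @param kappa0 initial mean degree; default `2 kappa_inf` (pre-pruning
#'   overgrowth, roughly twice the adult density).
#' @param kappa_inf stationary mean degree.
#' @param P number of stored patterns.
#' @param a0 pattern activity level.
#' @param pattern_mode `"uniform"` or `"sparse-block"` (see
#'   [generate_patterns()]).
#' @param ic_kind initial topology: `"homogeneous"` (delta degree
#'   distribution) or `"heterogeneous"` (power-law `k^-2.5` sequence).
#' @param neural_init `"random"` (fair-coin states) or `"pattern"` (clamp to
#'   the first pattern, the retrieval protocol).
#' @param mode `"coupled"` (currents drive edge dynamics) or `"topological"`
#'   (degrees replace currents; neural sweeps are skipped).
#' @param eta_approx use the memory-regime approximation `eta -> eta(I_i)`
#'   that drops the residual `k_i` dependence of the loss probability.
#' @param current_window `"last"` (currents from the final sweep of each
#'   neural window) or `"average"` (window-averaged currents).
#' @param growth_a,growth_tau optional transient growth factor
#'   `a exp(-t/tau_g)` added to the edge-gain probability.
#' @param t_max structural steps to run; default `10 tau_p`.
#' @param record_every record observables every this many structural steps.
#' @param t0_avg,dt_avg stationary-averaging window (structural steps);
#'   defaults to the final quarter of the run.
#' @param seed RNG seed for full reproducibility.
#' @return a `sim_config` list.
#' @export
sim_config <- function(N = 800, T = 1, alpha = 1, gamma = 1, n = 10, h_s = 10,
                       kappa_inf = 10, kappa0 = 2 * kappa_inf, P = 1, a0 = 0.5,
                       pattern_mode = "uniform",
                       ic_kind = c("homogeneous", "heterogeneous"),
                       neural_init = c("random", "pattern"),
                       mode = c("coupled", "topological"),
                       eta_approx = FALSE,
                       current_window = c("last", "average"),
                       growth_a = 0, growth_tau = Inf,
                       t_max = NULL, record_every = NULL,
                       t0_avg = NULL, dt_avg = NULL, seed = 1L) {
  ic_kind <- match.arg(ic_kind)
  neural_init <- match.arg(neural_init)
  mode <- match.arg(mode)
  current_window <- match.arg(current_window)
  stopifnot(N > 1, T >= 0, n >= 1, h_s >= 1, kappa_inf > 0, kappa0 >= 0,
            kappa0 < N - 1, P >= 1, a0 > 0, a0 < 1, growth_a >= 0)
  tau_p <- tau_pruning(N, kappa_inf, n)
  if (is.null(t_max)) t_max <- ceiling(10 * tau_p)
  if (is.null(record_every)) record_every <- max(1L, floor(t_max / 2000))
  if (is.null(t0_avg)) t0_avg <- ceiling(0.75 * t_max)
  if (is.null(dt_avg)) dt_avg <- t_max - t0_avg
  cfg <- list(N = N, T = T, alpha = alpha, gamma = gamma, n = n, h_s = h_s,
              kappa0 = kappa0, kappa_inf = kappa_inf, P = P, a0 = a0,
              pattern_mode = pattern_mode, ic_kind = ic_kind,
              neural_init = neural_init, mode = mode, eta_approx = eta_approx,
              current_window = current_window,
              growth_a = growth_a, growth_tau = growth_tau,
              t_max = as.integer(t_max), record_every = as.integer(record_every),
              t0_avg = t0_avg, dt_avg = dt_avg, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: N=%d T=%g alpha=%g gamma=%g n=%g h_s=%d P=%d a0=%g\n",
              x$N, x$T, x$alpha, x$gamma, x$n, x$h_s, x$P, x$a0))
  cat(sprintf("  kappa0=%g -> kappa_inf=%g (tau_p=%g), mode=%s, ic=%s, t_max=%d, seed=%d\n",
              x$kappa0, x$kappa_inf, tau_pruning(x$N, x$kappa_inf, x$n),
              x$mode, x$ic_kind, x$t_max, x$seed))
  invisible(x)
}

#' Pruning timescale
#'
#' `tau_p = N kappa_inf / (2 n)`, the exponential time constant of the decay
#' of the mean degree towards its stationary value.
#' @param N nodes; @param kappa_inf stationary mean degree; @param n edges
#'   per structural step.
#' @export
tau_pruning <- function(N, kappa_inf, n) N * kappa_inf / (2 * n)

#' Global edge gain/loss probabilities
#'
#' `u(kappa) = (n/N)(1 - kappa/(2 kappa_inf))` and
#' `d(kappa) = (n/N) kappa/(2 kappa_inf)`: growth slows and loss accelerates
#' with density, balancing at `kappa = kappa_inf`. An optional transient
#' growth factor `a exp(-t/tau_g)` models the early overproduction of
#' synapses. `u` is clipped at zero when a growth transient pushes the
#' density above `2 kappa_inf`.
#'
#' @param kappa current mean degree.
#' @param n,N,kappa_inf model parameters.
#' @param t time (structural steps), used by the growth factor.
#' @param growth_a,growth_tau growth-factor amplitude and time constant.
#' @return named vector `c(u = , d = )`.
#' @export
global_probs <- function(kappa, n, N, kappa_inf, t = 0,
                         growth_a = 0, growth_tau = Inf) {
  stopifnot(kappa >= 0)
  u <- (n / N) * (1 - kappa / (2 * kappa_inf))
  if (growth_a > 0) u <- u + growth_a * exp(-t / growth_tau)
  d <- (n / N) * kappa / (2 * kappa_inf)
  c(u = max(u, 0), d = d)
}

#' Local (per-node) gain and loss probabilities
#'
#' Implements the activity-dependent local probabilities
#' `pi(I_i) = 2 I_i^alpha / (<I^alpha> N) - 1/N` and
#' `eta(I_i, k_i) = 2 I_i^gamma / (<I^gamma> N) - k_i/(kappa N)`, clipped at
#' zero and renormalised; these are the node-selection weights of the
#' structural step (`pi_sel`, `eta_sel`). Each gain or loss event also
#' touches a second node -- the uniformly chosen partner, or the uniformly
#' chosen neighbour of the losing node -- so the effective per-node weights
#' are `pi~ = (pi + 1/N)/2` and `eta~ = (eta + k/(kappa N))/2`
#' (returned as `pi_tilde`, `eta_tilde`); with no clipping active they
#' reduce to `I^alpha/(<I^alpha> N)` and `I^gamma/(<I^gamma> N)`. If every
#' current vanishes (fully silent network), gains fall back to uniform and
#' losses to degree-proportional selection.
#'
#' @param I currents (or degrees, in the topological limit), length N.
#' @param deg node degrees.
#' @param alpha,gamma local exponents.
#' @param eta_approx memory-regime approximation `eta -> eta(I_i)`: the loss
#'   selection weight becomes proportional to `I^gamma` alone, dropping the
#'   explicit `k_i` dependence.
#' @return list with `pi`, `eta` (clipped raw probabilities), `pi_sel`,
#'   `eta_sel` (renormalised node-selection weights used for sampling), and
#'   `pi_tilde`, `eta_tilde` (effective per-event weights, both summing
#'   to 1).
#' @export
local_probs <- function(I, deg, alpha = 1, gamma = 1, eta_approx = FALSE) {
  N <- length(I)
  stopifnot(length(deg) == N, all(I >= 0))
  ktot <- sum(deg)  # = kappa * N = 2E
  Ia <- I^alpha; Ig <- I^gamma
  if (sum(Ia) > 0) {
    pi_raw <- pmax(2 * Ia / sum(Ia) - 1 / N, 0)
  } else {
    pi_raw <- rep(0, N)
  }
  pi_sel <- if (sum(pi_raw) > 0) pi_raw / sum(pi_raw) else rep(1 / N, N)
  if (eta_approx && sum(Ig) > 0) {
    eta_raw <- Ig / sum(Ig)
  } else if (sum(Ig) > 0 && ktot > 0) {
    eta_raw <- pmax(2 * Ig / sum(Ig) - deg / ktot, 0)
  } else {
    eta_raw <- rep(0, N)
  }
  eta_sel <- if (sum(eta_raw) > 0) eta_raw / sum(eta_raw)
             else if (ktot > 0) deg / ktot
             else rep(0, N)
  list(pi = pi_raw, eta = eta_raw,
       pi_sel = pi_sel, eta_sel = eta_sel,
       pi_tilde = (pi_sel + 1 / N) / 2,
       eta_tilde = if (ktot > 0) (eta_sel + deg / ktot) / 2 else eta_sel)
}

#' One structural update of the network
#'
#' Draws the numbers of edge gains and losses from Poisson distributions with
#' means `N u` and `N d`, then executes them in random interleaved order:
#' each gain picks a node by cumulative-weight (rejection-free) sampling on
#' `pi_sel` and a partner uniformly among its non-neighbours; each loss
#' picks a node by `eta_sel` and removes a uniformly chosen incident edge.
#' The uniform partner / neighbour choices realize the second channel of the
#' effective weights `pi~`, `eta~`. Infeasible draws (saturated or isolated
#' nodes) are resampled a bounded number of times and finally counted as
#' skipped.
#'
#' @param network an [sp_network].
#' @param pi_sel,eta_sel node-selection weights from [local_probs()].
#' @param u,d global probabilities from [global_probs()].
#' @return list with the updated `network` and a `report` of counts
#'   (`added`, `removed`, `skipped_gains`, `skipped_losses`).
#' @export
structural_step <- function(network, pi_sel, eta_sel, u, d) {
  stopifnot(length(pi_sel) == network$N, length(eta_sel) == network$N,
            u >= 0, d >= 0)
  res <- cpp_structural_step(network$edges, network$N,
                             pi_sel, eta_sel, u, d)
  list(network = sp_network(res$edges, network$N),
       report = res[c("added", "removed", "skipped_gains", "skipped_losses")])
}

#' Run the co-evolving network model
#'
#' Alternates `h_s` synchronous neural sweeps with one structural edge update
#' for `t_max` structural steps, recording the macroscopic observables
#' (mean degree, overlaps, activity, homogeneity, assortativity) along the
#' way. In `"topological"` mode the neural sweeps are skipped and degrees
#' replace currents in the edge dynamics. The run is fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param patterns optional pre-built `pattern_set` (generated from the
#'   config otherwise).
#' @param network optional initial `sp_network`.
#' @param states0 optional initial 0/1 states.
#' @return a `coevolution_run`: list with `trajectory` (data.frame `t`,
#'   `kappa`, `M`, `g`, `r`, `m.1..m.P`, `m_best`), final `network`,
#'   `states`, `currents`, pooled stationary `deg_hist` (counts over the
#'   averaging window, degrees `0..N-1`), `knn` (data.frame), the `config`,
#'   the generating `patterns`, and bookkeeping `report`.
#' @export
run_coevolution <- function(config, patterns = NULL, network = NULL,
                            states0 = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(patterns))
    patterns <- generate_patterns(config$N, config$P, config$a0,
                                  mode = config$pattern_mode)
  if (is.null(network))
    network <- initial_network(config$N, config$kappa0, config$ic_kind)
  if (is.null(states0)) {
    states0 <- if (config$neural_init == "pattern") as.integer(patterns[1, ])
               else as.integer(runif(config$N) < 0.5)
  }
  W <- if (config$mode == "coupled")
    hebbian_weights(patterns, config$kappa_inf)
  else
    matrix(0, 1, 1)  # unused in the topological limit
  avg_start <- config$t0_avg
  res <- cpp_coevolve(network$edges, config$N, unclass(W),
                      t(unclass(patterns)) * 1.0, config$a0,
                      as.integer(states0), config$T, config$alpha,
                      config$gamma, config$n, config$kappa_inf,
                      config$growth_a, config$growth_tau,
                      as.integer(config$h_s), config$t_max,
                      config$mode == "topological", config$eta_approx,
                      config$current_window == "average",
                      config$record_every, as.integer(avg_start))
  m <- res$m
  colnames(m) <- paste0("m.", seq_len(ncol(m)))
  traj <- data.frame(t = res$t, kappa = res$kappa, M = res$M,
                     g = res$g, r = res$r, m)
  traj$m_best <- apply(abs(m), 1, max)
  knn_k <- which(res$knn_cnt > 0)
  knn <- data.frame(k = knn_k - 1L,
                    knn = res$knn_sum[knn_k] / res$knn_cnt[knn_k],
                    weight = res$knn_cnt[knn_k])
  out <- list(trajectory = traj,
              network = sp_network(res$edges, config$N),
              states = res$states, currents = res$currents,
              deg_hist = as.numeric(res$deg_hist), knn = knn,
              patterns = patterns, config = config,
              report = list(skipped_gains = res$skipped_gains,
                            skipped_losses = res$skipped_losses))
  class(out) <- "coevolution_run"
  out
}

#' @export
print.coevolution_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("coevolution_run (%s): N=%d, %d structural steps recorded\n",
              x$config$mode, x$config$N, nrow(tr)))
  cat(sprintf("  final: kappa=%.2f g=%.3f r=%s m_best=%s\n",
              tail(tr$kappa, 1), tail(tr$g, 1),
              format(tail(tr$r, 1), digits = 3),
              format(tail(tr$m_best, 1), digits = 3)))
  invisible(x)
}

#' Compare a simulated mean-degree trajectory with its closed form
#'
#' The mean degree decouples from the local dynamics and follows
#' `kappa(t) = (kappa0 - kappa_inf) exp(-t/tau_p) + kappa_inf` with
#' `tau_p = N kappa_inf/(2n)`. Returns the sup-norm deviation between the
#' recorded trajectory and the closed form, relative to `kappa_inf`.
#'
#' @param run a `coevolution_run` (or a trajectory data.frame with `t`,
#'   `kappa`).
#' @param N,kappa0,kappa_inf,n model parameters; taken from the run's config
#'   when available.
#' @return maximum relative deviation.
#' @export
kappa_trajectory_check <- function(run, N = NULL, kappa0 = NULL,
                                   kappa_inf = NULL, n = NULL) {
  if (inherits(run, "coevolution_run")) {
    cfg <- run$config
    N <- cfg$N; kappa0 <- cfg$kappa0; kappa_inf <- cfg$kappa_inf; n <- cfg$n
    traj <- run$trajectory
  } else traj <- run
  tau <- tau_pruning(N, kappa_inf, n)
  expected <- (kappa0 - kappa_inf) * exp(-traj$t / tau) + kappa_inf
  max(abs(traj$kappa - expected)) / kappa_inf
}
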