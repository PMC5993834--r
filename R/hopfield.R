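#' Local fields, thresholds and currents of the attractor network
#'
#' The local field at neuron i is `h_i = sum_j w_ij e_ij s_j`, summing only
#' over edges present in the network; the firing threshold is half the sum of
#' incident weights, `theta_i = (1/2) sum_j w_ij e_ij`; the incoming current is
#' `I_i = |h_i - theta_i|`, the physiological variable that drives edge growth
#' and death in the coupled model.
#'
#' @param network an [sp_network].
#' @param couplings a [hebbian_weights] coupling matrix.
#' @param states 0/1 vector of neuron states, length N.
#' @return numeric vector of length N.
#' @export
local_fields <- function(network, couplings, states) {
  stopifnot(length(states) == network$N, nrow(couplings) == network$N)
  h <- numeric(network$N)
  e <- network$edges
  if (nrow(e) > 0) {
    w <- couplings[e]                      # w_ij per edge
    contrib_i <- w * states[e[, 2]]        # j firing feeds i
    contrib_j <- w * states[e[, 1]]
    acc <- rowsum(c(contrib_i, contrib_j), group = c(e[, 1], e[, 2]))
    h[as.integer(rownames(acc))] <- acc[, 1]
  }
  h
}

#' @rdname local_fields
#' @export
thresholds <- function(network, couplings) {
  stopifnot(nrow(couplings) == network$N)
  th <- numeric(network$N)
  e <- network$edges
  if (nrow(e) > 0) {
    w <- couplings[e]
    acc <- rowsum(c(w, w), group = c(e[, 1], e[, 2]))
    th[as.integer(rownames(acc))] <- acc[, 1]
  }
  th / 2
}

#' @rdname local_fields
#' @param fields local fields as returned by [local_fields()].
#' @param thresh thresholds as returned by [thresholds()].
#' @export
currents <- function(fields, thresh) abs(fields - thresh)

#' One synchronous stochastic update of all neuron states
#'
#' Every neuron fires at the next step with probability
#' `P(s_i = 1) = (1 + tanh(2 beta (h_i - theta_i))) / 2`, with `beta = 1/T`.
#' This is heat-bath dynamics for the equivalent +/-1 spins (whose local field
#' is `2(h_i - theta_i)`), the temperature convention under which the fully
#' connected reference model has its continuous transition at `T = 1`.
#' The noiseless limit `T = 0` is handled explicitly as a sign rule
#' (`s_i <- 1` if `h_i > theta_i`, 0 if below, fair coin on ties) to avoid
#' overflow at large `beta`.
#'
#' @param states 0/1 state vector.
#' @param fields local fields.
#' @param thresh thresholds.
#' @param T noise level (temperature); `T = 0` for deterministic dynamics.
#' @return updated 0/1 integer vector.
#' @export
update_states <- function(states, fields, thresh, T) {
  x <- fields - thresh
  if (T == 0) {
    s <- ifelse(x > 0, 1L, ifelse(x < 0, 0L, NA_integer_))
    ties <- is.na(s)
    if (any(ties)) s[ties] <- as.integer(runif(sum(ties)) < 0.5)
    return(s)
  }
  p <- 0.5 * (1 + tanh(2 * x / T))
  as.integer(runif(length(states)) < p)
}

#' Overlap with a stored pattern
#'
#' `m = (N a0 (1 - a0))^-1 sum_i (xi_i - a0) s_i`; equals 1 when the states
#' reproduce the pattern (for a pattern whose realized activity is exactly a0)
#' and fluctuates around 0 for uncorrelated states.
#'
#' @param states 0/1 state vector.
#' @param pattern 0/1 vector for one pattern.
#' @param a0 mean pattern activity in (0, 1).
#' @return signed overlap in \[-1, 1\] (up to sampling fluctuations of the
#'   pattern activity).
#' @export
overlap <- function(states, pattern, a0) {
  stopifnot(a0 > 0, a0 < 1, length(states) == length(pattern))
  sum((pattern - a0) * states) / (length(states) * a0 * (1 - a0))
}

#' Mean network activity
#' @param states 0/1 state vector.
#' @return fraction of firing neurons.
#' @export
mean_activity <- function(states) mean(states)

#' Run Hopfield dynamics on a fixed network
#'
#' Performs `n_sweeps` synchronous sweeps at noise level `T` on a fixed graph
#' (the canonical fully connected reference network when `network = NULL`),
#' recording the overlap with every stored pattern and the mean activity at
#' each sweep.
#'
#' @param couplings coupling matrix.
#' @param patterns `pattern_set` used for overlap bookkeeping.
#' @param network `sp_network`, or NULL for the complete graph.
#' @param states0 initial 0/1 states; defaults to the first pattern.
#' @param T noise level.
#' @param n_sweeps number of synchronous sweeps.
#' @return list with `trajectory` (data.frame: sweep, M, m.1..m.P), final
#'   `states`, `fields`, `thresholds`.
#' @export
run_hopfield <- function(couplings, patterns, network = NULL,
                         states0 = NULL, T = 1, n_sweeps = 100) {
  N <- ncol(patterns)
  a0 <- attr(patterns, "a0")
  if (is.null(states0)) states0 <- as.integer(patterns[1, ])
  edges <- if (is.null(network)) NULL else network$edges
  res <- cpp_hopfield(unclass(couplings), edges, N, as.integer(states0),
                      T, as.integer(n_sweeps), t(unclass(patterns)) * 1.0, a0)
  m <- res$m
  colnames(m) <- paste0("m.", seq_len(ncol(m)))
  traj <- data.frame(sweep = seq_len(n_sweeps), M = res$M, m)
  list(trajectory = traj, states = res$states,
       fields = res$fields, thresholds = res$thresholds)
}

#' Stationary overlap of the reference Hopfield model on a temperature grid
#'
#' Scans the noise level of the fully connected Amari-Hopfield network with
#' `P` stored patterns, starting each run at the first pattern and averaging
#' the overlap magnitude over the second half of the sweeps. The canonical
#' single-pattern model has its continuous transition at `T = 1`.
#'
#' @param T_grid noise levels to scan.
#' @param N system size.
#' @param replicates independent runs per grid point.
#' @param n_sweeps sweeps per run (second half is averaged).
#' @param a0,P pattern statistics for the reference model.
#' @return data.frame with columns `T`, `m_bar`, `sd`.
#' @export
hopfield_transition_scan <- function(T_grid, N = 800, replicates = 10,
                                     n_sweeps = 400, a0 = 0.5, P = 1) {
  rows <- lapply(T_grid, function(Tv) {
    ms <- vapply(seq_len(replicates), function(rep) {
      xi <- generate_patterns(N, P, a0)
      W <- hebbian_weights(xi, kappa_inf = N - 1)  # kappa_inf = N-1 on the full graph
      run <- run_hopfield(W, xi, network = NULL, T = Tv, n_sweeps = n_sweeps)
      keep <- run$trajectory$sweep > n_sweeps / 2
      mean(abs(run$trajectory$m.1[keep]))
    }, numeric(1))
    data.frame(T = Tv, m_bar = mean(ms), sd = sd(ms))
  })
  do.call(rbind, rows)
}

#' Grid location of the steepest drop of a curve
#'
#' Returns the midpoint of the grid interval with the most negative finite
#' difference; used to locate transition temperatures on a scanned grid.
#' @param x grid values (increasing).
#' @param y curve values.
#' @export
steepest_drop <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- diff(y) / diff(x)
  i <- which.min(d)
  (x[i] + x[i + 1]) / 2
}
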