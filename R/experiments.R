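#' Classify the stationary phase of a run
#'
#' Deterministic thresholds on the stationary order parameters: memory when
#' the best-pattern overlap magnitude exceeds `m_thr`, heterogeneous when
#' the homogeneity falls below `g_thr`. The phases of the model are
#' `homogeneous-memory` (high m, high g), `heterogeneous-memory` (high m,
#' very low g, disassortative), `homogeneous-noisy` (low m, high g), and a
#' spin-glass-like label when several patterns are partially retrieved at
#' once. When stats for the two initial conditions are both supplied and
#' disagree, the point is `bistable`.
#'
#' @param stats a `stationary_stats` (one IC), or list of two for
#'   homogeneous/heterogeneous ICs.
#' @param stats_het optional second `stationary_stats` (heterogeneous IC).
#' @param m_thr,g_thr,r_thr classification thresholds.
#' @param n_retrieved number of patterns with overlap above the SG
#'   threshold (see [count_retrieved()]); >= 2 marks the SG state.
#' @return character label.
#' @export
classify_phase <- function(stats, stats_het = NULL, m_thr = 0.5, g_thr = 0.2,
                           r_thr = -0.05, n_retrieved = 1) {
  one <- function(s, nr) {
    if (!isTRUE(s$stationary)) return("unresolved")
    mem <- !is.na(s$m_bar) && s$m_bar > m_thr
    het <- s$g_bar < g_thr
    if (mem && nr >= 2) return("SG")
    if (mem && het) return("heterogeneous-memory")
    if (mem) return("homogeneous-memory")
    if (het) return("heterogeneous-noisy")
    "homogeneous-noisy"
  }
  lab <- one(stats, n_retrieved)
  if (is.null(stats_het)) return(lab)
  lab2 <- one(stats_het, n_retrieved)
  if (lab != lab2) "bistable" else lab
}

#' Number of simultaneously retrieved patterns
#'
#' Counts patterns whose stationary overlap magnitude exceeds `thr`
#' (default 0.3); two or more mark a spin-glass-like state.
#' @param run a `coevolution_run`.
#' @param thr retrieval threshold.
#' @param window averaging window `c(t0, dt)`; defaults to the config's.
#' @export
count_retrieved <- function(run, thr = 0.3, window = NULL) {
  cfg <- run$config
  if (is.null(window)) window <- c(cfg$t0_avg, cfg$dt_avg)
  tr <- run$trajectory
  w <- tr$t >= window[1] & tr$t <= window[1] + window[2]
  mcols <- grep("^m\\.", names(tr), value = TRUE)
  mbar <- vapply(mcols, function(cn) mean(abs(tr[[cn]][w])), numeric(1))
  sum(mbar > thr)
}

#' Run replicated co-evolution at one parameter point
#'
#' @param config a [sim_config()] template (its seed is offset per
#'   replicate).
#' @param replicates number of independent runs.
#' @return list with per-replicate `stats`, pooled means, pooled
#'   `deg_hist`, pooled `knn` data, and the runs' SG retrieval counts.
#' @export
replicate_runs <- function(config, replicates = 10) {
  stats <- vector("list", replicates)
  nret <- integer(replicates)
  deg_hist <- numeric(config$N)
  knn_sum <- numeric(config$N); knn_cnt <- numeric(config$N)
  for (rep in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (rep - 1L)
    run <- run_coevolution(cfg)
    stats[[rep]] <- suppressWarnings(
      stationary_average(run$trajectory, cfg$t0_avg, cfg$dt_avg))
    nret[rep] <- count_retrieved(run)
    deg_hist <- deg_hist + run$deg_hist
    idx <- run$knn$k + 1L
    knn_sum[idx] <- knn_sum[idx] + run$knn$knn * run$knn$weight
    knn_cnt[idx] <- knn_cnt[idx] + run$knn$weight
  }
  pool <- function(f) {
    v <- vapply(stats, `[[`, numeric(1), f)
    c(mean = mean(v, na.rm = TRUE), sd = sd(v))
  }
  kk <- which(knn_cnt > 0)
  list(stats = stats,
       m_bar = pool("m_bar"), m1_bar = pool("m1_bar"), M_bar = pool("M_bar"),
       g_bar = pool("g_bar"), r_bar = pool("r_bar"),
       n_retrieved = nret,
       deg_hist = deg_hist,
       knn = data.frame(k = kk - 1L, knn = knn_sum[kk] / knn_cnt[kk],
                        weight = knn_cnt[kk]))
}

#' Phase-diagram sweep
#'
#' Runs replicated simulations over a grid of `alpha` and noise levels
#' (or pattern loads), for one or both initial-condition kinds, classifies
#' every grid point and flags bistability where the two ICs settle in
#' different phases.
#'
#' @param alpha_grid growth exponents to scan.
#' @param T_grid noise levels to scan (use a single value with `P_grid` for
#'   capacity-style diagrams).
#' @param config a [sim_config()] template.
#' @param ics initial-condition kinds to run.
#' @param replicates runs per point and IC.
#' @param P_grid optional pattern loads (overrides the config's P; `a0` is
#'   set to `1/P` when `sparse = TRUE`).
#' @param sparse use sparse-block patterns with `a0 = 1/P`.
#' @return data.frame, one row per grid point, with stationary means per IC
#'   and the phase label.
#' @export
phase_sweep <- function(alpha_grid, T_grid, config,
                        ics = c("homogeneous", "heterogeneous"),
                        replicates = 10, P_grid = NULL, sparse = FALSE) {
  grid2 <- if (is.null(P_grid)) T_grid else P_grid
  rows <- list()
  for (a in alpha_grid) for (x in grid2) {
    res_ic <- list()
    for (ic in ics) {
      cfg <- config
      cfg$alpha <- a
      if (is.null(P_grid)) cfg$T <- x
      else {
        cfg$P <- as.integer(x)
        if (sparse) { cfg$a0 <- 1 / x; cfg$pattern_mode <- "sparse-block" }
      }
      cfg$ic_kind <- ic
      res_ic[[ic]] <- replicate_runs(cfg, replicates)
    }
    s1 <- res_ic[[1]]
    mean_stats <- function(r) list(m_bar = unname(r$m_bar["mean"]),
                                   g_bar = unname(r$g_bar["mean"]),
                                   r_bar = unname(r$r_bar["mean"]),
                                   stationary = TRUE)
    lab <- if (length(ics) == 2)
      classify_phase(mean_stats(res_ic[[1]]), mean_stats(res_ic[[2]]),
                     n_retrieved = max(1, round(mean(s1$n_retrieved))))
    else classify_phase(mean_stats(s1),
                        n_retrieved = max(1, round(mean(s1$n_retrieved))))
    row <- data.frame(alpha = a,
                      T = if (is.null(P_grid)) x else config$T,
                      P = if (is.null(P_grid)) config$P else x,
                      phase = lab)
    for (ic in ics) {
      r <- res_ic[[ic]]
      tag <- substr(ic, 1, 3)
      row[[paste0("m_", tag)]] <- unname(r$m_bar["mean"])
      row[[paste0("g_", tag)]] <- unname(r$g_bar["mean"])
      row[[paste0("r_", tag)]] <- unname(r$r_bar["mean"])
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Memory-capacity curve
#'
#' For each pattern load P, stores P patterns (random `a0 = 0.5`, or sparse
#' blocks with `a0 = 1/P`), initializes the states at the first pattern,
#' co-evolves at `T = 0` to stationarity and reports the stationary overlap
#' of the best-matching ("recovered") pattern, averaged over replicates.
#' Set `mode = "topological"` for the decoupled limit, where the network
#' evolves by degrees alone and retrieval is then measured by relaxing the
#' neural dynamics on the evolved graph.
#'
#' @param P_grid pattern loads.
#' @param config a [sim_config()] template (T is forced to 0;
#'   `neural_init = "pattern"`).
#' @param sparse sparse patterns with `a0 = 1/P` (otherwise `a0 = 0.5`).
#' @param replicates runs per load.
#' @param relax_sweeps neural relaxation sweeps for the topological mode.
#' @return data.frame with `P`, `m_recovered` (mean), `sd`,
#'   `m_retrieved_mean` (mean overlap of all patterns above the retrieval
#'   threshold), `n_retrieved`.
#' @export
capacity_curve <- function(P_grid, config, sparse = TRUE, replicates = 10,
                           relax_sweeps = 200) {
  rows <- list()
  for (P in P_grid) {
    cfg <- config
    cfg$T <- 0
    cfg$P <- as.integer(P)
    cfg$neural_init <- "pattern"
    if (sparse) { cfg$a0 <- 1 / P; cfg$pattern_mode <- "sparse-block" }
    else { cfg$a0 <- 0.5; cfg$pattern_mode <- "uniform" }
    if (cfg$a0 * cfg$N < 1) stop("P too large: patterns would be empty")
    mrec <- numeric(replicates)
    mret <- numeric(replicates)
    nret <- integer(replicates)
    for (rep in seq_len(replicates)) {
      cfg$seed <- config$seed + 1000L * (rep - 1L) + P
      if (cfg$mode == "coupled") {
        run <- run_coevolution(cfg)
        tr <- run$trajectory
        w <- tr$t >= cfg$t0_avg
        mcols <- grep("^m\\.", names(tr), value = TRUE)
        mbar <- vapply(mcols, function(cn) mean(abs(tr[[cn]][w])), numeric(1))
      } else {
        run <- run_coevolution(cfg)  # degree-driven evolution only
        W <- hebbian_weights(run$patterns, cfg$kappa_inf)
        relax <- run_hopfield(W, run$patterns, network = run$network,
                              states0 = as.integer(run$patterns[1, ]),
                              T = 0, n_sweeps = relax_sweeps)
        keep <- relax$trajectory$sweep > relax_sweeps / 2
        mbar <- vapply(grep("^m\\.", names(relax$trajectory), value = TRUE),
                       function(cn) mean(abs(relax$trajectory[[cn]][keep])),
                       numeric(1))
      }
      mrec[rep] <- max(mbar)
      retrieved <- mbar[mbar > 0.3]
      mret[rep] <- if (length(retrieved)) mean(retrieved) else 0
      nret[rep] <- length(retrieved)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(P = P, m_recovered = mean(mrec), sd = sd(mrec),
                 m_retrieved_mean = mean(mret), n_retrieved = mean(nret))
  }
  do.call(rbind, rows)
}

#' Structural statistics along the critical line
#'
#' Pools the stationary degree distribution, neighbour-degree function and
#' clustering spectrum of replicated coupled runs (by default at the
#' scale-free point T = 0.5, alpha = 1.05) and fits the three tail
#' exponents: `p(k) ~ k^-mu`, `k_nn(k) ~ k^-v`, `C(k) ~ k^-theta`.
#'
#' @param config a [sim_config()]; defaults tuned for the critical line.
#' @param replicates independent runs pooled.
#' @param k_min tail cutoff; defaults to `kappa_inf`.
#' @return list with `p_fit` (a `tail_fit`), `knn_fit`, `C_fit`
#'   (log-log slopes), the pooled `deg_hist`, `knn`, and `C_spec`.
#' @export
protein_stats_run <- function(config, replicates = 20, k_min = NULL) {
  if (is.null(k_min)) k_min <- config$kappa_inf
  pool <- replicate_runs(config, replicates)
  # clustering spectrum from the final network of a few replicates
  C_acc <- NULL
  for (rep in seq_len(min(replicates, 5))) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (rep - 1L)
    run <- run_coevolution(cfg)
    cs <- clustering_spectrum(run$network)
    C_acc <- rbind(C_acc, cs)
  }
  C_spec <- do.call(rbind, lapply(split(C_acc, C_acc$k), function(d)
    data.frame(k = d$k[1], C = sum(d$C * d$n_nodes) / sum(d$n_nodes),
               n_nodes = sum(d$n_nodes))))
  ks <- seq_along(pool$deg_hist) - 1
  p_fit <- fit_tail_exponent(ks, counts = pool$deg_hist, k_min = k_min)
  knn_fit <- fit_loglog_slope(pool$knn$k, pool$knn$knn, k_min = k_min,
                              weights = pool$knn$weight)
  C_fit <- tryCatch(fit_loglog_slope(C_spec$k, C_spec$C, k_min = k_min,
                                     weights = C_spec$n_nodes),
                    error = function(e) list(exponent = NA_real_, se = NA_real_))
  list(p_fit = p_fit, knn_fit = knn_fit, C_fit = C_fit,
       deg_hist = pool$deg_hist, knn = pool$knn, C_spec = C_spec,
       order_params = pool[c("m_bar", "g_bar", "r_bar")])
}
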