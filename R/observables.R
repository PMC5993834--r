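#' Degree homogeneity
#'
#' `g = exp(-sigma^2 / kappa^2)` of the degree distribution: 1 for regular
#' (zero-variance) degrees, tending to 0 for heterogeneous (e.g. bimodal)
#' ones. Accepts a network, a raw degree vector, or a `degree_distribution`.
#'
#' @param x an [sp_network], numeric degree vector, or
#'   [degree_distribution].
#' @param ... unused.
#' @return homogeneity in (0, 1].
#' @export
homogeneity <- function(x, ...) UseMethod("homogeneity")

#' @export
homogeneity.sp_network <- function(x, ...) homogeneity(as.numeric(degrees(x)))

#' @export
homogeneity.degree_distribution <- function(x, ...) {
  kap <- sum(x$k * x$p)
  if (kap <= 0) stop("homogeneity undefined for kappa = 0")
  v <- sum(x$k^2 * x$p) - kap^2
  exp(-v / kap^2)
}

#' @export
homogeneity.default <- function(x, ...) {
  kap <- mean(x)
  if (kap <= 0) stop("homogeneity undefined for kappa = 0")
  v <- mean(x^2) - kap^2  # population variance
  exp(-v / kap^2)
}

#' Mean degree of the nearest neighbours, per degree class
#'
#' `k_nn,i = k_i^-1 sum_j a_ij k_j`, averaged over nodes of equal degree.
#' Nodes of degree zero are excluded.
#'
#' @param network an [sp_network].
#' @return data.frame with columns `k`, `knn`, `n_nodes`.
#' @export
knn_function <- function(network) {
  k <- degrees(network)
  e <- network$edges
  nbr_deg_sum <- numeric(network$N)
  acc <- rowsum(c(k[e[, 2]], k[e[, 1]]), group = c(e[, 1], e[, 2]))
  nbr_deg_sum[as.integer(rownames(acc))] <- acc[, 1]
  keep <- k > 0
  knn_i <- nbr_deg_sum[keep] / k[keep]
  agg <- rowsum(cbind(knn_i, 1), group = k[keep])
  data.frame(k = as.integer(rownames(agg)), knn = agg[, 1] / agg[, 2],
             n_nodes = as.integer(agg[, 2]))
}

#' Degree assortativity (edge Pearson coefficient)
#'
#' Pearson correlation of degrees across edge ends. Both the direct
#' edge-based average and the algebraically identical estimate through the
#' neighbour-degree function,
#' `r = (<k><k^2 k_nn(k)> - <k^2>^2) / (<k><k^3> - <k^2>^2)`,
#' are available and agree to numerical precision on any graph. For regular
#' graphs the coefficient is undefined (0/0) and `NA` is returned.
#'
#' @param network an [sp_network].
#' @param method `"edges"` or `"knn"`.
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(network, method = c("edges", "knn")) {
  method <- match.arg(method)
  k <- as.numeric(degrees(network))
  e <- network$edges
  if (nrow(e) == 0) return(NA_real_)
  if (method == "edges") {
    x <- c(k[e[, 1]], k[e[, 2]])
    y <- c(k[e[, 2]], k[e[, 1]])
    mx <- mean(x)
    den <- mean(x^2) - mx^2
    if (den < 1e-14) return(NA_real_)
    (mean(x * y) - mx^2) / den
  } else {
    nbr_deg_sum <- numeric(network$N)
    acc <- rowsum(c(k[e[, 2]], k[e[, 1]]), group = c(e[, 1], e[, 2]))
    nbr_deg_sum[as.integer(rownames(acc))] <- acc[, 1]
    knn_i <- ifelse(k > 0, nbr_deg_sum / pmax(k, 1), 0)
    m1 <- mean(k); m2 <- mean(k^2); m3 <- mean(k^3)
    den <- m1 * m3 - m2^2
    if (den < 1e-14 * max(m3, 1)) return(NA_real_)
    (m1 * mean(k^2 * knn_i) - m2^2) / den
  }
}

#' Local clustering coefficients and clustering spectrum
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))` where `t_i` counts triangles through node
#' i; the spectrum averages `C_i` over nodes of equal degree (`k >= 2` only).
#'
#' @param network an [sp_network].
#' @return `local_clustering`: numeric vector (NA for `k < 2`);
#'   `clustering_spectrum`: data.frame `k`, `C`, `n_nodes`.
#' @export
local_clustering <- function(network) {
  N <- network$N
  k <- degrees(network)
  adj <- adj_list(network)
  Ci <- rep(NA_real_, N)
  for (i in which(k >= 2)) {
    nb <- adj[[i]]
    ti <- 0L
    nbset <- nb
    for (j in nb) ti <- ti + sum(adj[[j]] %in% nbset)
    Ci[i] <- ti / (k[i] * (k[i] - 1))  # each triangle counted twice in ti
  }
  Ci
}

#' @rdname local_clustering
#' @export
clustering_spectrum <- function(network) {
  k <- degrees(network)
  Ci <- local_clustering(network)
  keep <- !is.na(Ci)
  if (!any(keep)) return(data.frame(k = integer(0), C = numeric(0),
                                    n_nodes = integer(0)))
  agg <- rowsum(cbind(Ci[keep], 1), group = k[keep])
  data.frame(k = as.integer(rownames(agg)), C = agg[, 1] / agg[, 2],
             n_nodes = as.integer(agg[, 2]))
}

#' Discrete power-law tail fit
#'
#' Maximum-likelihood fit of `p(k) ~ k^-mu` for `k >= k_min` on a bounded
#' support, for either a sample of degrees or a tabulated distribution
#' (counts/probabilities per degree). When `k_min` is `NULL` it is chosen by
#' minimising the Kolmogorov-Smirnov distance between the fitted and
#' empirical tail distributions over the candidate cutoffs. A log-binned
#' least-squares slope is provided as a cross-check method.
#'
#' @param k degree observations (method `"mle"`/`"logbin"` with
#'   `counts = NULL`), or the support values when `counts` is given.
#' @param counts optional weights (counts or probabilities) matching `k`.
#' @param k_min lower cutoff of the fitted tail; `NULL` for KS selection.
#' @param k_max upper end of the modelled support; defaults to
#'   `max(10 * max(k), 1e5)` (effectively unbounded for steep tails).
#' @param method `"mle"` (default) or `"logbin"`.
#' @return a `tail_fit`: list with `exponent`, `se`, `k_min`, `ks`
#'   (goodness statistic), `n_tail`, `method`.
#' @export
fit_tail_exponent <- function(k, counts = NULL, k_min = NULL, k_max = NULL,
                              method = c("mle", "logbin")) {
  method <- match.arg(method)
  if (is.null(counts)) {
    tab <- table(k[k >= 1])
    kk <- as.numeric(names(tab))
    w <- as.numeric(tab)
  } else {
    keep <- counts > 0 & k >= 1
    kk <- as.numeric(k[keep]); w <- as.numeric(counts[keep])
  }
  if (length(kk) < 2) stop("degenerate support: nothing to fit")
  if (is.null(k_max)) k_max <- max(10 * max(kk), 1e5)
  fit_at <- function(kmin) {
    sel <- kk >= kmin
    ks_vals <- kk[sel]; ws <- w[sel]
    n <- sum(ws)
    support <- seq(kmin, k_max)
    slog <- sum(ws * log(ks_vals)) / n
    nll <- function(mu) mu * slog + log(sum(support^(-mu)))
    opt <- optimize(nll, c(1.01, 8))
    mu <- opt$minimum
    # KS distance between fitted and empirical tail CDFs
    pfit <- support^(-mu); pfit <- pfit / sum(pfit)
    cdf_fit <- cumsum(pfit)
    emp <- numeric(length(support))
    emp[match(ks_vals, support)] <- ws / n
    cdf_emp <- cumsum(emp)
    ks_stat <- max(abs(cdf_fit - cdf_emp))
    # curvature of the mean negative log-likelihood; total information n * d2
    hh <- 1e-4
    d2 <- (nll(mu + hh) - 2 * nll(mu) + nll(mu - hh)) / hh^2
    # a standard error is meaningful only when the weights are real counts
    se <- if (d2 > 0 && n > 1.5) 1 / sqrt(n * d2) else NA_real_
    list(exponent = mu, se = se, k_min = kmin, ks = ks_stat, n_tail = n)
  }
  if (method == "logbin") {
    kmin <- if (is.null(k_min)) min(kk) else k_min
    sel <- kk >= kmin
    ks_vals <- kk[sel]; ws <- w[sel]
    breaks <- 2^seq(floor(log2(kmin)), ceiling(log2(max(ks_vals) + 1)))
    bin <- findInterval(ks_vals, breaks, rightmost.closed = TRUE)
    bins_used <- sort(unique(bin))
    mass <- as.numeric(tapply(ws, factor(bin, levels = bins_used), sum))
    dens <- mass / diff(breaks)[bins_used]
    ctr <- sqrt(breaks[bins_used] * breaks[bins_used + 1])
    # weight bins by their probability mass so that the far tail (vanishing
    # density) does not dominate the regression
    ok <- dens > 0 & !is.na(dens) & mass > 1e-9 * sum(mass)
    if (sum(ok) < 3) stop("too few occupied log bins above k_min")
    fit <- lm(log(dens[ok]) ~ log(ctr[ok]), weights = mass[ok])
    return(structure(list(exponent = -unname(coef(fit)[2]),
                          se = unname(sqrt(diag(vcov(fit)))[2]),
                          k_min = kmin, ks = NA_real_, n_tail = sum(ws),
                          method = "logbin"),
                     class = "tail_fit"))
  }
  if (!is.null(k_min)) {
    out <- fit_at(k_min)
  } else {
    cands <- sort(unique(kk))
    cands <- cands[cands <= quantile(rep(kk, pmax(round(w), 1)), 0.9)]
    if (length(cands) > 30) cands <- cands[unique(round(seq(1, length(cands),
                                                            length.out = 30)))]
    fits <- lapply(cands, fit_at)
    fits <- Filter(function(f) f$n_tail >= 10, fits)
    if (length(fits) == 0) stop("no viable k_min candidate")
    out <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  }
  out$method <- "mle"
  class(out) <- "tail_fit"
  out
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("tail_fit (%s): exponent = %.3f (se %.3f), k_min = %g, KS = %.4f, n = %g\n",
              x$method, x$exponent, x$se, x$k_min, x$ks, x$n_tail))
  invisible(x)
}

#' Log-log least-squares decay exponent of a spectrum
#'
#' Fits `log(y) ~ log(k)` over `k >= k_min` and returns the (positive) decay
#' exponent; used for the tails of `k_nn(k)` and `C(k)`.
#'
#' @param k degree values.
#' @param y spectrum values (positive).
#' @param k_min lower cutoff.
#' @param weights optional weights for the regression.
#' @return list with `exponent` (decay, positive when `y` falls with `k`)
#'   and `se`.
#' @export
fit_loglog_slope <- function(k, y, k_min = 1, weights = NULL) {
  sel <- k >= k_min & y > 0
  if (sum(sel) < 3) stop("too few points above k_min")
  fit <- if (is.null(weights)) lm(log(y[sel]) ~ log(k[sel]))
         else lm(log(y[sel]) ~ log(k[sel]), weights = weights[sel])
  list(exponent = -unname(coef(fit)[2]),
       se = unname(sqrt(diag(vcov(fit)))[2]))
}

#' Stationary time averages of the order parameters
#'
#' Averages a recorded trajectory over the declared window
#' `[t0_avg, t0_avg + dt_avg]` and reports means and standard deviations of
#' the overlap (signed first pattern, and magnitude of the best-retrieved
#' pattern), activity, homogeneity and assortativity. A simple stationarity
#' check compares the means of the first and second half-windows and warns
#' when they drift by more than `drift_tol` times the within-window sd.
#'
#' @param trajectory data.frame from [run_coevolution()].
#' @param t0_avg,dt_avg averaging window (structural steps).
#' @param drift_tol drift tolerance in within-window standard deviations.
#' @return a `stationary_stats` list: `m_bar` (|m| of best pattern),
#'   `m1_bar` (signed), `M_bar`, `g_bar`, `r_bar`, the sds, `drift`, and the
#'   window.
#' @export
stationary_average <- function(trajectory, t0_avg, dt_avg,
                               drift_tol = 3) {
  stopifnot(t0_avg >= min(trajectory$t), t0_avg + dt_avg <= max(trajectory$t) + 1e-9)
  w <- trajectory$t >= t0_avg & trajectory$t <= t0_avg + dt_avg
  if (sum(w) < 2) stop("averaging window contains fewer than 2 records")
  win <- trajectory[w, ]
  half <- win$t <= t0_avg + dt_avg / 2
  stat <- function(v) c(mean = mean(v), sd = sd(v),
                        drift = abs(mean(v[half]) - mean(v[!half])),
                        sd_half = max(sd(v[half]), sd(v[!half])))
  cols <- list(m_bar = win$m_best, m1_bar = win$m.1, M_bar = win$M,
               g_bar = win$g, r_bar = win$r)
  out <- lapply(cols, function(v) if (all(is.na(v)))
                  c(mean = NA, sd = NA, drift = NA, sd_half = NA)
                else stat(v[!is.na(v)]))
  drift_flag <- vapply(out, function(s) {
    !is.na(s["drift"]) && s["sd_half"] > 0 &&
      s["drift"] > drift_tol * s["sd_half"]
  }, logical(1))
  if (any(drift_flag))
    warning("possible non-stationarity in: ",
            paste(names(out)[drift_flag], collapse = ", "))
  res <- c(lapply(out, `[[`, "mean"),
           list(sd = vapply(out, `[[`, numeric(1), "sd"),
                drift = vapply(out, `[[`, numeric(1), "drift"),
                window = c(t0_avg = t0_avg, dt_avg = dt_avg),
                stationary = !any(drift_flag)))
  class(res) <- "stationary_stats"
  res
}

#' @export
print.stationary_stats <- function(x, ...) {
  cat(sprintf("stationary_stats over [%g, %g]: m_bar=%.3f M_bar=%.3f g_bar=%.3f r_bar=%s%s\n",
              x$window[1], x$window[1] + x$window[2],
              x$m_bar, x$M_bar, x$g_bar, format(x$r_bar, digits = 3),
              if (isTRUE(x$stationary)) "" else "  [drifting]"))
  invisible(x)
}
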