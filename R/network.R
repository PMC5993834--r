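#' Simple undirected network object
#'
#' A light container for an evolving synaptic graph: a two-column edge matrix
#' (1-based node indices, each undirected edge stored once) plus the number of
#' nodes. The constructor validates simplicity (no self-loops, no multi-edges).
#'
#' @param edges integer matrix with two columns, one row per undirected edge.
#' @param N number of nodes.
#' @return an `sp_network` object.
#' @export
sp_network <- function(edges, N) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > N)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("multi-edges are not allowed")
  }
  structure(list(edges = edges, N = as.integer(N)), class = "sp_network")
}

#' @export
print.sp_network <- function(x, ...) {
  cat(sprintf("sp_network: N = %d nodes, E = %d edges, mean degree %.3f\n",
              x$N, nrow(x$edges), mean_degree(x)))
  invisible(x)
}

#' Node degrees and mean degree
#' @param network an `sp_network`.
#' @return integer vector of length N (`degrees`), or a scalar (`mean_degree`).
#' @export
degrees <- function(network) {
  tabulate(c(network$edges[, 1], network$edges[, 2]), nbins = network$N)
}

#' @rdname degrees
#' @export
mean_degree <- function(network) 2 * nrow(network$edges) / network$N

#' Adjacency list (internal helper)
#' @noRd
adj_list <- function(network) {
  e <- network$edges
  split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(network$N)))
}

#' Generate an initial network with prescribed mean degree
#'
#' Draws an initial degree sequence and pairs stubs Chung-Lu style: edges are
#' placed between nodes sampled with probability proportional to their target
#' degrees, rejecting self-loops and duplicates so the graph stays simple.
#' Two initial-condition kinds are supported: `"homogeneous"`, where every
#' node has target degree `round(kappa0)`, and `"heterogeneous"`, where the
#' sequence is drawn from a power law `k^-exponent` whose lower cutoff is
#' tuned numerically so that the expected mean equals `kappa0`.
#'
#' @param N number of nodes.
#' @param kappa0 target mean degree (0 <= kappa0 < N - 1). `kappa0 = 0` gives
#'   the empty graph.
#' @param ic_kind `"homogeneous"` or `"heterogeneous"`.
#' @param exponent degree-distribution exponent for the heterogeneous case.
#' @param max_tries resampling budget for infeasible draws before failing.
#' @return an `sp_network` whose realized mean degree is within 5% of
#'   `kappa0` (for `kappa0` large enough for relative accuracy to make sense).
#' @export
initial_network <- function(N, kappa0, ic_kind = c("homogeneous", "heterogeneous"),
                            exponent = 2.5, max_tries = 20L) {
  ic_kind <- match.arg(ic_kind)
  stopifnot(kappa0 >= 0, kappa0 < N - 1)
  if (kappa0 == 0) return(sp_network(matrix(integer(0), ncol = 2), N))
  if (ic_kind == "homogeneous") {
    k_target <- rep(round(kappa0), N)
  } else {
    k_target <- powerlaw_degree_sequence(N, kappa0, exponent)
  }
  M <- round(sum(k_target) / 2)
  for (attempt in seq_len(max_tries)) {
    edges <- chung_lu_edges(k_target, M, N)
    if (!is.null(edges)) {
      net <- sp_network(edges, N)
      return(net)
    }
    if (ic_kind == "heterogeneous")
      k_target <- powerlaw_degree_sequence(N, kappa0, exponent)
  }
  stop("initial_network: could not realize a simple graph with the requested degrees")
}

# degree sequence from a rounded, truncated Pareto law with lower cutoff tuned
# so the expected (rounded) mean equals kappa0
#' @noRd
powerlaw_degree_sequence <- function(N, kappa0, exponent) {
  kmax <- N - 1
  mean_rounded <- function(xm) {
    # E[round(X)] for X ~ truncated Pareto(xm, exponent) on [xm, kmax]
    ks <- seq(max(1, floor(xm)), kmax)
    lo <- pmax(ks - 0.5, xm)
    hi <- pmin(ks + 0.5, kmax)
    w <- pmax(lo^(1 - exponent) - hi^(1 - exponent), 0)
    sum(ks * w) / sum(w)
  }
  f <- function(xm) mean_rounded(xm) - kappa0
  if (f(1) > 0) stop("kappa0 too small for a power-law sequence with this exponent")
  xm <- uniroot(f, c(1, kappa0))$root
  u <- runif(N)
  x <- (xm^(1 - exponent) - u * (xm^(1 - exponent) - kmax^(1 - exponent)))^(1 / (1 - exponent))
  pmin(pmax(round(x), 1L), kmax)
}

# place M edges with endpoint probability proportional to the target degrees,
# rejecting self-loops/duplicates; NULL if the budget is exhausted
#' @noRd
chung_lu_edges <- function(k_target, M, N) {
  if (M == 0) return(matrix(integer(0), ncol = 2))
  keys <- character(0)
  out_i <- integer(0); out_j <- integer(0)
  need <- M
  for (batch in seq_len(200L)) {
    nb <- ceiling(need * 1.4) + 16L
    i <- sample.int(N, nb, replace = TRUE, prob = k_target)
    j <- sample.int(N, nb, replace = TRUE, prob = k_target)
    lo <- pmin(i, j); hi <- pmax(i, j)
    ok <- lo != hi
    key <- paste(lo, hi)
    ok <- ok & !duplicated(key) & !(key %in% keys)
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    out_i <- c(out_i, lo[take]); out_j <- c(out_j, hi[take])
    keys <- c(keys, key[take])
    need <- M - length(out_i)
    if (need == 0) return(cbind(out_i, out_j))
  }
  NULL
}

#' Write / read a network as a whitespace edge list
#'
#' Header line `# N <nodes>`, then one edge per line as two 0-based node ids.
#' @param network an `sp_network`.
#' @param path file path.
#' @export
write_edgelist <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N %d", network$N), con)
  if (nrow(network$edges) > 0)
    write.table(network$edges - 1L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  hdr <- readLines(path, n = 1L)
  N <- as.integer(strsplit(hdr, " ")[[1]][3])
  lines <- readLines(path)[-1L]
  if (length(lines) == 0) return(sp_network(matrix(integer(0), ncol = 2), N))
  e <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  sp_network(e + 1L, N)
}
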