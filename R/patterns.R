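#' Generate binary activity patterns
#'
#' Draws a set of `P` binary patterns over `N` neurons with mean activity `a0`.
#' In `"uniform"` mode every entry is independently 1 with probability `a0`.
#' In `"sparse-block"` mode each pattern activates exactly `ceiling(a0 * N)`
#' neurons chosen at random, the configuration relevant for sparse memories
#' with `a0` close to `1/P`; by default the active sets of different patterns
#' are drawn independently (overlaps allowed), set `disjoint = TRUE` to
#' partition neurons into non-overlapping blocks instead.
#'
#' @param N number of neurons.
#' @param P number of patterns (>= 1).
#' @param a0 mean activity per pattern, in (0, 1). `a0 * N` must be >= 1.
#' @param mode `"uniform"` or `"sparse-block"`.
#' @param disjoint for `"sparse-block"`: draw mutually disjoint active sets
#'   (requires `P * ceiling(a0 * N) <= N`).
#' @return A `pattern_set`: integer matrix with `P` rows and `N` columns of
#'   0/1 values, with attribute `a0`.
#' @examples
#' xi <- generate_patterns(100, 4, 0.25)
#' rowMeans(xi)
#' @export
generate_patterns <- function(N, P, a0, mode = c("uniform", "sparse-block"),
                              disjoint = FALSE) {
  mode <- match.arg(mode)
  stopifnot(N >= 1, P >= 1, a0 > 0, a0 < 1)
  if (a0 * N < 1) stop("a0 * N < 1: patterns would have no active neurons")
  if (mode == "uniform") {
    xi <- matrix(rbinom(P * N, 1L, a0), nrow = P, ncol = N)
  } else {
    n_act <- ceiling(a0 * N)
    xi <- matrix(0L, nrow = P, ncol = N)
    if (disjoint) {
      if (P * n_act > N) stop("disjoint blocks require P * ceiling(a0*N) <= N")
      perm <- sample.int(N)
      for (mu in seq_len(P))
        xi[mu, perm[((mu - 1) * n_act + 1):(mu * n_act)]] <- 1L
    } else {
      for (mu in seq_len(P)) xi[mu, sample.int(N, n_act)] <- 1L
    }
  }
  structure(xi, a0 = a0, class = c("pattern_set", "matrix", "array"))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: P = %d patterns, N = %d neurons, a0 = %g (realized %.4f)\n",
              nrow(x), ncol(x), attr(x, "a0"), mean(x)))
  invisible(x)
}

#' Hebbian coupling matrix
#'
#' Builds the symmetric synaptic weights storing a pattern set,
#' `w_ij = [kappa_inf a0 (1 - a0)]^-1 sum_mu (xi_i^mu - a0)(xi_j^mu - a0)`,
#' with zero diagonal. `kappa_inf` is the stationary mean degree used to
#' normalise weights so that local fields stay of order one on the pruned graph.
#'
#' @param patterns a `pattern_set` (or P x N 0/1 matrix with attribute `a0`).
#' @param kappa_inf stationary mean degree, > 0.
#' @param a0 mean activity; defaults to the `a0` attribute of `patterns`.
#' @return `coupling_matrix`: N x N symmetric numeric matrix, attribute
#'   `kappa_inf`.
#' @export
hebbian_weights <- function(patterns, kappa_inf, a0 = attr(patterns, "a0")) {
  stopifnot(kappa_inf > 0, !is.null(a0))
  if (a0 <= 0 || a0 >= 1) stop("a0 must lie strictly inside (0, 1)")
  X <- unclass(patterns) - a0              # P x N
  W <- crossprod(X) / (kappa_inf * a0 * (1 - a0))
  diag(W) <- 0
  structure(W, kappa_inf = kappa_inf, class = c("coupling_matrix", "matrix", "array"))
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %d x %d, kappa_inf = %g, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "kappa_inf"), min(x), max(x)))
  invisible(x)
}

#' Write / read a pattern set as a plain 0/1 text matrix
#'
#' One row per pattern, space-separated 0/1 entries; a header comment line
#' stores `a0`.
#' @param patterns a `pattern_set`.
#' @param path file path.
#' @export
write_patterns <- function(patterns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# a0 %.17g", attr(patterns, "a0")), con)
  write.table(unclass(patterns), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  hdr <- readLines(path, n = 1L)
  a0 <- as.numeric(strsplit(hdr, " ")[[1]][3])
  xi <- as.matrix(read.table(path, skip = 1L))
  dimnames(xi) <- NULL
  storage.mode(xi) <- "integer"
  structure(xi, a0 = a0, class = c("pattern_set", "matrix", "array"))
}
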