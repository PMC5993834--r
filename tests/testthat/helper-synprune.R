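# Small fixtures shared across test files (all built in code).

# path graph 1-2-3 with explicit weights used in the hand-worked field case
worked_net3 <- function() sp_network(rbind(c(1L, 2L), c(2L, 3L)), 3)

worked_W3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- -0.25
  W[1, 3] <- W[3, 1] <- 0.9  # no edge 1-3: must not contribute
  W
}

# 5-node graph with one triangle and a tail: edges 1-2,1-3,2-3,3-4,4-5
listed_net5 <- function() {
  sp_network(rbind(c(1L,2L), c(1L,3L), c(2L,3L), c(3L,4L), c(4L,5L)), 5)
}

star_net <- function(n_leaves) {
  sp_network(cbind(1L, 2:(n_leaves + 1L)), n_leaves + 1L)
}

# balanced single pattern with activity exactly 1/2
half_pattern <- function(N) {
  xi <- matrix(0L, 1, N)
  xi[1, seq_len(N / 2)] <- 1L
  structure(xi, a0 = 0.5, class = c("pattern_set", "matrix", "array"))
}

# sample n draws from a discrete power law k^-mu on [kmin, kmax]
rpowerlaw <- function(n, mu, kmin = 1, kmax = 1e5) {
  ks <- kmin:kmax
  cdf <- cumsum(ks^(-mu))
  cdf <- cdf / cdf[length(cdf)]
  ks[findInterval(runif(n), cdf) + 1L]
}
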