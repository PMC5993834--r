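test_that("homogeneity identities hold exactly", {
  expect_equal(homogeneity(rep(10, 50)), 1)           # delta distribution
  # two-point distribution with sigma^2 = kappa^2: degrees 0 and 2k in halves
  expect_equal(homogeneity(c(rep(0, 50), rep(20, 50))), exp(-1))
  # sigma^2 / kappa^2 = 3
  k2 <- c(rep(0, 3), 4)  # mean 1, var 3
  expect_equal(homogeneity(k2), exp(-3))
  expect_error(homogeneity(rep(0, 10)), "kappa = 0")
})

test_that("homogeneity is invariant under degree rescaling", {
  set.seed(50)
  k <- rpois(200, 7) + 1
  expect_equal(homogeneity(3 * k), homogeneity(k))
  # distribution and sample routes agree
  p <- prop.table(tabulate(k + 1L, nbins = 40))
  expect_equal(homogeneity(degree_distribution(p)), homogeneity(k))
})

test_that("knn function matches hand computations", {
  star <- star_net(4)
  kn <- knn_function(star)
  expect_equal(kn$knn[kn$k == 1], 4)   # leaves see the hub
  expect_equal(kn$knn[kn$k == 4], 1)   # hub sees leaves
  # 4-regular ring of 5 nodes (complete graph K5): constant k = 4
  k5 <- sp_network(t(combn(5, 2)), 5)
  expect_equal(knn_function(k5)$knn, 4)
  # listed 5-node graph, by direct computation
  kn5 <- knn_function(listed_net5())
  expect_equal(kn5$knn[kn5$k == 1], 2)
  expect_equal(kn5$knn[kn5$k == 2], mean(c(2.5, 2.5, 2)))
  expect_equal(kn5$knn[kn5$k == 3], 2)
})

test_that("edge Pearson r: star is -1, regular graphs are undefined, ER ~ 0", {
  expect_equal(pearson_r(star_net(6)), -1)
  # two disjoint triangles: regular, r undefined (never silently 0)
  cl <- sp_network(rbind(c(1L,2L), c(2L,3L), c(1L,3L),
                         c(4L,5L), c(5L,6L), c(4L,6L)), 6)
  expect_true(is.na(pearson_r(cl)))
  set.seed(51)
  rs <- replicate(12, {
    e <- unique(t(apply(matrix(sample.int(2000, 2 * 10000, TRUE), ncol = 2),
                        1, sort)))
    e <- e[e[, 1] != e[, 2], ]
    pearson_r(sp_network(e, 2000))
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("edge-based and knn-based r agree to 1e-6 on arbitrary graphs", {
  set.seed(52)
  for (rep in 1:10) {
    net <- initial_network(150, sample(4:12, 1),
                           sample(c("homogeneous", "heterogeneous"), 1))
    r1 <- pearson_r(net, "edges")
    r2 <- pearson_r(net, "knn")
    if (!is.na(r1)) expect_lt(abs(r1 - r2), 1e-6)
  }
})

test_that("r and clustering agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(53)
  net <- initial_network(200, 8, "heterogeneous")
  ig <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  expect_equal(pearson_r(net), igraph::assortativity_degree(ig), tolerance = 1e-10)
  Ci <- local_clustering(net)
  Cig <- igraph::transitivity(ig, type = "local", isolates = "NaN")
  idx <- which(degrees(net) >= 2)
  expect_equal(Ci[idx], Cig[idx], tolerance = 1e-10)
})

test_that("clustering spectrum matches hand counts", {
  tri <- sp_network(rbind(c(1L,2L), c(2L,3L), c(1L,3L)), 3)
  expect_equal(clustering_spectrum(tri)$C, 1)
  # trees have zero clustering
  tree <- sp_network(rbind(c(1L,2L), c(1L,3L), c(2L,4L), c(2L,5L)), 5)
  expect_true(all(clustering_spectrum(tree)$C == 0))
  cs <- clustering_spectrum(listed_net5())
  expect_equal(cs$C[cs$k == 2], 2 / 3)   # nodes 1, 2 in the triangle, node 4 not
  expect_equal(cs$C[cs$k == 3], 1 / 3)   # node 3: one triangle of three pairs
})

test_that("tail exponent recovery across exponents within 2 s.e.", {
  set.seed(54)
  for (mu in c(2.0, 2.5, 3.0)) {
    x <- rpowerlaw(1e5, mu, kmin = 1)
    fit <- fit_tail_exponent(x, k_min = 1)
    expect_lt(abs(fit$exponent - mu), 2 * fit$se)
    expect_lt(fit$se, 0.02)
  }
  # log-binned cross-check stays in the neighbourhood
  x <- rpowerlaw(1e5, 2.5, kmin = 1)
  lb <- fit_tail_exponent(x, k_min = 1, method = "logbin")
  expect_lt(abs(lb$exponent - 2.5), 0.6)  # coarse bins: qualitative cross-check
})

test_that("an exponential tail is flagged by the goodness statistic", {
  set.seed(55)
  x_pl <- rpowerlaw(2e4, 2.5, kmin = 5)
  x_exp <- rpois(2e4, 30)
  ks_pl <- fit_tail_exponent(x_pl, k_min = 5)$ks
  ks_exp <- fit_tail_exponent(x_exp, k_min = 5)$ks
  expect_gt(ks_exp, 3 * ks_pl)
})

test_that("KS-selected k_min lands inside the power-law region", {
  set.seed(56)
  # power law only above k = 8: uniform bulk below
  x <- c(sample(1:7, 3e4, TRUE), rpowerlaw(3e4, 2.5, kmin = 8))
  fit <- fit_tail_exponent(x)
  expect_gte(fit$k_min, 6)
  expect_lt(abs(fit$exponent - 2.5), 0.15)
})

test_that("stationary averages and drift detection behave", {
  traj <- data.frame(t = 1:100, kappa = 10, M = 0.5, g = 0.8, r = 0,
                     m.1 = 0.9, m_best = 0.9)
  st <- stationary_average(traj, 1, 99)
  expect_equal(st$m_bar, 0.9)
  expect_equal(st$g_bar, 0.8)
  expect_true(st$stationary)
  # linear ramp: mean is the midpoint value, and the drift check warns
  traj$m_best <- seq(0, 1, length.out = 100)
  traj$m.1 <- traj$m_best
  expect_warning(st2 <- stationary_average(traj, 1, 99), "non-stationarity")
  expect_equal(st2$m_bar, mean(traj$m_best[traj$t >= 1]), tolerance = 1e-12)
  # OU-like series: mean within 3 s.e.
  set.seed(57)
  x <- numeric(500); for (i in 2:500) x[i] <- 0.9 * x[i - 1] + rnorm(1, 0, 0.1)
  traj3 <- data.frame(t = 1:500, kappa = 10, M = 0.5, g = 0.8, r = 0,
                      m.1 = x + 0.5, m_best = x + 0.5)
  st3 <- suppressWarnings(stationary_average(traj3, 100, 400))
  n_eff <- 300 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(st3$m_bar - 0.5), 3 * sd(x) / sqrt(n_eff))
})
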