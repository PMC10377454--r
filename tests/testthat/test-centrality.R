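test_that("strength and expected influence are signed/absolute edge sums", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.3
  net <- make_network(w)
  expect_equal(unname(node_strength(net)), c(0.8, 0.5, 0.3))

  w2 <- w; w2[1, 3] <- w2[3, 1] <- -0.3
  net2 <- make_network(w2)
  expect_equal(unname(expected_influence(net2))[1], 0.2)
  # flipping every sign leaves strength unchanged
  expect_equal(node_strength(make_network(-w2)), node_strength(net2))
  # all-positive network: the two coincide
  expect_equal(node_strength(net), expected_influence(net))
  zero <- make_network(matrix(0, 3, 3))
  expect_equal(unname(node_strength(zero)), c(0, 0, 0))
  expect_equal(unname(expected_influence(zero)), c(0, 0, 0))
})

test_that("closeness follows inverse mean geodesic distance at length 1/|w|", {
  two <- matrix(0, 2, 2); two[1, 2] <- two[2, 1] <- 0.5
  expect_equal(unname(node_closeness(make_network(two))), c(0.5, 0.5))

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(unname(node_closeness(make_network(chain))),
               c(1 / 1.5, 1, 1 / 1.5))

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(node_closeness(make_network(iso)))[3], 0)
})

test_that("betweenness counts geodesics through bridges", {
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(unname(node_betweenness(make_network(chain))), c(0, 1, 0))

  tri <- matrix(0.6, 3, 3); diag(tri) <- 0
  expect_equal(unname(node_betweenness(make_network(tri))), c(0, 0, 0))

  k <- 5
  star <- matrix(0, k + 1, k + 1)
  star[1, -1] <- star[-1, 1] <- 0.7
  expect_equal(unname(node_betweenness(make_network(star))),
               c(k * (k - 1) / 2, rep(0, k)))
})

test_that("z-standardization uses the sample standard deviation", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(z <- standardize(c(2, 2, 2)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(1)
  x <- rnorm(9)
  expect_equal(mean(standardize(x)), 0, tolerance = 1e-12)
  expect_equal(sd(standardize(x)), 1, tolerance = 1e-12)
})

test_that("the centrality table matches the exhaustive-path oracle", {
  set.seed(2024)
  for (rep in 1:40) {
    w <- random_small_graph()
    net <- make_network(w)
    oracle <- oracle_centrality(w)
    tab <- suppressWarnings(centrality_table(net))
    for (m in names(oracle)) {
      got <- tab$raw[tab$metric == m]
      expect_equal(got, oracle[[m]], tolerance = 1e-8)
      zs <- tab$z[tab$metric == m]
      if (sd(oracle[[m]]) > 0)
        expect_equal(zs, (oracle[[m]] - mean(oracle[[m]])) / sd(oracle[[m]]),
                     tolerance = 1e-8)
    }
  }
})

test_that("relabelling nodes permutes every metric identically", {
  set.seed(7)
  w <- random_small_graph(5)
  p <- nrow(w)
  perm <- sample(p)
  net <- make_network(w)
  net_p <- make_network(w[perm, perm])
  for (f in list(node_strength, node_closeness, node_betweenness,
                 expected_influence)) {
    expect_equal(unname(f(net))[perm], unname(f(net_p)), tolerance = 1e-10)
  }
})

test_that("strength dominates the absolute expected influence", {
  set.seed(11)
  for (rep in 1:10) {
    w <- random_small_graph()
    net <- make_network(w)
    expect_true(all(node_strength(net) >= abs(expected_influence(net)) - 1e-12))
  }
})
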