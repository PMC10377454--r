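test_that("pearson matrix equals the phi coefficient on 2x2 tables", {
  # (a, b, c, d) = (30, 10, 10, 30): phi = (ad - bc)/sqrt(...) = 0.5 by hand
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  d <- symptom_dataset(cbind(a = x, b = y))
  r <- pearson_matrix(d)
  expect_equal(r["a", "b"], 0.5, tolerance = 1e-12)

  dup <- symptom_dataset(cbind(a = x, b = x))
  expect_equal(pearson_matrix(dup)["a", "b"], 1)
})

test_that("pearson matrix flags zero-variance symptoms", {
  d <- symptom_dataset(cbind(a = c(1, 1, 1, 1), b = c(0, 1, 0, 1)))
  expect_warning(r <- pearson_matrix(d), "zero-variance")
  expect_true(is.na(r["a", "b"]))
  expect_equal(diag(r), c(a = 1, b = 1))
})

test_that("penalized path solver matches glmnet coefficient for coefficient", {
  library(glmnet)
  set.seed(10)
  d <- sample_cohort(cohort_spec(c(A = 1500), list(A = recovery_truth()),
                                 seed = 2))$A
  for (node in c(1, 5, 9)) {
    y <- d$matrix[, node]
    X <- d$matrix[, -node]
    lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
    lams <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 60))
    ref <- glmnet(X, y, family = "binomial", lambda = lams,
                  standardize = FALSE, thresh = 1e-12)
    own <- isingnet:::.elasso_node_path(
      matrix(as.numeric(X), nrow(X)), as.numeric(y), rep(1, length(y)),
      lams, tol = 1e-8)
    nv <- own$n_valid
    expect_gt(nv, 40)
    expect_lt(max(abs(as.matrix(ref$beta)[, 1:nv] - own$beta[, 1:nv])), 1e-4)
    expect_lt(max(abs(ref$a0[1:nv] - own$b0[1:nv])), 1e-4)
  }
})

test_that("independent symptoms yield an empty network", {
  pars <- ising_parameters(paste0("s", 1:6), rnorm(6, 0, 0.4),
                           matrix(0, 6, 6))
  d <- sample_cohort(cohort_spec(c(A = 10000), list(A = pars), seed = 77))$A
  net <- fit_ising(d)
  expect_true(all(net$weights == 0))
})

test_that("a single strong edge is recovered with its sign", {
  labels <- paste0("s", 1:9)
  w <- matrix(0, 9, 9); w[2, 7] <- w[7, 2] <- 1.5
  pars <- ising_parameters(labels, rep(0, 9), w)
  fps <- vapply(1:5, function(s) {
    d <- sample_cohort(cohort_spec(c(A = 2000), list(A = pars),
                                   seed = 100 + s))$A
    est <- fit_ising(d)$weights
    expect_gt(est[2, 7], 0)
    sum(est[upper.tri(est)] != 0) - 1
  }, numeric(1))
  expect_lte(mean(fps), 2)
})

test_that("the AND rule is never denser than the OR rule", {
  for (s in 1:3) {
    d <- sample_cohort(cohort_spec(c(A = 400), list(A = recovery_truth()),
                                   seed = 200 + s))$A
    net_and <- fit_ising(d, rule = "AND")
    net_or <- fit_ising(d, rule = "OR")
    and_edges <- net_and$weights != 0
    or_edges <- net_or$weights != 0
    expect_true(all(or_edges[and_edges]))
  }
})

test_that("zero-variance symptoms are retained as edge-free nodes", {
  set.seed(3)
  m <- cbind(always = rep(1L, 300),
             a = rbinom(300, 1, 0.5), b = rbinom(300, 1, 0.4))
  d <- symptom_dataset(m)
  expect_warning(net <- fit_ising(d), "zero-variance")
  expect_true(all(net$weights["always", ] == 0))
  expect_equal(length(net$labels), 3)
  expect_gt(net$thresholds[["always"]], 5)
})

test_that("selected nodewise coefficients agree in sign with unpenalized refits", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1.2; w[3, 4] <- w[4, 3] <- -1.0
  pars <- ising_parameters(paste0("s", 1:4), rep(0, 4), w)
  d <- sample_cohort(cohort_spec(c(A = 3000), list(A = pars), seed = 55))$A
  net <- fit_ising(d)
  B <- net$directed
  for (node in 1:4) {
    sel <- which(B[node, ] != 0)
    if (length(sel) == 0) next
    df <- data.frame(y = d$matrix[, node], d$matrix[, sel, drop = FALSE])
    refit <- glm(y ~ ., data = df, family = binomial())
    expect_equal(unname(sign(coef(refit)[-1])), unname(sign(B[node, sel])))
  }
})

test_that("small samples trigger the n-per-node warning", {
  d <- sample_cohort(cohort_spec(c(A = 60), list(A = recovery_truth()),
                                 seed = 1))$A
  expect_warning(fit_ising(d), "small")
})

test_that("networks round-trip through JSON and export edge lists", {
  d <- sample_cohort(cohort_spec(c(A = 1500), list(A = recovery_truth()),
                                 seed = 6))$A
  net <- fit_ising(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$weights, net$weights)
  expect_equal(unname(back$thresholds), unname(net$thresholds))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), sum(net$weights[upper.tri(net$weights)] != 0))
  expect_named(el, c("node_i", "node_j", "weight"))
})
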