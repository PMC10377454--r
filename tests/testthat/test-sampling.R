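test_that("DSM-constrained cohorts satisfy the diagnostic rule by construction", {
  cohort <- tiny_cohort(n_a = 200, n_b = 150, seed = 3)
  for (d in cohort) {
    expect_true(all(rowSums(d$matrix) >= 5))
    expect_true(all(d$matrix[, "sadness"] + d$matrix[, "anhedonia"] >= 1))
  }
})

test_that("exact sampling reproduces the enumerated distribution", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.7; w[1, 3] <- w[3, 1] <- -0.4
  pars <- ising_parameters(c("a", "b", "c"), c(0.2, -0.3, 0.1), w)
  n <- 50000
  d <- sample_cohort(cohort_spec(c(g = n), list(g = pars), seed = 21))$g
  probs <- enumerate_distribution(pars)
  key <- as.vector(d$matrix %*% c(1, 2, 4)) + 1
  obs <- tabulate(key, nbins = 8) / n
  expc <- probs$prob[order(as.matrix(probs[c("a", "b", "c")]) %*% c(1, 2, 4))]
  mc_se <- sqrt(expc * (1 - expc) / n)
  expect_true(all(abs(obs - expc) <= 3 * mc_se))
})

test_that("group-specific couplings shift empirical pairwise odds ratios", {
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 1
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- -1
  labs <- c("a", "b", "c")
  spec <- cohort_spec(
    c(pos = 20000, neg = 20000),
    list(pos = ising_parameters(labs, rep(0, 3), w1),
         neg = ising_parameters(labs, rep(0, 3), w2)),
    seed = 8)
  cohort <- sample_cohort(spec)
  emp_or <- vapply(cohort, function(d) {
    tab <- table(factor(d$matrix[, 1], 0:1), factor(d$matrix[, 2], 0:1))
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }, numeric(1))
  expect_gt(emp_or[["pos"]], 1)
  expect_lt(emp_or[["neg"]], 1)
})

test_that("conditioned sampling equals unconditioned sampling plus filtering", {
  pars <- example_parameters("ppd")
  con <- dsm_constraint()
  n <- 40000
  cond <- sample_cohort(cohort_spec(c(g = n), list(g = pars),
                                    constraint = con, seed = 14))$g
  raw <- sample_cohort(cohort_spec(c(g = 3 * n), list(g = pars), seed = 15))$g
  keep <- dsm_qualifies(raw$matrix, con, raw$labels)
  filt <- raw$matrix[keep, , drop = FALSE]
  key_c <- as.vector(cond$matrix %*% 2^(0:8))
  key_f <- as.vector(filt %*% 2^(0:8))
  all_keys <- sort(unique(c(key_c, key_f)))
  f_c <- tabulate(match(key_c, all_keys), length(all_keys)) / length(key_c)
  f_f <- tabulate(match(key_f, all_keys), length(all_keys)) / length(key_f)
  # both empirical distributions estimate the same conditional law
  expect_lt(max(abs(f_c - f_f)), 0.01)
})

test_that("sampling is deterministic given the spec seed", {
  a <- tiny_cohort(seed = 99)
  b <- tiny_cohort(seed = 99)
  expect_identical(a$A$matrix, b$A$matrix)
  expect_identical(a$B$matrix, b$B$matrix)
})

test_that("cohort specs reject mismatched labels and impossible rules", {
  pars <- example_parameters("mde")
  other <- ising_parameters(letters[1:9], pars$thresholds,
                            unname(pars$weights))
  expect_error(cohort_spec(c(A = 10, B = 10), list(A = pars, B = other)),
               "same labels")
  expect_error(
    cohort_spec(c(A = 10), list(A = pars),
                constraint = dsm_constraint(k_min = 10)),
    "k_min")
})

test_that("gibbs sampling matches independent-site logistic marginals", {
  tau <- c(-1, 0, 0.8, 1.5)
  pars <- ising_parameters(paste0("s", 1:4), tau, matrix(0, 4, 4))
  d <- gibbs_sample(pars, n = 20000, burn_in = 200, thin = 2, seed = 4)
  marg <- colMeans(d$matrix)
  se <- sqrt(plogis(tau) * (1 - plogis(tau)) / 20000)
  # thinned draws are mildly autocorrelated; allow a generous band
  expect_true(all(abs(marg - plogis(tau)) <= 6 * se))
})

test_that("gibbs sampling agrees with exact enumeration on a coupled model", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- -0.8
  pars <- ising_parameters(paste0("s", 1:4), c(0, -0.5, 0.5, 0), w)
  d <- gibbs_sample(pars, n = 40000, seed = 31)
  key <- as.vector(d$matrix %*% 2^(0:3)) + 1
  obs <- tabulate(key, nbins = 16)
  dist <- enumerate_distribution(pars)
  expc <- 40000 *
    dist$prob[order(as.matrix(dist[paste0("s", 1:4)]) %*% 2^(0:3))]
  stat <- sum((obs - expc)^2 / expc)
  expect_gt(pchisq(stat, df = 15, lower.tail = FALSE), 0.01)
})

test_that("gibbs sampling is bit-reproducible given the seed", {
  pars <- example_parameters("mde")
  a <- gibbs_sample(pars, 500, seed = 7)
  b <- gibbs_sample(pars, 500, seed = 7)
  expect_identical(a$matrix, b$matrix)
})
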