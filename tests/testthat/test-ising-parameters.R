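test_that("parameter containers validate their invariants", {
  w <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(ising_parameters(c("a", "b"), c(0, 0), w), "ising_parameters")
  expect_error(ising_parameters("a", 0, matrix(0, 1, 1)), "at least 2")
  expect_error(ising_parameters(c("a", "a"), c(0, 0), w), "unique")
  wbad <- w; wbad[1, 2] <- 2
  expect_error(ising_parameters(c("a", "b"), c(0, 0), wbad), "symmetric")
  wdiag <- w; diag(wdiag) <- 1
  expect_error(ising_parameters(c("a", "b"), c(0, 0), wdiag), "diagonal")
  expect_error(ising_parameters(c("a", "b"), c(0, Inf), w), "finite")
})

test_that("enumeration matches closed forms on independent models", {
  # two independent zero-threshold symptoms: all four states equally likely
  pars <- ising_parameters(c("a", "b"), c(0, 0), matrix(0, 2, 2))
  d <- enumerate_distribution(pars)
  expect_equal(d$prob, rep(0.25, 4))

  # independent sites factorize, so each marginal is logistic(tau)
  pars <- ising_parameters(c("a", "b"), c(log(3), -1), matrix(0, 2, 2))
  d <- enumerate_distribution(pars)
  expect_equal(sum(d$prob[d$a == 1]), 0.75, tolerance = 1e-12)
  expect_equal(sum(d$prob[d$b == 1]), plogis(-1), tolerance = 1e-12)
})

test_that("enumeration agrees with direct summation and couples states", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  pars <- ising_parameters(c("x", "y", "z"), c(0, 0, 0), w)
  d <- enumerate_distribution(pars)
  oracle <- oracle_ising_probs(c(0, 0, 0), w)
  key_impl <- as.matrix(d[c("x", "y", "z")]) %*% c(1, 2, 4)
  key_orac <- oracle$states %*% c(1, 2, 4)
  expect_equal(d$prob[order(key_impl)], oracle$probs[order(key_orac)],
               tolerance = 1e-12)
  # the positive edge pulls the pair above independence
  expect_gt(sum(d$prob[d$x == 1 & d$y == 1]), 0.25)
})

test_that("enumeration probabilities are a distribution and p is guarded", {
  set.seed(42)
  for (rep in 1:5) {
    p <- sample(2:6, 1)
    w <- matrix(0, p, p)
    w[upper.tri(w)] <- rnorm(p * (p - 1) / 2)
    w <- w + t(w)
    pars <- ising_parameters(paste0("s", 1:p), rnorm(p), w)
    d <- enumerate_distribution(pars)
    expect_true(all(d$prob >= 0))
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
  big <- ising_parameters(paste0("s", 1:21), rep(0, 21), matrix(0, 21, 21))
  expect_error(enumerate_distribution(big), "gibbs_sample")
})

test_that("parameters round-trip through JSON", {
  pars <- recovery_truth()
  path <- withr::local_tempfile(fileext = ".json")
  write_ising_parameters(pars, path)
  back <- read_ising_parameters(path)
  expect_equal(back$labels, pars$labels)
  expect_equal(back$thresholds, pars$thresholds)
  expect_equal(back$weights, pars$weights)
})

test_that("threshold calibration hits target marginals", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.8; w[2, 3] <- w[3, 2] <- -0.5
  targets <- c(0.7, 0.5, 0.4)
  pars <- calibrate_thresholds(w, targets, c("a", "b", "c"))
  d <- enumerate_distribution(pars)
  got <- vapply(c("a", "b", "c"), function(l) sum(d$prob[d[[l]] == 1]),
                numeric(1))
  expect_equal(unname(got), targets, tolerance = 1e-5)
})

test_that("bundled synthetic models reproduce the intended frequency ordering", {
  for (g in c("mde", "ppd")) {
    pars <- example_parameters(g)
    expect_identical(pars$labels, dsm5_symptoms())
    d <- enumerate_distribution(pars)
    keep <- dsm_qualifies(as.matrix(d[pars$labels]), dsm_constraint(),
                          pars$labels)
    d$prob <- d$prob * keep / sum(d$prob[keep])
    marg <- vapply(pars$labels, function(l) sum(d$prob * d[[l]]), numeric(1))
    top3 <- names(sort(marg, decreasing = TRUE))[1:3]
    expect_setequal(top3, c("sadness", "anhedonia", "fatigue"))
    expect_true(all(marg[top3] >= 0.83 - 1e-4 & marg[top3] <= 0.99 + 1e-4))
  }
})
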