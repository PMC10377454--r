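#' Ising model parameters for binary symptom networks
#'
#' Container for a pairwise Markov random field over `p` binary ({0,1})
#' symptoms: node thresholds \eqn{\tau_i} (log-odds scale main effects) and a
#' symmetric edge-weight matrix \eqn{w_{ij}} (pairwise interactions, zero
#' diagonal). The model is
#' \deqn{P(x) \propto \exp\left(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\right),
#'   \quad x \in \{0,1\}^p.}
#'
#' @param labels Character vector of unique symptom names (length `p >= 2`).
#' @param thresholds Numeric vector of length `p`.
#' @param weights Symmetric `p x p` numeric matrix with zero diagonal.
#' @return An object of class `ising_parameters`.
#' @examples
#' ising_parameters(c("a", "b"), c(0, 0), matrix(c(0, 1, 1, 0), 2))
#' @export
ising_parameters <- function(labels, thresholds, weights) {
  labels <- as.character(labels)
  p <- length(labels)
  if (p < 2) stop("need at least 2 symptoms")
  if (anyDuplicated(labels)) stop("symptom labels must be unique")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != p) stop("thresholds must have length ", p)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || any(dim(weights) != p))
    stop("weights must be a numeric ", p, " x ", p, " matrix")
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("weights must be symmetric")
  if (any(diag(weights) != 0))
    stop("weights must have a zero diagonal")
  if (any(!is.finite(thresholds)) || any(!is.finite(weights)))
    stop("parameters must be finite")
  weights <- (weights + t(weights)) / 2
  dimnames(weights) <- list(labels, labels)
  names(thresholds) <- labels
  structure(list(labels = labels, thresholds = thresholds, weights = weights),
            class = "ising_parameters")
}

#' @export
print.ising_parameters <- function(x, ...) {
  cat("Ising model parameters:", length(x$labels), "symptoms,",
      sum(x$weights[upper.tri(x$weights)] != 0), "nonzero edges\n")
  cat("  symptoms:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# all 2^p binary states as a (2^p x p) matrix, x_1 varying fastest
state_matrix <- function(p) {
  stopifnot(p >= 1, p <= 20)
  m <- matrix(0L, 2L^p, p)
  for (j in seq_len(p)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2L^(j - 1)), length.out = 2L^p)
  }
  m
}

#' Exact state distribution of a small Ising model
#'
#' Enumerates all \eqn{2^p} binary states and returns each state's exact
#' probability, normalized by log-sum-exp for numerical stability. Intended
#' as the exact oracle behind the samplers; refuses `p > 20`.
#'
#' @param params An [ising_parameters] object.
#' @return A data frame with one row per state: the `p` symptom columns
#'   (0/1) and a `prob` column summing to 1.
#' @examples
#' pars <- ising_parameters(c("a", "b"), c(0, 0), matrix(0, 2, 2))
#' enumerate_distribution(pars)  # four states, each probability 1/4
#' @export
enumerate_distribution <- function(params) {
  stopifnot(inherits(params, "ising_parameters"))
  p <- length(params$labels)
  if (p > 20)
    stop("p = ", p, " is too large for exact enumeration (limit 20); ",
         "use gibbs_sample() instead")
  states <- state_matrix(p)
  logpot <- as.numeric(states %*% params$thresholds +
                         0.5 * rowSums((states %*% params$weights) * states))
  m <- max(logpot)
  logz <- m + log(sum(exp(logpot - m)))
  out <- as.data.frame(states)
  names(out) <- params$labels
  out$prob <- exp(logpot - logz)
  out
}

#' Solve thresholds for target marginal frequencies
#'
#' Given fixed edge weights and target per-symptom marginal probabilities,
#' finds thresholds \eqn{\tau} such that the (optionally DSM-conditioned)
#' exact marginals match the targets, by damped fixed-point iteration on the
#' log-odds scale using exact enumeration.
#'
#' @param weights Symmetric weight matrix.
#' @param target_marginals Desired marginal frequencies, in (0, 1).
#' @param labels Symptom names.
#' @param constraint Optional diagnostic constraint as produced by
#'   [dsm_constraint()]; when supplied, the conditioned marginals are matched.
#' @param tol,max_iter Convergence tolerance on marginals and iteration cap.
#' @return An [ising_parameters] object.
#' @export
calibrate_thresholds <- function(weights, target_marginals, labels,
                                 constraint = NULL, tol = 1e-6,
                                 max_iter = 500) {
  p <- length(labels)
  stopifnot(length(target_marginals) == p,
            all(target_marginals > 0 & target_marginals < 1))
  tau <- stats::qlogis(target_marginals)
  pars <- ising_parameters(labels, tau, weights)
  for (it in seq_len(max_iter)) {
    dist <- enumerate_distribution(pars)
    if (!is.null(constraint)) dist <- condition_distribution(dist, constraint)
    marg <- marginals_from_distribution(dist, labels)
    err <- target_marginals - marg
    if (max(abs(err)) < tol) break
    # damped log-odds step; exact Newton is unnecessary at p = 9
    tau <- tau + 0.8 * (stats::qlogis(pmin(pmax(target_marginals, 1e-12), 1 - 1e-12)) -
                          stats::qlogis(pmin(pmax(marg, 1e-12), 1 - 1e-12)))
    pars <- ising_parameters(labels, tau, weights)
  }
  if (max(abs(err)) >= tol)
    warning("calibration stopped at max_iter with marginal error ",
            signif(max(abs(err)), 3))
  pars
}

marginals_from_distribution <- function(dist, labels) {
  vapply(labels, function(l) sum(dist$prob * dist[[l]]), numeric(1))
}

#' Read and write Ising parameters as JSON
#'
#' Serializes labels, thresholds and the weight matrix (row-major) to JSON.
#'
#' @param params An [ising_parameters] object.
#' @param path File path.
#' @return `read_ising_parameters()` returns an [ising_parameters] object;
#'   `write_ising_parameters()` returns `path` invisibly.
#' @export
write_ising_parameters <- function(params, path) {
  stopifnot(inherits(params, "ising_parameters"))
  obj <- list(labels = params$labels,
              thresholds = unname(params$thresholds),
              weights = matrix(t(params$weights),
                               nrow = nrow(params$weights), byrow = TRUE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ising_parameters
#' @export
read_ising_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ising_parameters(obj$labels, obj$thresholds, as.matrix(obj$weights))
}

#' Bundled synthetic study-like Ising parameters
#'
#' Returns one of the two synthetic 9-symptom parameter sets shipped with the
#' package ("mde" or "ppd"). These were built once by fixing a sparse signed
#' weight structure and calibrating thresholds (via [calibrate_thresholds],
#' under the DSM-5 diagnostic constraint) so that the conditioned marginal
#' frequencies follow the qualitative ordering reported for depressed women:
#' sadness/anhedonia/fatigue most frequent, in the 0.83-0.99 range. They are
#' synthetic stand-ins for the access-restricted cohort, not its estimates.
#'
#' @param group `"mde"` or `"ppd"`.
#' @return An [ising_parameters] object.
#' @export
example_parameters <- function(group = c("mde", "ppd")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      paste0("synthetic_", group, "_params.json"),
                      package = "isingnet", mustWork = TRUE)
  read_ising_parameters(path)
}

#' The nine DSM-5 depressive symptom labels
#'
#' @return Character vector of length 9 in canonical order.
#' @export
dsm5_symptoms <- function() {
  c("sadness", "anhedonia", "appetite", "sleep", "psychomotor",
    "fatigue", "culpability", "concentration", "suicidal_ideations")
}
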