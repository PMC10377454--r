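#' DSM-5-style diagnostic constraint
#'
#' Describes the diagnostic event used to condition sampled cohorts: at least
#' `k_min` of the `p` symptoms present, including at least one cardinal
#' symptom. The DSM-5 major depressive episode rule is `k_min = 5` with
#' cardinal symptoms sadness and anhedonia.
#'
#' @param k_min Minimum number of symptoms present.
#' @param cardinal Labels (or indices) of the cardinal symptoms, at least one
#'   of which must be present.
#' @return An object of class `dsm_constraint`.
#' @export
dsm_constraint <- function(k_min = 5, cardinal = c("sadness", "anhedonia")) {
  stopifnot(k_min >= 1, length(cardinal) >= 1)
  structure(list(k_min = as.integer(k_min), cardinal = cardinal),
            class = "dsm_constraint")
}

cardinal_indices <- function(constraint, labels) {
  if (is.numeric(constraint$cardinal)) return(as.integer(constraint$cardinal))
  idx <- match(constraint$cardinal, labels)
  if (anyNA(idx))
    stop("cardinal symptoms not found among labels: ",
         paste(constraint$cardinal[is.na(idx)], collapse = ", "))
  idx
}

#' Does a symptom profile satisfy the diagnostic rule?
#'
#' @param x A 0/1 vector or matrix (rows = participants) with named columns
#'   when `constraint` uses labels.
#' @param constraint A [dsm_constraint].
#' @param labels Symptom labels for `x`'s columns.
#' @return Logical vector, one value per row.
#' @export
dsm_qualifies <- function(x, constraint = dsm_constraint(),
                          labels = colnames(x)) {
  if (is.vector(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, labels))
  idx <- cardinal_indices(constraint, labels)
  if (constraint$k_min > ncol(x)) stop("k_min exceeds the number of symptoms")
  rowSums(x) >= constraint$k_min &
    rowSums(x[, idx, drop = FALSE]) >= 1
}

condition_distribution <- function(dist, constraint) {
  labels <- setdiff(names(dist), "prob")
  keep <- dsm_qualifies(as.matrix(dist[labels]), constraint, labels)
  mass <- sum(dist$prob[keep])
  if (mass <= 0)
    stop("the diagnostic constraint has zero probability mass under this model")
  out <- dist[keep, , drop = FALSE]
  out$prob <- out$prob / mass
  rownames(out) <- NULL
  out
}

#' Cohort specification for the synthetic generator
#'
#' Bundles per-group sample sizes and Ising parameters, the optional
#' diagnostic constraint and a seed, for [sample_cohort()]. All groups must
#' share the same symptom labels and ordering.
#'
#' @param n_per_group Named vector of positive group sizes.
#' @param params_per_group Named list of [ising_parameters], same names.
#' @param constraint A [dsm_constraint], or `NULL` for unconditioned
#'   sampling.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, params_per_group, constraint = NULL,
                        seed = 1L) {
  stopifnot(length(n_per_group) == length(params_per_group),
            all(n_per_group >= 1),
            !is.null(names(n_per_group)),
            identical(sort(names(n_per_group)), sort(names(params_per_group))))
  labels <- params_per_group[[1]]$labels
  for (p in params_per_group) {
    stopifnot(inherits(p, "ising_parameters"))
    if (!identical(p$labels, labels))
      stop("all groups must share the same labels and ordering")
  }
  if (!is.null(constraint)) {
    stopifnot(inherits(constraint, "dsm_constraint"))
    if (constraint$k_min > length(labels))
      stop("k_min exceeds the number of symptoms")
  }
  structure(list(n_per_group = n_per_group,
                 params_per_group = params_per_group[names(n_per_group)],
                 constraint = constraint, seed = as.integer(seed)),
            class = "cohort_spec")
}

sample_states_exact <- function(params, n, constraint = NULL) {
  dist <- enumerate_distribution(params)
  if (!is.null(constraint)) dist <- condition_distribution(dist, constraint)
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
  as.matrix(dist[idx, params$labels, drop = FALSE])
}

#' Sample a synthetic symptom cohort
#'
#' Draws each group exactly from its Ising model by enumerating the state
#' distribution (optionally restricted to diagnostically qualifying states
#' and renormalized — not rejection sampling) and sampling states from it.
#' Reproducible given the spec's seed.
#'
#' @param spec A [cohort_spec].
#' @return Named list of [symptom_dataset] objects, one per group.
#' @examples
#' pars <- example_parameters("mde")
#' spec <- cohort_spec(c(MDE = 100), list(MDE = pars),
#'                     constraint = dsm_constraint(), seed = 7)
#' cohort <- sample_cohort(spec)
#' all(rowSums(cohort$MDE$matrix) >= 5)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  out <- lapply(names(spec$n_per_group), function(g) {
    m <- sample_states_exact(spec$params_per_group[[g]], spec$n_per_group[[g]],
                             spec$constraint)
    symptom_dataset(m, labels = spec$params_per_group[[g]]$labels, group = g)
  })
  names(out) <- names(spec$n_per_group)
  out
}

#' Gibbs sampler for larger Ising models
#'
#' Single-site Gibbs sampling with conditionals
#' \eqn{P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)}.
#' Intended for models beyond the exact-enumeration guard (`p > 20`); for
#' small `p` it is validated against [enumerate_distribution()].
#'
#' @param params An [ising_parameters] object.
#' @param n Number of retained samples.
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th sweep.
#' @param seed Integer seed.
#' @param group Group label for the returned dataset.
#' @return A [symptom_dataset].
#' @export
gibbs_sample <- function(params, n, burn_in = 1000, thin = 10, seed = 1L,
                         group = "gibbs") {
  stopifnot(inherits(params, "ising_parameters"),
            n >= 1, burn_in >= 1, thin >= 1)
  set.seed(seed)
  m <- .gibbs_chain(params$thresholds, params$weights, as.integer(n),
                    as.integer(burn_in), as.integer(thin))
  symptom_dataset(m, labels = params$labels, group = group)
}
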