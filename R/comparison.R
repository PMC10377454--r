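#' Permutation-based network comparison test
#'
#' Compares the regularized Ising networks of two groups with the
#' permutation test of network invariance. Two statistics are computed from
#' networks fit separately per group with identical estimator settings:
#' \itemize{
#'   \item network structure invariance
#'     \eqn{M = \max_{i<j} |w^{(a)}_{ij} - w^{(b)}_{ij}|}, and
#'   \item global strength invariance
#'     \eqn{S = |\sum_{i<j} |w^{(a)}_{ij}| - \sum_{i<j} |w^{(b)}_{ij}||}.
#' }
#' The null distribution pools all participants, randomly reassigns group
#' labels preserving group sizes, refits both networks and recomputes M and
#' S; p-values use the add-one correction
#' \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})}.
#'
#' @param data_a,data_b Two [symptom_dataset]s with identical symptom labels
#'   and ordering.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param gamma,rule Estimator settings applied to every fit.
#' @param edge_tests Also compute per-edge permutation p-values (off by
#'   default).
#' @return A list of class `nct_result`: `m_observed`, `p_m`, `s_observed`,
#'   `p_s`, `global_strengths`, `null_m`, `null_s`, `n_perm`, `seed`, the
#'   two fitted networks, and `edge_p` when requested.
#' @export
nct <- function(data_a, data_b, n_perm = 1000, seed = 1L, gamma = 0.25,
                rule = "AND", edge_tests = FALSE) {
  stopifnot(inherits(data_a, "symptom_dataset"),
            inherits(data_b, "symptom_dataset"))
  if (!identical(data_a$labels, data_b$labels))
    stop("both datasets must share the same symptom labels and ordering")
  p <- length(data_a$labels)
  and_rule <- as.integer(rule == "AND")

  net_a <- suppressWarnings(fit_ising(data_a, gamma = gamma, rule = rule))
  net_b <- suppressWarnings(fit_ising(data_b, gamma = gamma, rule = rule))
  ut <- upper.tri(net_a$weights)
  gs <- c(a = sum(abs(net_a$weights[ut])), b = sum(abs(net_b$weights[ut])))
  diff_obs <- net_a$weights - net_b$weights
  m_obs <- max(abs(diff_obs[ut]))
  s_obs <- abs(gs[["a"]] - gs[["b"]])

  # pooled unique states; a permutation only redistributes the counts, so
  # each refit runs on at most 2^p weighted rows. States are sorted by
  # binary key and the subsample is always drawn for the smaller group, so
  # the null draws (and hence the p-values) are invariant to swapping the
  # two input datasets.
  pooled <- rbind(data_a$matrix, data_b$matrix)
  n_tot <- nrow(pooled)
  cs <- collapse_states(pooled)
  key <- as.vector(cs$states %*% (2^(seq_len(p) - 1)))
  ord <- order(key)
  states <- cs$states[ord, , drop = FALSE]
  counts <- cs$counts[ord]
  n_states <- nrow(states)
  n_small <- min(data_a$n, data_b$n)
  small_is_a <- data_a$n <= data_b$n
  # participant-level state index, sorted so it depends only on the pooled
  # multiset of symptom profiles
  participant_state <- rep(seq_len(n_states), counts)

  set.seed(seed)
  null_m <- numeric(n_perm)
  null_s <- numeric(n_perm)
  edge_null_ge <- if (edge_tests) matrix(0, p, p) else NULL
  for (b in seq_len(n_perm)) {
    in_small <- sample.int(n_tot, n_small)
    counts_small <- tabulate(participant_state[in_small], nbins = n_states)
    counts_a <- if (small_is_a) counts_small else counts - counts_small
    counts_b <- counts - counts_a
    w_a <- fit_weights_from_counts(states, counts_a, gamma, and_rule)
    w_b <- fit_weights_from_counts(states, counts_b, gamma, and_rule)
    d <- w_a - w_b
    null_m[b] <- max(abs(d[ut]))
    null_s[b] <- abs(sum(abs(w_a[ut])) - sum(abs(w_b[ut])))
    if (edge_tests) edge_null_ge <- edge_null_ge + (abs(d) >= abs(diff_obs))
  }
  out <- list(m_observed = m_obs, p_m = (1 + sum(null_m >= m_obs)) / (1 + n_perm),
              s_observed = s_obs, p_s = (1 + sum(null_s >= s_obs)) / (1 + n_perm),
              global_strengths = gs, null_m = null_m, null_s = null_s,
              n_perm = n_perm, seed = seed, gamma = gamma, rule = rule,
              network_a = net_a, network_b = net_b)
  if (edge_tests) {
    ep <- (1 + edge_null_ge) / (1 + n_perm)
    diag(ep) <- NA_real_
    dimnames(ep) <- dimnames(net_a$weights)
    out$edge_p <- ep
  }
  structure(out, class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$n_perm, " permutations)\n", sep = "")
  cat(sprintf("  structure invariance  M = %.3f, p = %.3f\n",
              x$m_observed, x$p_m))
  cat(sprintf("  global strength       S = %.3f, p = %.3f  (%.2f vs %.2f)\n",
              x$s_observed, x$p_s,
              x$global_strengths[["a"]], x$global_strengths[["b"]]))
  invisible(x)
}

#' Write an NCT result as JSON (plus optional null-draw CSV)
#'
#' @param result An `nct_result`.
#' @param path JSON output path.
#' @param null_csv Optional path for the permutation null draws.
#' @export
write_nct_json <- function(result, path, null_csv = NULL) {
  obj <- list(m_observed = result$m_observed, p_m = result$p_m,
              s_observed = result$s_observed, p_s = result$p_s,
              global_strength_a = unname(result$global_strengths[["a"]]),
              global_strength_b = unname(result$global_strengths[["b"]]),
              n_perm = result$n_perm, seed = result$seed,
              gamma = result$gamma, rule = result$rule)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(null_csv))
    utils::write.csv(data.frame(null_m = result$null_m,
                                null_s = result$null_s),
                     null_csv, row.names = FALSE, quote = FALSE)
  invisible(path)
}
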