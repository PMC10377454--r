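centrality_vector <- function(weights, metric) {
  switch(metric,
    strength = rowSums(abs(weights)),
    expected_influence = rowSums(weights),
    closeness = node_closeness(weights_as_network(weights)),
    betweenness = node_betweenness(weights_as_network(weights)),
    stop("unknown centrality metric: ", metric))
}

weights_as_network <- function(weights) {
  structure(list(labels = rownames(weights), weights = weights),
            class = "ising_network")
}

#' Case-dropping bootstrap of centrality stability
#'
#' Quantifies how stable the centrality ordering is under loss of
#' participants: for each drop proportion q in the grid and each replicate,
#' a subsample of \eqn{\lceil n(1-q) \rceil} participants is drawn without
#' replacement, the full network pipeline is refit, and the Pearson
#' correlation between the subsample and full-sample centrality vectors
#' (raw values) is recorded. The CS-coefficient of a metric is the largest
#' grid proportion at which at least 95% of replicates correlate at least
#' 0.70 with the full-sample centralities (0 if none).
#'
#' @param data A [symptom_dataset].
#' @param metrics Centrality metrics to track.
#' @param n_boot Replicates per drop proportion (default 1000; use ~250 for
#'   a fast run).
#' @param proportions Strictly increasing drop fractions in (0, 1).
#' @param seed Integer seed.
#' @param gamma,rule Estimator settings passed to the refits.
#' @param cor_threshold,confidence The CS rule: correlation level and the
#'   required fraction of replicates attaining it.
#' @return A list of class `stability_result`: tidy `correlations` data
#'   frame (metric, proportion, replicate, correlation) and named
#'   `cs_coefficient` vector.
#' @export
case_drop_bootstrap <- function(data,
                                metrics = c("strength", "closeness",
                                            "betweenness",
                                            "expected_influence"),
                                n_boot = 1000,
                                proportions = seq(0.05, 0.75, by = 0.05),
                                seed = 1L, gamma = 0.25, rule = "AND",
                                cor_threshold = 0.70, confidence = 0.95) {
  stopifnot(inherits(data, "symptom_dataset"),
            all(diff(proportions) > 0),
            all(proportions > 0 & proportions < 1))
  metrics <- match.arg(metrics, several.ok = TRUE)
  p <- length(data$labels)
  if (ceiling(data$n * (1 - max(proportions))) < 3 * p)
    warning("largest drop proportion leaves fewer than 3 cases per node")

  full <- fit_ising(data, gamma = gamma, rule = rule)
  full_cent <- lapply(metrics, function(m) centrality_vector(full$weights, m))
  names(full_cent) <- metrics
  for (m in metrics) {
    if (stats::sd(full_cent[[m]]) == 0)
      stop("full-sample '", m, "' centrality is constant; ",
           "stability correlations are undefined for this metric")
  }

  and_rule <- as.integer(rule == "AND")
  set.seed(seed)
  rows <- vector("list", length(proportions) * n_boot)
  k <- 0
  for (q in proportions) {
    keep_n <- ceiling(data$n * (1 - q))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(data$n, keep_n)
      cs <- collapse_states(data$matrix[idx, , drop = FALSE])
      w <- suppressWarnings(
        fit_weights_from_counts(cs$states, cs$counts, gamma, and_rule))
      dimnames(w) <- list(data$labels, data$labels)
      cors <- vapply(metrics, function(m) {
        sub <- centrality_vector(w, m)
        if (stats::sd(sub) == 0) return(NA_real_)
        stats::cor(full_cent[[m]], sub)
      }, numeric(1))
      k <- k + 1
      rows[[k]] <- data.frame(metric = metrics, proportion = q, replicate = b,
                              correlation = unname(cors),
                              stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)
  rownames(correlations) <- NULL

  cs_coef <- vapply(metrics, function(m) {
    ok <- vapply(proportions, function(q) {
      r <- correlations$correlation[correlations$metric == m &
                                      correlations$proportion == q]
      # replicates with undefined correlation count as failures
      mean(!is.na(r) & r >= cor_threshold) >= confidence
    }, logical(1))
    if (!any(ok)) 0 else max(proportions[ok])
  }, numeric(1))

  structure(list(correlations = correlations, cs_coefficient = cs_coef,
                 proportions = proportions, n_boot = n_boot,
                 cor_threshold = cor_threshold, confidence = confidence,
                 seed = seed),
            class = "stability_result")
}

#' CS-coefficients of a stability result
#'
#' @param result A `stability_result`.
#' @return Named numeric vector of CS-coefficients.
#' @export
cs_coefficient <- function(result) {
  stopifnot(inherits(result, "stability_result"))
  result$cs_coefficient
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Case-dropping bootstrap:", x$n_boot, "replicates per proportion,",
      "grid", min(x$proportions), "-", max(x$proportions), "\n")
  cat("  CS-coefficient (cor >=", x$cor_threshold, "with prob >=",
      x$confidence, "):\n")
  for (m in names(x$cs_coefficient))
    cat(sprintf("    %-20s %.2f\n", m, x$cs_coefficient[[m]]))
  invisible(x)
}

#' Write stability correlations as tidy CSV
#'
#' @param result A `stability_result`.
#' @param path Output path.
#' @export
write_stability_csv <- function(result, path) {
  utils::write.csv(result$correlations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
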