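#' Pairwise Pearson correlation matrix of binary symptoms
#'
#' Standard Pearson r on the 0/1 columns, which for binary data equals the
#' phi coefficient. Zero-variance columns yield `NA` entries with a warning;
#' the diagonal is always 1.
#'
#' @param data A [symptom_dataset].
#' @return A `p x p` symmetric correlation matrix with symptom dimnames.
#' @export
pearson_matrix <- function(data) {
  stopifnot(inherits(data, "symptom_dataset"))
  m <- data$matrix
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance symptom(s): ",
            paste(data$labels[sds == 0], collapse = ", "),
            "; correlations set to NA")
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

# collapse an n x p binary matrix to its unique state table + counts
collapse_states <- function(m) {
  key <- as.vector(m %*% (2^(seq_len(ncol(m)) - 1)))
  tab <- tabulate(match(key, unique(key)))
  states <- m[!duplicated(key), , drop = FALSE]
  list(states = matrix(as.numeric(states), nrow(states), ncol(states)),
       counts = as.numeric(tab))
}

#' Estimate a regularized Ising network (eLASSO)
#'
#' Nodewise estimation of the Ising model for binary symptom data: for each
#' symptom, an L1-penalized logistic regression of that symptom on all others
#' is fit over a descending penalty path (100 log-spaced values from the
#' nodewise maximal penalty down to `lambda_min_ratio` times it), and the
#' penalty is chosen by minimizing the extended BIC
#' \deqn{\mathrm{EBIC} = -2\,\ell + k\log n + 2\gamma k \log(p-1),}
#' with ties broken toward the sparser model. The two directed coefficients
#' of each pair are combined into one symmetric edge weight by the `"AND"`
#' rule (both nonzero, averaged; the default) or the `"OR"` rule (either
#' nonzero; nonzero ones averaged). Node thresholds are the selected
#' intercepts. Zero-variance symptoms are retained as edge-free nodes with a
#' warning.
#'
#' @param data A [symptom_dataset].
#' @param gamma EBIC hyperparameter (default 0.25, the established eLASSO
#'   default).
#' @param rule Symmetrization rule, `"AND"` or `"OR"`.
#' @param nlambda,lambda_min_ratio Penalty path length and lower endpoint as
#'   a fraction of the nodewise maximal penalty.
#' @return An object of class `ising_network`: `labels`, `thresholds`,
#'   symmetric `weights` with zero diagonal, `gamma`, `rule`, plus the
#'   directed coefficient matrix and the sample size `n`.
#' @export
fit_ising <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                      nlambda = 100, lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "symptom_dataset"))
  rule <- match.arg(rule)
  p <- length(data$labels)
  if (data$n < 10 * p)
    warning("n = ", data$n, " is small for p = ", p,
            " (fewer than 10 cases per node)")
  cs <- collapse_states(data$matrix)
  fit <- .elasso_fit(cs$states, cs$counts, gamma,
                     as.integer(rule == "AND"),
                     as.integer(nlambda), lambda_min_ratio)
  if (any(fit$degenerate == 1))
    warning("zero-variance symptom(s) retained without edges: ",
            paste(data$labels[fit$degenerate == 1], collapse = ", "))
  w <- fit$weights
  dimnames(w) <- list(data$labels, data$labels)
  thresholds <- stats::setNames(as.numeric(fit$thresholds), data$labels)
  structure(list(labels = data$labels, thresholds = thresholds, weights = w,
                 gamma = gamma, rule = rule, directed = fit$directed,
                 n = data$n, group = data$group),
            class = "ising_network")
}

# fast path used inside permutation/bootstrap loops: states fixed, counts vary
fit_weights_from_counts <- function(states, counts, gamma, and_rule,
                                    nlambda = 100, lambda_min_ratio = 0.01) {
  keep <- counts > 0
  .elasso_fit(states[keep, , drop = FALSE], counts[keep], gamma, and_rule,
              as.integer(nlambda), lambda_min_ratio)$weights
}

#' Construct an Ising network object directly
#'
#' Mainly for tests and for networks produced outside [fit_ising()] (e.g. a
#' ground-truth model whose centrality is wanted).
#'
#' @inheritParams ising_parameters
#' @param gamma,rule Estimator settings to record (defaults `NA`, `"AND"`).
#' @return An `ising_network` object.
#' @export
ising_network <- function(labels, weights, thresholds = rep(0, length(labels)),
                          gamma = NA_real_, rule = "AND") {
  pars <- ising_parameters(labels, thresholds, weights)
  structure(list(labels = pars$labels, thresholds = pars$thresholds,
                 weights = pars$weights, gamma = gamma, rule = rule,
                 directed = NULL, n = NA_integer_, group = NA_character_),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Regularized Ising network: ", length(x$labels), " nodes, ", ne,
      " edges (gamma = ", x$gamma, ", ", x$rule, " rule",
      if (!is.na(x$n)) paste0(", n = ", x$n), ")\n", sep = "")
  if (ne > 0) {
    el <- edge_list(x)
    top <- el[order(-abs(el$weight)), ][seq_len(min(3, ne)), ]
    cat("  strongest edges:",
        paste(sprintf("%s--%s %.2f", top$node_i, top$node_j, top$weight),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Edge list of a network
#'
#' @param network An `ising_network`.
#' @param keep_zero Keep absent edges too?
#' @return Data frame with columns `node_i`, `node_j`, `weight`.
#' @export
edge_list <- function(network, keep_zero = FALSE) {
  w <- network$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(node_i = network$labels[idx[, 1]],
                    node_j = network$labels[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network as JSON or a weighted edge-list TSV
#'
#' @param network An `ising_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_json <- function(network, path) {
  obj <- list(labels = network$labels,
              thresholds = unname(network$thresholds),
              weights = matrix(t(network$weights),
                               nrow = nrow(network$weights), byrow = TRUE),
              gamma = network$gamma, rule = network$rule, n = network$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- ising_network(obj$labels, as.matrix(obj$weights), obj$thresholds,
                       gamma = obj$gamma, rule = obj$rule)
  net$n <- obj$n
  net
}

#' @rdname write_network_json
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(edge_list(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Force-directed layout coordinates
#'
#' Fruchterman-Reingold layout of the network with attraction proportional
#' to the absolute edge weight, so strongly connected symptoms are placed
#' close together; deterministic given the seed.
#'
#' @param network An `ising_network`.
#' @param seed Integer seed.
#' @param iterations Number of layout iterations.
#' @return Data frame with columns `node`, `x`, `y`.
#' @export
fr_layout <- function(network, seed = 1L, iterations = 500) {
  g <- igraph::graph_from_adjacency_matrix(abs(network$weights),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations,
                               weights = if (igraph::ecount(g) > 0)
                                 igraph::E(g)$weight else NULL)
  data.frame(node = network$labels, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
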