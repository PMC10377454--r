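as_length_graph <- function(network) {
  # geodesics use edge length 1/|w|: strong edges are short
  w <- abs(network$weights)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Node strength
#'
#' Sum of absolute edge weights at each node (the weighted number of
#' connections).
#'
#' @param network An `ising_network`.
#' @return Named numeric vector.
#' @export
node_strength <- function(network) {
  rowSums(abs(network$weights))
}

#' Expected influence
#'
#' Signed one-step expected influence: the sum of all (signed) edge weights
#' extending from each node.
#'
#' @param network An `ising_network`.
#' @return Named numeric vector.
#' @export
expected_influence <- function(network) {
  rowSums(network$weights)
}

#' Closeness centrality
#'
#' Inverse mean geodesic distance to the other nodes, with edge lengths
#' \eqn{1/|w_{ij}|}. On disconnected networks the mean is taken within the
#' node's connected component and scaled by (reachable - 1)/(p - 1); fully
#' isolated nodes get closeness 0.
#'
#' @param network An `ising_network`.
#' @return Named numeric vector.
#' @export
node_closeness <- function(network) {
  g <- as_length_graph(network)
  p <- length(network$labels)
  d <- igraph::distances(g, weights = if (igraph::ecount(g) > 0)
    igraph::E(g)$length else NULL)
  out <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    (sum(reach) / (p - 1)) / mean(di[reach])
  }, numeric(1))
  stats::setNames(out, network$labels)
}

#' Betweenness centrality
#'
#' Weighted shortest-path betweenness (Brandes accounting with fractional
#' credit for tied geodesics), edge lengths \eqn{1/|w_{ij}|}.
#'
#' @param network An `ising_network`.
#' @return Named numeric vector.
#' @export
node_betweenness <- function(network) {
  g <- as_length_graph(network)
  b <- igraph::betweenness(g, weights = if (igraph::ecount(g) > 0)
    igraph::E(g)$length else NULL, directed = FALSE)
  stats::setNames(as.numeric(b), network$labels)
}

#' Centrality table with z-standardization
#'
#' Computes Strength, Closeness, Betweenness and Expected Influence for every
#' node, each both raw and z-standardized across nodes (subtract the mean,
#' divide by the sample standard deviation; a constant metric yields z = 0
#' with a warning).
#'
#' @param network An `ising_network`.
#' @return A tidy data frame of class `centrality_table` with columns
#'   `node`, `metric`, `raw`, `z`.
#' @export
centrality_table <- function(network) {
  metrics <- list(strength = node_strength(network),
                  closeness = node_closeness(network),
                  betweenness = node_betweenness(network),
                  expected_influence = expected_influence(network))
  out <- do.call(rbind, lapply(names(metrics), function(m) {
    data.frame(node = network$labels, metric = m, raw = unname(metrics[[m]]),
               z = standardize(metrics[[m]]), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' z-standardize a metric across nodes
#'
#' @param x Numeric vector (length >= 2).
#' @return `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation;
#'   all zeros with a warning when the metric is constant.
#' @export
standardize <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) {
    warning("constant metric: z-scores set to 0")
    return(rep(0, length(x)))
  }
  unname((x - mean(x)) / s)
}

#' Small-world measures of a network
#'
#' Binarizes the network (any nonzero edge is present), computes the global
#' clustering coefficient C (transitivity) and the average shortest path
#' length L over connected pairs, and compares them with `n_random`
#' Erdős–Rényi G(n, m) graphs with the same node and edge counts. The
#' small-world index is
#' \deqn{\sigma = (C / \langle C_{rand}\rangle) / (L / \langle L_{rand}\rangle);}
#' a network is called a small world when the index exceeds 1.
#'
#' @param network An `ising_network`, or an igraph graph (used as-is).
#' @param n_random Number of reference random graphs.
#' @param seed Integer seed.
#' @return A list of class `small_world_result`: `clustering`,
#'   `avg_path_length`, `c_random`, `l_random`, `index`.
#' @export
small_world <- function(network, n_random = 1000, seed = 1L) {
  g <- if (inherits(network, "igraph")) network else {
    igraph::graph_from_adjacency_matrix(abs(network$weights) > 0,
                                        mode = "undirected", diag = FALSE)
  }
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (ne == 0) stop("small_world() needs a network with at least one edge")
  C <- igraph::transitivity(g, type = "global")
  if (is.nan(C)) C <- 0
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  set.seed(seed)
  cr <- numeric(n_random)
  lr <- numeric(n_random)
  for (b in seq_len(n_random)) {
    r <- igraph::sample_gnm(nv, ne)
    tb <- igraph::transitivity(r, type = "global")
    cr[b] <- if (is.nan(tb)) 0 else tb
    lr[b] <- igraph::mean_distance(r, directed = FALSE, unconnected = TRUE)
  }
  c_random <- mean(cr)
  l_random <- mean(lr)
  index <- if (c_random == 0) {
    warning("reference graphs have zero clustering: index undefined")
    NA_real_
  } else {
    (C / c_random) / (L / l_random)
  }
  structure(list(clustering = C, avg_path_length = L, c_random = c_random,
                 l_random = l_random, index = index, n_random = n_random),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "Small-world analysis: C = %.3f (random %.3f), L = %.3f (random %.3f)\n",
    x$clustering, x$c_random, x$avg_path_length, x$l_random))
  cat(sprintf("  index = %.3f -> %ssmall world (rule: index > 1)\n", x$index,
              if (isTRUE(x$index > 1)) "" else "not a "))
  invisible(x)
}

#' Write a centrality table as tidy CSV
#'
#' @param table A `centrality_table`.
#' @param path Output path.
#' @export
write_centrality_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
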