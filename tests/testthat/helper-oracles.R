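# Independent oracles and shared fixtures. Everything here is deliberately
# written the slow, obvious way (direct sums, explicit path enumeration) so
# it cannot share a code path with the implementation it checks.

# direct enumeration of an Ising distribution: plain exp-and-normalize,
# no log-sum-exp, loop over states
oracle_ising_probs <- function(thresholds, weights) {
  p <- length(thresholds)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
  pots <- apply(states, 1, function(x) {
    s <- sum(thresholds * x)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) s <- s + weights[i, j] * x[i] * x[j]
    }
    exp(s)
  })
  list(states = states, probs = pots / sum(pots))
}

# a fixed 9-node ground truth with 6 strong edges, used by the recovery and
# stability checks
recovery_truth <- function() {
  labels <- dsm5_symptoms()
  w <- matrix(0, 9, 9, dimnames = list(labels, labels))
  set_edge <- function(i, j, v) {
    w[i, j] <<- v
    w[j, i] <<- v
  }
  set_edge(1, 2, -1.0)
  set_edge(1, 9, 0.8)
  set_edge(2, 6, 0.6)
  set_edge(4, 9, 0.7)
  set_edge(7, 9, 0.9)
  set_edge(3, 5, 0.5)
  ising_parameters(labels, rep(-0.2, 9), w)
}

make_network <- function(w, labels = paste0("s", seq_len(nrow(w)))) {
  dimnames(w) <- list(labels, labels)
  ising_network(labels, w)
}

# all simple paths between two nodes by depth-first search
oracle_simple_paths <- function(adj, from, to) {
  p <- nrow(adj)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (nxt in seq_len(p)) {
      if (adj[last, nxt] != 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  out
}

# exhaustive-path centrality on a small weighted graph: geodesics found by
# enumerating every simple path with edge length 1/|w|
oracle_centrality <- function(w) {
  p <- nrow(w)
  strength <- rowSums(abs(w))
  ei <- rowSums(w)
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  geodesics <- vector("list", p * p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      paths <- oracle_simple_paths(w, i, j)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(pa) {
        sum(vapply(seq_len(length(pa) - 1), function(k) {
          1 / abs(w[pa[k], pa[k + 1]])
        }, numeric(1)))
      }, numeric(1))
      dmin <- min(lens)
      dist[i, j] <- dist[j, i] <- dmin
      geodesics[[(i - 1) * p + j]] <- paths[lens <= dmin * (1 + 1e-9)]
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    di <- dist[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    (sum(reach) / (p - 1)) / mean(di[reach])
  }, numeric(1))
  betweenness <- numeric(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      gs <- geodesics[[(i - 1) * p + j]]
      if (is.null(gs) || length(gs) == 0) next
      for (g in gs) {
        inner <- setdiff(g, c(i, j))
        for (v in inner) betweenness[v] <- betweenness[v] + 1 / length(gs)
      }
    }
  }
  list(strength = strength, closeness = closeness,
       betweenness = betweenness, expected_influence = ei)
}

# random connected weighted graph on 2..5 nodes with signed weights
random_small_graph <- function(pmax = 5) {
  p <- sample(2:pmax, 1)
  repeat {
    w <- matrix(0, p, p)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (stats::runif(1) < 0.6) {
          v <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 1.5)
          w[i, j] <- w[j, i] <- v
        }
      }
    }
    g <- igraph::graph_from_adjacency_matrix(abs(w) > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}

# small two-group cohort from the bundled synthetic models
tiny_cohort <- function(n_a = 150, n_b = 120, seed = 5,
                        constraint = dsm_constraint()) {
  sample_cohort(cohort_spec(
    c(A = n_a, B = n_b),
    list(A = example_parameters("mde"), B = example_parameters("ppd")),
    constraint = constraint, seed = seed))
}
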