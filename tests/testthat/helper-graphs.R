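# Small graphs used across the clustering tests.

graph_two_triangles <- function() {
  neighbor_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                          c(4, 5), c(5, 6), c(4, 6)))
}

graph_complete <- function(n) {
  neighbor_graph(n, t(utils::combn(n, 2)))
}

# two triangles bridged by a single edge (3-4)
graph_barbell <- function() {
  neighbor_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                          c(4, 5), c(5, 6), c(4, 6), c(3, 4)))
}

graph_path <- function(n) {
  neighbor_graph(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

graph_cycle <- function(n) {
  neighbor_graph(n, rbind(cbind(seq_len(n - 1), seq_len(n - 1) + 1),
                          c(n, 1)))
}

graph_star <- function(n) {
  neighbor_graph(n, cbind(1, 2:n))
}

graph_erdos <- function(n, p, seed) {
  withr::with_seed(seed, {
    full <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(full)) < p
    # guarantee at least one edge so the quality function is defined
    if (!any(keep)) keep[1] <- TRUE
    neighbor_graph(n, full[keep, , drop = FALSE])
  })
}

# the fixture family for exhaustive-oracle validation: assorted structured
# graphs plus seeded random graphs, all with <= 8 nodes
oracle_graph_family <- function() {
  fam <- list(
    triangles = graph_two_triangles(),
    k5 = graph_complete(5),
    k8 = graph_complete(8),
    barbell = graph_barbell(),
    path6 = graph_path(6),
    cycle8 = graph_cycle(8),
    star7 = graph_star(7)
  )
  for (s in 1:6) {
    n <- 6 + (s %% 3)
    fam[[paste0("er", s)]] <- graph_erdos(n, 0.5, seed = 100 + s)
  }
  fam
}

# random frozen-constraint initialisation for a graph
random_constrained_init <- function(graph, seed) {
  withr::with_seed(seed, {
    n <- graph$n_cells
    labels <- sample(0:2, n, replace = TRUE)
    frozen <- stats::runif(n) < 0.4
    partition(labels, frozen)
  })
}

frozen_pairs_consistent <- function(init, result) {
  fi <- which(init$frozen)
  if (length(fi) < 2) return(TRUE)
  for (a in fi) for (b in fi) {
    if (a >= b) next
    same_init <- init$labels[a] == init$labels[b]
    same_final <- result$labels[a] == result$labels[b]
    if (same_init != same_final) return(FALSE)
  }
  TRUE
}
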