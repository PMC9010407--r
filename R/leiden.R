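#' Clustering parameters
#'
#' @param k_neighbors neighbours per cell for the kNN graph (default 15).
#' @param resolution resolution parameter of the RB-configuration modularity
#'   quality function (default 1; larger values favour more, smaller
#'   clusters).
#' @param seed integer seed; every stochastic routine in the package takes
#'   an explicit seed so runs are byte-reproducible.
#' @param max_iterations cap on outer Leiden iterations (each iteration is a
#'   full local-move/refine/aggregate pass; iteration stops early once the
#'   quality no longer improves).
#' @param n_restarts number of independent seeded runs; the partition with
#'   the best quality is kept. Local moving is greedy, so restarts guard
#'   against poor local optima on small or awkward graphs (default 5).
#' @return a list of class \code{ClusterParams}.
#' @export
cluster_params <- function(k_neighbors = 15, resolution = 1.0, seed = 0L,
                           max_iterations = 20L, n_restarts = 5L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1", call. = FALSE)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 resolution = resolution, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts)),
            class = c("ClusterParams", "list"))
}

# --- internal weighted-graph representation -------------------------------
# adj/wts: parallel lists of neighbour indices and edge weights;
# selfw: internal (self-loop) weight per node, counted once;
# k: node strength = 2*selfw + sum of incident edge weights;
# m2: sum(k) = twice the total edge weight (constant across aggregation).
.graph_from_edges <- function(n, edges, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  adj <- vector("list", n)
  wts <- vector("list", n)
  if (nrow(edges)) {
    both_i <- c(edges[, 1], edges[, 2])
    both_j <- c(edges[, 2], edges[, 1])
    both_w <- c(weights, weights)
    o <- order(both_i)
    sp <- split(seq_along(both_i)[o], both_i[o])
    for (nm in names(sp)) {
      idx <- sp[[nm]]
      adj[[as.integer(nm)]] <- both_j[idx]
      wts[[as.integer(nm)]] <- both_w[idx]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(adj[[i]])) { adj[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  }
  selfw <- rep(0, n)
  k <- vapply(wts, sum, 0) + 2 * selfw
  list(n = n, adj = adj, wts = wts, selfw = selfw, k = k, m2 = sum(k))
}

# RB-configuration modularity on the internal graph representation
.quality <- function(g, comm, gamma) {
  if (g$m2 == 0) return(0)
  K <- tapply(g$k, comm, sum)
  e_in <- sum(g$selfw)
  for (v in seq_len(g$n)) {
    same <- comm[g$adj[[v]]] == comm[v]
    e_in <- e_in + sum(g$wts[[v]][same]) / 2
  }
  (2 * e_in) / g$m2 - gamma * sum(K^2) / g$m2^2
}

# Queue-based local moving. Frozen nodes (flab not NA) never move.
.local_move <- function(g, comm, flab, gamma) {
  n <- g$n
  comm_K <- rep(0, max(comm))
  agg <- tapply(g$k, comm, sum)
  comm_K[as.integer(names(agg))] <- agg
  movable <- which(is.na(flab))
  queue <- movable[sample.int(length(movable))]
  in_queue <- rep(FALSE, n); in_queue[queue] <- TRUE
  head <- 1L
  next_comm <- length(comm_K) + 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L; in_queue[v] <- FALSE
    old <- comm[v]
    nb <- g$adj[[v]]; wv <- g$wts[[v]]
    cand <- comm[nb]
    w_to <- tapply(wv, cand, sum)
    cand_ids <- as.integer(names(w_to))
    if (!old %in% cand_ids) { cand_ids <- c(cand_ids, old); w_to <- c(w_to, 0) }
    # candidate score: edge weight to community minus the configuration-null
    # expectation, community strength taken excluding v itself
    Kc <- comm_K[cand_ids]
    Kc[cand_ids == old] <- Kc[cand_ids == old] - g$k[v]
    score <- w_to - gamma * g$k[v] * Kc / g$m2
    # moving to a fresh empty community scores 0
    cand_ids <- c(cand_ids, -1L); score <- c(score, 0)
    cur <- score[cand_ids == old]
    ord <- order(-score, cand_ids)
    bestc <- cand_ids[ord[1]]; bests <- score[ord[1]]
    if (bests > cur + 1e-12 && bestc != old) {
      if (bestc == -1L) {
        bestc <- next_comm
        next_comm <- next_comm + 1L
        comm_K <- c(comm_K, rep(0, bestc - length(comm_K)))
      }
      comm[v] <- bestc
      comm_K[old] <- comm_K[old] - g$k[v]
      comm_K[bestc] <- comm_K[bestc] + g$k[v]
      push <- nb[comm[nb] != bestc & !in_queue[nb] & is.na(flab[nb])]
      if (length(push)) {
        queue <- c(queue, push)
        in_queue[push] <- TRUE
      }
    }
  }
  comm
}

# Refinement: inside each community, start from singleton units (cells that
# share a frozen label form one indivisible unit) and greedily merge units
# that are still unmerged into the best positive-gain refined community.
.refine <- function(g, comm, flab, gamma) {
  n <- g$n
  # units: frozen groups (per frozen label) and individual unfrozen nodes
  unit <- integer(n)
  fr_labels <- unique(flab[!is.na(flab)])
  u <- 0L
  for (fl in fr_labels) {
    u <- u + 1L
    unit[!is.na(flab) & flab == fl] <- u
  }
  for (v in which(is.na(flab))) { u <- u + 1L; unit[v] <- u }
  n_units <- u
  unit_comm <- comm[match(seq_len(n_units), unit)]
  unit_k <- as.numeric(tapply(g$k, unit, sum)[as.character(seq_len(n_units))])
  refined <- seq_len(n_units)       # refined community per unit
  ref_K <- unit_k                   # strength of each refined community
  ref_size <- rep(1L, n_units)      # units per refined community
  merged <- rep(FALSE, n_units)
  for (uu in sample(seq_len(n_units))) {
    if (merged[uu]) next
    members <- which(unit == uu)
    # weights from this unit to refined communities within the same community
    nb <- unlist(g$adj[members], use.names = FALSE)
    wv <- unlist(g$wts[members], use.names = FALSE)
    ok <- comm[nb] == unit_comm[uu] & unit[nb] != uu
    if (!any(ok)) next
    tgt <- refined[unit[nb[ok]]]
    w_to <- tapply(wv[ok], tgt, sum)
    tgt_ids <- as.integer(names(w_to))
    score <- w_to - gamma * unit_k[uu] * ref_K[tgt_ids] / g$m2
    ord <- order(-score, tgt_ids)
    if (score[ord[1]] > 1e-12) {
      r_old <- refined[uu]; r_new <- tgt_ids[ord[1]]
      refined[uu] <- r_new
      ref_K[r_old] <- ref_K[r_old] - unit_k[uu]
      ref_K[r_new] <- ref_K[r_new] + unit_k[uu]
      ref_size[r_old] <- ref_size[r_old] - 1L
      ref_size[r_new] <- ref_size[r_new] + 1L
      merged[uu] <- TRUE
      merged[r_new] <- TRUE  # target root stays put once it has absorbed
    }
  }
  refined[unit]  # per-node refined community id (non-contiguous is fine)
}

# Agglomerative sweep: repeatedly apply the best positive-gain merge of two
# whole communities. Complements node-level local moving, which cannot see
# multi-node merges. Communities holding different frozen labels never merge.
.merge_communities <- function(g, comm, flab, gamma) {
  repeat {
    ids <- sort(unique(comm))
    if (length(ids) < 2) break
    K <- rep(0, max(ids))
    agg <- tapply(g$k, comm, sum)
    K[as.integer(names(agg))] <- agg
    cf <- rep(NA_integer_, max(ids))
    for (v in which(!is.na(flab))) cf[comm[v]] <- flab[v]
    # inter-community edge weights
    keys <- character(0); wsum <- numeric(0)
    ei <- integer(0); ej <- integer(0); ew <- numeric(0)
    for (v in seq_len(g$n)) {
      nb <- g$adj[[v]]
      sel <- nb > v & comm[nb] != comm[v]
      if (any(sel)) {
        ei <- c(ei, rep(comm[v], sum(sel)))
        ej <- c(ej, comm[nb[sel]])
        ew <- c(ew, g$wts[[v]][sel])
      }
    }
    if (!length(ei)) break
    key <- paste(pmin(ei, ej), pmax(ei, ej))
    w_cd <- rowsum(ew, key)
    pr <- do.call(rbind, strsplit(rownames(w_cd), " "))
    ca <- as.integer(pr[, 1]); cb <- as.integer(pr[, 2])
    gain <- 2 * as.numeric(w_cd) / g$m2 -
      gamma * 2 * K[ca] * K[cb] / g$m2^2
    feasible <- is.na(cf[ca]) | is.na(cf[cb]) | cf[ca] == cf[cb]
    gain[!feasible] <- -Inf
    best <- which.max(gain)
    if (gain[best] <= 1e-12) break
    comm[comm == cb[best]] <- ca[best]
  }
  comm
}

# Collapse refined communities into super-nodes, carrying community
# assignment and frozen labels along.
.aggregate <- function(g, refined, comm, flab) {
  ids <- unique(refined)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  rnode <- remap[refined]          # per-flat-node aggregate index
  n2 <- length(ids)
  selfw2 <- rep(0, n2)
  k2 <- as.numeric(tapply(g$k, rnode, sum)[as.character(seq_len(n2))])
  # accumulate inter-aggregate weights
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (v in seq_len(g$n)) {
    nb <- g$adj[[v]]; wv <- g$wts[[v]]
    rv <- rnode[v]; rn <- rnode[nb]
    internal <- rn == rv
    selfw2[rv] <- selfw2[rv] + sum(wv[internal]) / 2 + g$selfw[v]
    keep <- which(!internal & nb > v)
    if (length(keep)) {
      ei <- c(ei, rep(rv, length(keep))); ej <- c(ej, rn[keep])
      ew <- c(ew, wv[keep])
    }
  }
  if (length(ei)) {
    key <- paste(pmin(ei, ej), pmax(ei, ej))
    agg <- rowsum(ew, key)
    pr <- do.call(rbind, strsplit(rownames(agg), " "))
    edges2 <- cbind(as.integer(pr[, 1]), as.integer(pr[, 2]))
    w2 <- as.numeric(agg)
  } else {
    edges2 <- matrix(integer(0), ncol = 2); w2 <- numeric(0)
  }
  g2 <- .graph_from_edges(n2, edges2, w2)
  g2$selfw <- selfw2
  g2$k <- k2
  g2$m2 <- sum(k2)
  comm2 <- comm[match(seq_len(n2), rnode)]
  flab2 <- rep(NA_integer_, n2)
  for (i in seq_len(n2)) {
    fl <- flab[rnode == i]
    fl <- fl[!is.na(fl)]
    if (length(fl)) flab2[i] <- fl[1]
  }
  list(g = g2, comm = comm2, flab = flab2, rnode = rnode)
}

# One full Leiden pass: returns the improved flat community vector.
.leiden_pass <- function(g0, comm0, flab0, gamma) {
  g <- g0; comm <- comm0; flab <- flab0
  node_of <- seq_len(g0$n)  # flat node -> current aggregate node
  repeat {
    comm <- .local_move(g, comm, flab, gamma)
    flat_comm <- comm[node_of]
    sizes <- table(comm)
    if (all(sizes == 1L)) break
    refined <- .refine(g, comm, flab, gamma)
    if (length(unique(refined)) == g$n) break  # aggregation would be a no-op
    ag <- .aggregate(g, refined, comm, flab)
    node_of <- ag$rnode[node_of]
    g <- ag$g; comm <- ag$comm; flab <- ag$flab
  }
  comm[node_of]
}

.leiden_engine <- function(graph, init_labels, frozen, resolution, seed,
                           max_iterations, n_restarts = 5L) {
  n <- graph$n_cells
  if (n == 0) stop("empty graph", call. = FALSE)
  g <- .graph_from_edges(n, graph$edges)
  comm0 <- as.integer(factor(init_labels, levels = unique(init_labels)))
  best_comm <- NULL
  best_q <- -Inf
  # tiny graphs have the most treacherous local optima and the cheapest
  # restarts, so the search budget is raised there
  if (n <= 32) n_restarts <- max(n_restarts, 20L)
  for (r in seq_len(n_restarts)) {
    withr::with_seed(seed + r - 1L, {
      comm <- comm0
      if (r > 1) {
        # diversify later restarts: unfrozen nodes start in random groups
        # (frozen nodes always keep their initial communities)
        # candidate groups include the initial (frozen) communities, so a
        # restart can seed unfrozen nodes inside frozen communities too
        G <- max(comm0) + sample.int(min(n, 10L), 1)
        free <- which(!frozen)
        comm[free] <- sample.int(G, length(free), replace = TRUE)
      }
      flab <- ifelse(frozen, comm, NA_integer_)
      q <- if (r == 1) .quality(g, comm, resolution) else -Inf
      for (it in seq_len(max_iterations)) {
        comm_new <- .leiden_pass(g, comm, flab, resolution)
        comm_new <- .merge_communities(g, comm_new, flab, resolution)
        q_new <- .quality(g, comm_new, resolution)
        if (q_new <= q + 1e-12) break
        comm <- comm_new
        flab <- ifelse(frozen, comm, NA_integer_)
        q <- q_new
      }
    })
    if (q > best_q + 1e-12) { best_q <- q; best_comm <- comm }
  }
  canonicalize(partition(best_comm - 1L, frozen))
}

#' Leiden community detection
#'
#' Finds a partition of the neighbour graph that (locally) maximizes the
#' RB-configuration modularity at the given resolution, using the Leiden
#' scheme of queue-based local moving, refinement, and graph aggregation,
#' iterated until the quality stops improving. Deterministic given
#' \code{p$seed}; labels are canonicalized to 0..K-1.
#'
#' @param graph a \code{NeighborGraph}.
#' @param p a \code{ClusterParams}.
#' @return a \code{Partition}.
#' @export
leiden <- function(graph, p = cluster_params()) {
  n <- graph$n_cells
  if (n == 0) stop("empty graph", call. = FALSE)
  .leiden_engine(graph, init_labels = seq_len(n) - 1L,
                 frozen = rep(FALSE, n), resolution = p$resolution,
                 seed = p$seed, max_iterations = p$max_iterations,
                 n_restarts = p$n_restarts)
}

#' Semi-supervised Leiden with frozen clusters
#'
#' Constrained variant used to refine transferred labels: cells marked
#' frozen in \code{init} keep their initial co-membership throughout — any
#' two frozen cells sharing an initial label end in the same community, any
#' two with different initial labels end in different communities — while
#' unfrozen cells move freely, including into frozen communities. Frozen
#' sets are never split by refinement and the constraint is carried onto
#' super-nodes during aggregation. Quality never decreases across
#' iterations given the constraints.
#'
#' @param graph a \code{NeighborGraph}.
#' @param init a \code{Partition} covering every node, whose \code{frozen}
#'   mask marks the constrained cells.
#' @param p a \code{ClusterParams}.
#' @return a \code{Partition} (canonicalized; frozen mask preserved).
#' @export
leiden_semisupervised <- function(graph, init, p = cluster_params()) {
  n <- graph$n_cells
  if (length(init$labels) != n)
    stop("init covers ", length(init$labels), " nodes but the graph has ", n,
         call. = FALSE)
  if (length(init$frozen) != n)
    stop("frozen mask length ", length(init$frozen), " != number of nodes ",
         n, call. = FALSE)
  .leiden_engine(graph, init_labels = init$labels, frozen = init$frozen,
                 resolution = p$resolution, seed = p$seed,
                 max_iterations = p$max_iterations,
                 n_restarts = p$n_restarts)
}

#' Partition quality (RB-configuration modularity)
#'
#' The objective maximized by \code{\link{leiden}}:
#' \deqn{Q = \frac{1}{2m}\sum_c \left(2 e_c - \gamma \frac{K_c^2}{2m}\right)}
#' where \eqn{e_c} is the edge weight inside cluster c, \eqn{K_c} the summed
#' degree of its nodes, m the total edge weight and \eqn{\gamma} the
#' resolution.
#'
#' @param graph a \code{NeighborGraph}.
#' @param part a \code{Partition} over the graph's nodes.
#' @param resolution the resolution parameter \eqn{\gamma}.
#' @return the scalar quality.
#' @export
partition_quality <- function(graph, part, resolution = 1.0) {
  g <- .graph_from_edges(graph$n_cells, graph$edges)
  .quality(g, part$labels + 1L, resolution)
}

#' Exhaustive search for the best (constrained) partition
#'
#' Enumerates every set partition of the graph's nodes (restricted-growth
#' strings), optionally filtered to those satisfying frozen-cluster
#' constraints, and returns the quality maximizer. Only feasible for tiny
#' graphs (Bell(n) grows fast; n <= 10 or so); intended as an exact oracle
#' for validating \code{\link{leiden}} and
#' \code{\link{leiden_semisupervised}}.
#'
#' @param graph a \code{NeighborGraph} with few nodes.
#' @param resolution quality resolution.
#' @param init optional \code{Partition} carrying the frozen constraints.
#' @return list with \code{partition} (a \code{Partition}) and
#'   \code{quality}.
#' @export
best_partition_exhaustive <- function(graph, resolution = 1.0, init = NULL) {
  n <- graph$n_cells
  if (n > 12) stop("exhaustive search is limited to n <= 12", call. = FALSE)
  g <- .graph_from_edges(n, graph$edges)
  best_q <- -Inf; best <- NULL
  for (labs in .set_partitions(n)) {
    if (!is.null(init) && any(init$frozen) &&
        !.satisfies_constraints(labs, init)) next
    q <- .quality(g, labs, resolution)
    if (q > best_q + 1e-12) { best_q <- q; best <- labs }
  }
  if (is.null(best)) stop("no constraint-satisfying partition", call. = FALSE)
  list(partition = canonicalize(partition(best - 1L,
                                          if (is.null(init)) rep(FALSE, n)
                                          else init$frozen)),
       quality = best_q)
}

# all set partitions of n items as restricted growth strings (1-based)
.set_partitions <- function(n) {
  out <- list()
  rec <- function(labs, mx) {
    if (length(labs) == n) { out[[length(out) + 1L]] <<- labs; return() }
    for (l in seq_len(mx + 1L)) rec(c(labs, l), max(mx, l))
  }
  rec(integer(0), 0L)
  out
}

# frozen cells sharing an init label must share a final label; frozen cells
# with different init labels must differ
.satisfies_constraints <- function(labs, init) {
  fi <- which(init$frozen)
  if (length(fi) < 2) return(TRUE)
  grp <- init$labels[fi]
  fin <- labs[fi]
  for (a in seq_along(fi)) {
    for (b in seq_along(fi)) {
      if (a >= b) next
      if (grp[a] == grp[b] && fin[a] != fin[b]) return(FALSE)
      if (grp[a] != grp[b] && fin[a] == fin[b]) return(FALSE)
    }
  }
  TRUE
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency-table closed
#' form; 1 means identical up to relabelling, 0 is the expectation under
#' random labelling, and values can be negative.
#'
#' @param a,b \code{Partition}s (or plain label vectors) of equal length.
#' @return the ARI, a scalar in [-1, 1].
#' @export
ari <- function(a, b) {
  la <- if (inherits(a, "Partition")) a$labels else a
  lb <- if (inherits(b, "Partition")) b$labels else b
  if (length(la) != length(lb))
    stop("partitions have different lengths (", length(la), " vs ",
         length(lb), ")", call. = FALSE)
  n <- length(la)
  tab <- table(la, lb)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
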