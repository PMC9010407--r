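#' Dimensionality-reduction parameters
#'
#' @param n_components dimensionality of the clustering embedding
#'   (default 40, the usual PCA depth for single-cell matrices).
#' @param method one of \code{"pca"}, \code{"umap"}, \code{"precomputed"}.
#'   \code{"umap"} as the clustering reduction is the spatial-proteomics
#'   path, where a 10-dimensional UMAP replaces PCA; \code{"precomputed"}
#'   accepts an externally computed reduction (e.g. a cell-by-topic matrix)
#'   loaded via \code{\link{read_csv_matrix}}.
#' @param umap_dims dimensionality when \code{method = "umap"} (default 10).
#' @param seed integer seed for stochastic methods.
#' @return a list of class \code{ReductionParams}.
#' @export
reduction_params <- function(n_components = 40, method = "pca",
                             umap_dims = 10, seed = 0L) {
  method <- match.arg(method, c("pca", "umap", "precomputed"))
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  structure(list(n_components = as.integer(n_components), method = method,
                 umap_dims = as.integer(umap_dims), seed = as.integer(seed)),
            class = c("ReductionParams", "list"))
}

#' Principal component embedding
#'
#' Stores a cells x n_components embedding named \code{"reduced"},
#' components ordered by decreasing explained variance. Columns are not
#' re-centred or re-scaled here: run \code{\link{scale_unit_variance}}
#' first (the standard pipeline does).
#'
#' @param m an \code{AnnotatedMatrix} with (scaled) values.
#' @param p a \code{ReductionParams}.
#' @param key name under which the embedding is stored.
#' @return the \code{AnnotatedMatrix} with the embedding added; explained
#'   variances are attached to the embedding as attribute
#'   \code{"explained_variance"}.
#' @export
reduce_pca <- function(m, p = reduction_params(), key = "reduced") {
  x <- as.matrix(m$values)
  max_nc <- min(nrow(x) - 1L, ncol(x))
  if (p$n_components > max_nc)
    stop("n_components = ", p$n_components, " exceeds the admissible maximum ",
         max_nc, " for ", nrow(x), " cells x ", ncol(x), " features",
         call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = p$n_components)
  emb <- pc$x[, seq_len(p$n_components), drop = FALSE]
  rownames(emb) <- m$cell_ids
  attr(emb, "explained_variance") <- pc$sdev[seq_len(p$n_components)]^2
  out <- m
  out$embeddings[[key]] <- emb
  out
}

#' UMAP embedding
#'
#' Non-linear embedding of a source embedding (or, failing that, the raw
#' values), used both for 2-D visualization and, on spatial-proteomics
#' data, as a 10-dimensional clustering representation. Deterministic given
#' \code{seed}.
#'
#' @param m an \code{AnnotatedMatrix}.
#' @param n_dims output dimensionality (2 for visualization).
#' @param source name of the source embedding (default \code{"reduced"};
#'   falls back to the values matrix when absent).
#' @param key name under which the embedding is stored.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size.
#' @return the \code{AnnotatedMatrix} with the embedding added.
#' @export
reduce_umap <- function(m, n_dims = 2, source = "reduced", key = "umap",
                        seed = 0L, n_neighbors = 15) {
  x <- m$embeddings[[source]]
  if (is.null(x)) x <- as.matrix(m$values)
  if (nrow(x) <= n_neighbors)
    stop("need more cells (", nrow(x), ") than n_neighbors (", n_neighbors,
         ")", call. = FALSE)
  emb <- withr::with_seed(as.integer(seed),
    uwot::umap(as.matrix(x), n_components = n_dims,
               n_neighbors = n_neighbors, n_threads = 1, n_sgd_threads = 1,
               batch = TRUE))
  rownames(emb) <- m$cell_ids
  out <- m
  out$embeddings[[key]] <- emb
  out
}

#' Exact k-nearest-neighbour graph
#'
#' For each cell, its k nearest neighbours by Euclidean distance (self
#' excluded; ties broken towards the lower cell index). The directed
#' neighbour lists are symmetrized by union into an undirected, unweighted
#' graph, so each node ends with degree >= k (unless the graph has fewer
#' than k+1 nodes). The search is exact.
#'
#' @param embedding numeric matrix, cells x d.
#' @param k neighbours per cell.
#' @return a \code{NeighborGraph}.
#' @export
build_knn_graph <- function(embedding, k = 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n)
    stop("k = ", k, " must be smaller than the number of cells (", n, ")",
         call. = FALSE)
  if (n <= 2000) {
    # brute-force with explicit lowest-index tie-breaking
    d <- as.matrix(stats::dist(embedding))
    diag(d) <- Inf
    nn_idx <- t(apply(d, 1, function(r) order(r, seq_len(n))[seq_len(k)]))
  } else {
    nn_idx <- FNN::get.knn(embedding, k = k)$nn.index
  }
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn_idx))
  neighbor_graph(n, cbind(from, to), k = k)
}
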