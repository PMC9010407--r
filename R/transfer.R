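#' Fit a reference-to-query transfer model
#'
#' Restricts the reference to the genes shared with the query (in reference
#' feature order), scales them to zero mean / unit variance using reference
#' statistics, fits a PCA latent space on the reference only (components
#' capped at the admissible maximum), and embeds the reference cells.
#'
#' @param reference an \code{AnnotatedMatrix} with normalized values and a
#'   label column in \code{cell_meta}.
#' @param label_key name of the label column.
#' @param query_features character vector of the query's feature ids.
#' @param n_components latent dimensionality (default 40).
#' @return a list of class \code{TransferModel}: \code{overlapping_genes},
#'   \code{reference_means}, \code{reference_sds}, \code{rotation},
#'   \code{reference_embedding}, \code{reference_labels}.
#' @export
fit_transfer <- function(reference, label_key, query_features,
                         n_components = 40) {
  if (!label_key %in% names(reference$cell_meta))
    stop("label key '", label_key, "' not in reference cell_meta",
         call. = FALSE)
  shared <- reference$feature_ids[reference$feature_ids %in% query_features]
  if (length(shared) < 2)
    stop("gene intersection too small (", length(shared), " genes); ",
         "reference features look like: ",
         paste(utils::head(reference$feature_ids, 3), collapse = ", "),
         "; query features look like: ",
         paste(utils::head(query_features, 3), collapse = ", "),
         call. = FALSE)
  x <- as.matrix(reference$values[, shared, drop = FALSE])
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sd_div <- ifelse(sd_pop > 0, sd_pop, 1)
  xs <- sweep(sweep(x, 2, mu), 2, sd_div, "/")
  nc <- min(n_components, nrow(xs) - 1L, ncol(xs))
  pc <- stats::prcomp(xs, center = TRUE, scale. = FALSE, rank. = nc)
  structure(list(overlapping_genes = shared,
                 reference_means = mu, reference_sds = sd_div,
                 center = pc$center,
                 rotation = pc$rotation[, seq_len(nc), drop = FALSE],
                 reference_embedding = pc$x[, seq_len(nc), drop = FALSE],
                 reference_labels = reference$cell_meta[[label_key]]),
            class = c("TransferModel", "list"))
}

#' Transfer labels from reference to query
#'
#' The query is restricted to the shared genes, scaled with the REFERENCE
#' means and standard deviations (the latent space was fit on reference
#' data, so query cells must enter it through the same map), projected by
#' the reference-fit rotation, and each query cell is labelled by majority
#' vote among its k nearest reference cells in the latent space. Vote ties
#' are broken by the larger summed inverse distance, then by the smaller
#' label. The per-cell confidence is the fraction of voting neighbours that
#' agree with the winning label, in [1/k, 1].
#'
#' @param model a \code{TransferModel}.
#' @param query an \code{AnnotatedMatrix} containing all shared genes.
#' @param k voting neighbours (default 15).
#' @return a list of class \code{TransferResult}: \code{labels},
#'   \code{confidence}, \code{embedding} (the query's latent coordinates).
#' @export
transfer_labels <- function(model, query, k = 15) {
  n_ref <- nrow(model$reference_embedding)
  if (k > n_ref)
    stop("k = ", k, " exceeds the number of reference cells (", n_ref, ")",
         call. = FALSE)
  missing <- setdiff(model$overlapping_genes, query$feature_ids)
  if (length(missing))
    stop("query lacks ", length(missing), " model gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  xq <- as.matrix(query$values[, model$overlapping_genes, drop = FALSE])
  xq <- sweep(sweep(xq, 2, model$reference_means), 2, model$reference_sds, "/")
  emb <- sweep(xq, 2, model$center) %*% model$rotation
  nn <- FNN::get.knnx(model$reference_embedding, emb, k = k)
  ref_labels <- model$reference_labels
  if (is.factor(ref_labels)) ref_labels <- as.character(ref_labels)
  n_q <- nrow(emb)
  labels <- vector(mode = if (is.numeric(ref_labels)) "numeric" else
                     "character", length = n_q)
  confidence <- numeric(n_q)
  for (i in seq_len(n_q)) {
    votes <- ref_labels[nn$nn.index[i, ]]
    d <- nn$nn.dist[i, ]
    tal <- table(votes)
    top <- names(tal)[tal == max(tal)]
    if (length(top) > 1) {
      invd <- vapply(top, function(l)
        sum(1 / pmax(d[votes == l], 1e-12)), 0)
      top <- top[invd == max(invd)]
      top <- if (is.numeric(ref_labels)) top[order(as.numeric(top))][1]
             else sort(top)[1]
    }
    labels[i] <- if (is.numeric(ref_labels)) as.numeric(top) else top
    confidence[i] <- max(tal) / k
  }
  structure(list(labels = labels, confidence = confidence, embedding = emb),
            class = c("TransferResult", "list"))
}

#' Freeze high-confidence clusters
#'
#' Marks as frozen every cell of each cluster whose median transfer
#' confidence reaches the threshold — the operational reading of "least
#' noisy" clusters. An explicit \code{override} list of cluster ids freezes
#' exactly those clusters instead, supporting expert manual choices.
#'
#' @param result a \code{TransferResult} aligned with \code{part}.
#' @param part a \code{Partition} over the same cells.
#' @param min_median_confidence threshold in (0, 1] (default 0.9).
#' @param override optional integer vector of cluster ids to freeze
#'   unconditionally (ignoring confidence).
#' @return the \code{Partition} with its frozen mask set.
#' @export
select_frozen_clusters <- function(result, part, min_median_confidence = 0.9,
                                   override = NULL) {
  if (min_median_confidence <= 0 || min_median_confidence > 1)
    stop("min_median_confidence must be in (0, 1]", call. = FALSE)
  if (length(result$confidence) != length(part$labels))
    stop("transfer result covers ", length(result$confidence),
         " cells but the partition has ", length(part$labels), call. = FALSE)
  if (!is.null(override)) {
    frozen_clusters <- as.integer(override)
  } else {
    med <- tapply(result$confidence, part$labels, stats::median)
    frozen_clusters <- as.integer(names(med)[med >= min_median_confidence])
  }
  partition(part$labels, part$labels %in% frozen_clusters)
}

#' Transfer labels and refine them with constrained clustering
#'
#' The full supervised-assignment path: fit the transfer model on the
#' reference, transfer labels to the query by neighbour voting, build the
#' query's own kNN graph on its own PCA embedding, freeze the
#' high-confidence clusters, and run semi-supervised Leiden initialized
#' from the transferred labels so that noisy, low-confidence regions are
#' re-clustered while trusted clusters stay fixed.
#'
#' @param reference,query preprocessed \code{AnnotatedMatrix} objects
#'   (normalized comparably).
#' @param label_key label column in the reference's \code{cell_meta}.
#' @param p a \code{ClusterParams} (k also used for voting).
#' @param n_components latent dimensionality for both the transfer model
#'   and the query's own embedding.
#' @param min_median_confidence freezing threshold.
#' @param override optional explicit cluster ids to freeze.
#' @return list with \code{refined} (a \code{Partition}), \code{transferred}
#'   (the pre-refinement \code{Partition}), \code{result} (the
#'   \code{TransferResult}) and \code{label_levels} (mapping of partition
#'   labels back to reference label values).
#' @export
transfer_and_refine <- function(reference, query, label_key,
                                p = cluster_params(), n_components = 40,
                                min_median_confidence = 0.9, override = NULL) {
  model <- fit_transfer(reference, label_key, query$feature_ids, n_components)
  res <- transfer_labels(model, query, k = p$k_neighbors)
  levels_ <- sort(unique(model$reference_labels))
  transferred <- partition(match(res$labels, levels_) - 1L)
  # the query is clustered on its own latent space, not the reference's
  nc <- min(n_components, n_cells(query) - 1L, n_features(query))
  q_emb <- reduce_pca(scale_unit_variance(query),
                      reduction_params(n_components = nc, seed = p$seed))
  graph <- build_knn_graph(q_emb$embeddings[["reduced"]], k = p$k_neighbors)
  init <- select_frozen_clusters(res, transferred, min_median_confidence,
                                 override)
  refined <- leiden_semisupervised(graph, init, p)
  list(refined = refined, transferred = canonicalize(transferred),
       result = res, label_levels = levels_)
}

#' Copy labels between datasets by shared cell id
#'
#' Joint-modality helper: cells of \code{target} whose id appears in
#' \code{source} receive the source's label; the rest get the explicit
#' label \code{"unassigned"}. Zero matches is a warning, not an error.
#'
#' @param source an \code{AnnotatedMatrix} with labels under
#'   \code{label_key}.
#' @param target an \code{AnnotatedMatrix}.
#' @param label_key label column in the source's \code{cell_meta}.
#' @param unassigned value given to unmatched target cells.
#' @return \code{target} with the label column added to its
#'   \code{cell_meta}; the number of matched cells is attached as attribute
#'   \code{"n_matched"}.
#' @export
copy_labels_by_cell_id <- function(source, target, label_key,
                                   unassigned = "unassigned") {
  if (!label_key %in% names(source$cell_meta))
    stop("label key '", label_key, "' not in source cell_meta", call. = FALSE)
  idx <- match(target$cell_ids, source$cell_ids)
  labels <- as.character(source$cell_meta[[label_key]])[idx]
  n_matched <- sum(!is.na(idx))
  if (n_matched == 0)
    warning("no shared cell ids between source and target; ",
            "all target cells left unassigned")
  labels[is.na(idx)] <- unassigned
  out <- target
  out$cell_meta[[label_key]] <- labels
  attr(out, "n_matched") <- n_matched
  message("copy_labels_by_cell_id: matched ", n_matched, " of ",
          length(target$cell_ids), " target cells")
  out
}

#' Write transfer results as TSV
#'
#' @param m an \code{AnnotatedMatrix} providing cell ids.
#' @param result a \code{TransferResult}.
#' @param path output TSV with columns cell_id, label, confidence.
#' @return invisibly, \code{path}.
#' @export
write_transfer_tsv <- function(m, result, path) {
  utils::write.table(
    data.frame(cell_id = m$cell_ids, label = result$labels,
               confidence = result$confidence),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
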