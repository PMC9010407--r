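#' Annotated cell-by-feature matrix
#'
#' The central container of the package: a cells x features numeric matrix
#' (raw counts or transformed values) together with per-cell and per-feature
#' metadata tables, named embeddings, and named layers (e.g. raw counts kept
#' under layer \code{"counts"} after normalization).
#'
#' Rows are always cells and columns are always features, whatever the
#' on-disk orientation was. Cell and feature identifiers must be unique;
#' duplicates are rejected rather than merged, because silent merging
#' corrupts downstream label transfer by cell ID.
#'
#' @param values numeric matrix or sparse \code{Matrix}, cells x features.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   the row names of \code{values}).
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to the column names of \code{values}).
#' @param cell_meta data.frame of per-cell annotations (labels, spatial x/y).
#' @param feature_meta data.frame of per-feature annotations.
#' @param embeddings named list of cells x d numeric matrices.
#' @param layers named list of matrices with the same shape as \code{values};
#'   a layer named \code{"counts"} must be non-negative.
#'
#' @return An object of class \code{AnnotatedMatrix}.
#' @export
AnnotatedMatrix <- function(values, cell_ids = rownames(values),
                            feature_ids = colnames(values),
                            cell_meta = NULL, feature_meta = NULL,
                            embeddings = list(), layers = list()) {
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  values <- .as_backing(values)
  if (nrow(values) != length(cell_ids))
    stop("values has ", nrow(values), " rows but there are ",
         length(cell_ids), " cell ids", call. = FALSE)
  if (ncol(values) != length(feature_ids))
    stop("values has ", ncol(values), " columns but there are ",
         length(feature_ids), " feature ids", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(utils::head(unique(feature_ids[duplicated(feature_ids)]), 5),
               collapse = ", "), call. = FALSE)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta has ", nrow(cell_meta), " rows; expected ",
           length(cell_ids), call. = FALSE)
    rownames(cell_meta) <- cell_ids
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(row.names = feature_ids)
  } else {
    feature_meta <- as.data.frame(feature_meta)
    if (nrow(feature_meta) != length(feature_ids))
      stop("feature_meta has ", nrow(feature_meta), " rows; expected ",
           length(feature_ids), call. = FALSE)
    rownames(feature_meta) <- feature_ids
  }
  for (nm in names(embeddings)) {
    if (nrow(embeddings[[nm]]) != length(cell_ids))
      stop("embedding '", nm, "' has ", nrow(embeddings[[nm]]),
           " rows; expected ", length(cell_ids), call. = FALSE)
  }
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    if (!all(dim(ly) == dim(values)))
      stop("layer '", nm, "' shape differs from values", call. = FALSE)
    if (nm == "counts" && min_value(ly) < 0)
      stop("layer 'counts' contains negative values", call. = FALSE)
    layers[[nm]] <- .as_backing(ly)
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 feature_ids = feature_ids, cell_meta = cell_meta,
                 feature_meta = feature_meta, embeddings = embeddings,
                 layers = layers),
            class = "AnnotatedMatrix")
}

# Sparse backing whenever density < 50%; dense base matrix otherwise.
# All operations must give identical results for either backing.
.as_backing <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    dens <- Matrix::nnzero(x) / prod(dim(x))
    if (dens >= 0.5) return(as.matrix(x))
    return(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dens <- sum(x != 0) / max(1, prod(dim(x)))
  if (prod(dim(x)) > 0 && dens < 0.5)
    return(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"))
  x
}

min_value <- function(x) if (length(x) == 0 || prod(dim(x)) == 0) 0 else min(x)

#' @export
dim.AnnotatedMatrix <- function(x) dim(x$values)

#' @export
print.AnnotatedMatrix <- function(x, ...) {
  cat("AnnotatedMatrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " features\n", sep = "")
  if (length(x$layers)) cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (length(x$embeddings))
    cat("embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  if (ncol(x$cell_meta))
    cat("cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells / features
#' @param m an \code{AnnotatedMatrix}.
#' @return integer count.
#' @export
n_cells <- function(m) nrow(m$values)

#' @rdname n_cells
#' @export
n_features <- function(m) ncol(m$values)

#' Subset an AnnotatedMatrix by cells and/or features
#'
#' Subsetting carries metadata, layers and embeddings along, so QC filters
#' never desynchronise the container.
#'
#' @param m an \code{AnnotatedMatrix}.
#' @param cells,features integer or logical index vectors (default: keep all).
#' @return the subsetted \code{AnnotatedMatrix}.
#' @export
am_subset <- function(m, cells = NULL, features = NULL) {
  ci <- if (is.null(cells)) seq_len(n_cells(m)) else cells
  fi <- if (is.null(features)) seq_len(n_features(m)) else features
  if (is.logical(ci)) ci <- which(ci)
  if (is.logical(fi)) fi <- which(fi)
  AnnotatedMatrix(
    values = m$values[ci, fi, drop = FALSE],
    cell_ids = m$cell_ids[ci], feature_ids = m$feature_ids[fi],
    cell_meta = m$cell_meta[ci, , drop = FALSE],
    feature_meta = m$feature_meta[fi, , drop = FALSE],
    embeddings = lapply(m$embeddings, function(e) e[ci, , drop = FALSE]),
    layers = lapply(m$layers, function(l) l[ci, fi, drop = FALSE]))
}

#' Genomic interval (0-based, half-open)
#'
#' Unit of peak and gene-range arithmetic: chromosome name, 0-based inclusive
#' start, exclusive end, and strand in \{+, -, .\}.
#'
#' @param chrom character chromosome name(s).
#' @param start,end integer-like 0-based half-open bounds, \code{0 <= start < end}.
#' @param strand one of \code{"+"}, \code{"-"}, \code{"."} (recycled).
#' @return a data.frame of class \code{GenomicIntervalSet} with columns
#'   chrom/start/end/strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(start >= end)) stop("interval requires start < end", call. = FALSE)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .", call. = FALSE)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("GenomicIntervalSet", "data.frame")
  out
}

#' Cluster partition with optional frozen mask
#'
#' Per-cell integer cluster labels (0-based) plus a logical frozen mask
#' marking cells whose assignment is constrained during semi-supervised
#' clustering.
#'
#' @param labels integer vector of non-negative cluster labels, one per cell.
#' @param frozen logical vector, same length (default all \code{FALSE}).
#' @return an object of class \code{Partition}.
#' @export
partition <- function(labels, frozen = rep(FALSE, length(labels))) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0))
    stop("labels must be non-negative integers", call. = FALSE)
  frozen <- as.logical(frozen)
  if (length(frozen) != length(labels))
    stop("frozen mask length ", length(frozen), " != labels length ",
         length(labels), call. = FALSE)
  structure(list(labels = labels, frozen = frozen), class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat("Partition of", length(x$labels), "cells into",
      length(unique(x$labels)), "clusters;", sum(x$frozen), "frozen\n")
  invisible(x)
}

#' Canonicalize a partition
#'
#' Relabels clusters to the contiguous range 0..K-1 in order of first
#' appearance. The frozen mask is untouched. Idempotent, and equivalent to
#' the input up to a bijective relabelling (ARI 1).
#'
#' @param p a \code{Partition}.
#' @return the canonicalized \code{Partition}, with the old-to-new label map
#'   attached as attribute \code{"mapping"} (named integer vector).
#' @export
canonicalize <- function(p) {
  stopifnot(inherits(p, "Partition"))
  firsts <- unique(p$labels)
  map <- stats::setNames(seq_along(firsts) - 1L, firsts)
  out <- partition(map[as.character(p$labels)], p$frozen)
  attr(out, "mapping") <- map
  out
}

#' k-nearest-neighbour graph over cells
#'
#' Undirected, unweighted adjacency produced by symmetrizing (union) the
#' directed k-nearest-neighbour lists. Used by Leiden clustering and by
#' label-transfer refinement.
#'
#' @param n_cells number of nodes.
#' @param edges two-column integer matrix of 1-based node index pairs
#'   (unordered, no self-loops, stored with smaller index first).
#' @param k the neighbours-per-node parameter the graph was built with.
#' @return an object of class \code{NeighborGraph}.
#' @export
neighbor_graph <- function(n_cells, edges, k = NA_integer_) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_cells))
      stop("edge endpoints must be in 1..n_cells", call. = FALSE)
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed", call. = FALSE)
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n_cells = as.integer(n_cells), edges = edges,
                 k = as.integer(k)),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat("NeighborGraph:", x$n_cells, "cells,", nrow(x$edges), "edges (k =",
      x$k, ")\n")
  invisible(x)
}
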