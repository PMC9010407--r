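#' Quality-control parameters
#'
#' Defaults follow the standard scRNA-seq workflow: cells are kept when
#' their number of expressed (strictly positive) genes lies in
#' [\code{min_genes_per_cell}, \code{max_genes_per_cell}] inclusive, genes
#' when their number of expressing cells lies in
#' [\code{min_cells_per_gene}, \code{max_cells_per_gene}] inclusive, and
#' each cell is rescaled to a fixed total of \code{target_sum} counts
#' before the log1p transform.
#'
#' @param min_genes_per_cell,max_genes_per_cell expressed-gene bounds per cell.
#' @param min_cells_per_gene,max_cells_per_gene expressing-cell bounds per gene.
#' @param target_sum per-cell total after count normalization (default 1e5).
#' @return a list of class \code{QCParams}.
#' @export
qc_params <- function(min_genes_per_cell = 50, max_genes_per_cell = 3000,
                      min_cells_per_gene = 50, max_cells_per_gene = 3000,
                      target_sum = 1e5) {
  if (min_genes_per_cell < 0 || min_genes_per_cell > max_genes_per_cell)
    stop("need 0 <= min_genes_per_cell <= max_genes_per_cell", call. = FALSE)
  if (min_cells_per_gene < 0 || min_cells_per_gene > max_cells_per_gene)
    stop("need 0 <= min_cells_per_gene <= max_cells_per_gene", call. = FALSE)
  if (target_sum <= 0) stop("target_sum must be > 0", call. = FALSE)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_genes_per_cell = max_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_cells_per_gene = max_cells_per_gene,
                 target_sum = target_sum),
            class = c("QCParams", "list"))
}

.counts_layer <- function(m) {
  cts <- m$layers[["counts"]]
  if (is.null(cts)) stop("layer 'counts' is required", call. = FALSE)
  cts
}

# "expressed" means strictly > 0
.n_expressed_per_cell <- function(cts) {
  if (methods::is(cts, "sparseMatrix")) Matrix::rowSums(cts > 0)
  else rowSums(cts > 0)
}
.n_expressing_cells_per_gene <- function(cts) {
  if (methods::is(cts, "sparseMatrix")) Matrix::colSums(cts > 0)
  else colSums(cts > 0)
}

#' Filter cells by number of expressed genes
#'
#' Keeps cells whose number of features with value > 0 lies within the
#' inclusive bounds of \code{p}; cell order is preserved.
#'
#' @param m an \code{AnnotatedMatrix} with layer \code{"counts"}.
#' @param p a \code{QCParams}.
#' @return the filtered \code{AnnotatedMatrix}.
#' @export
filter_cells <- function(m, p = qc_params()) {
  cts <- .counts_layer(m)
  ng <- .n_expressed_per_cell(cts)
  keep <- ng >= p$min_genes_per_cell & ng <= p$max_genes_per_cell
  if (!any(keep))
    stop("cell filtering removed all ", n_cells(m), " cells", call. = FALSE)
  if (any(!keep))
    message("filter_cells: removed ", sum(!keep), " of ", n_cells(m), " cells")
  am_subset(m, cells = keep)
}

#' Filter genes by number of expressing cells
#'
#' Keeps features whose number of cells with value > 0 lies within the
#' inclusive bounds of \code{p}.
#'
#' @inheritParams filter_cells
#' @return the filtered \code{AnnotatedMatrix}.
#' @export
filter_genes <- function(m, p = qc_params()) {
  cts <- .counts_layer(m)
  nc <- .n_expressing_cells_per_gene(cts)
  keep <- nc >= p$min_cells_per_gene & nc <= p$max_cells_per_gene
  if (!any(keep))
    stop("gene filtering removed all ", n_features(m), " genes", call. = FALSE)
  if (any(!keep))
    message("filter_genes: removed ", sum(!keep), " of ", n_features(m),
            " genes")
  am_subset(m, features = keep)
}

#' Count normalization and log1p transform
#'
#' Scales every cell so its total equals \code{target_sum} (CPM-style total
#' count normalization) and applies log(1 + x). Raw counts are retained in
#' layer \code{"counts"}.
#'
#' @param m an \code{AnnotatedMatrix} with layer \code{"counts"}.
#' @param target_sum per-cell total before the log transform.
#' @return the \code{AnnotatedMatrix} with transformed values.
#' @export
normalize_cpm_log1p <- function(m, target_sum = 1e5) {
  cts <- .counts_layer(m)
  totals <- if (methods::is(cts, "sparseMatrix")) Matrix::rowSums(cts)
            else rowSums(cts)
  if (any(totals <= 0))
    stop("zero-total cell(s): ",
         paste(utils::head(m$cell_ids[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  if (methods::is(cts, "sparseMatrix")) {
    scaled <- methods::as(Matrix::Matrix(cts, sparse = TRUE), "generalMatrix")
    scaled@x <- scaled@x * (target_sum / totals)[scaled@i + 1L]
    scaled@x <- log1p(scaled@x)
  } else {
    scaled <- as.matrix(cts) * (target_sum / totals)
    scaled <- log1p(scaled)
  }
  out <- m
  out$values <- .as_backing(scaled)
  dimnames(out$values) <- list(out$cell_ids, out$feature_ids)
  out
}

#' Scale features to zero mean and unit variance
#'
#' Per feature: subtract the mean and divide by the population (ddof = 0)
#' standard deviation. Zero-variance features are centred only. No value
#' clipping is applied. The result is dense by construction.
#'
#' @param m an \code{AnnotatedMatrix} with normalized values.
#' @return the \code{AnnotatedMatrix} with scaled dense values.
#' @export
scale_unit_variance <- function(m) {
  x <- as.matrix(m$values)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sd_div <- ifelse(sd_pop > 0, sd_pop, 1)
  x <- sweep(sweep(x, 2, mu), 2, sd_div, "/")
  out <- m
  out$values <- x
  dimnames(out$values) <- list(out$cell_ids, out$feature_ids)
  out
}

#' Full preprocessing pipeline
#'
#' Cell filtering, then gene filtering (each applied once, in that order),
#' then count normalization + log1p, then unit-variance scaling. With
#' \code{skip_normalization = TRUE} (the spatial-proteomics path, where
#' antibody intensities are used as measured) the input passes through
#' unchanged.
#'
#' @param m an \code{AnnotatedMatrix} with layer \code{"counts"}.
#' @param p a \code{QCParams}.
#' @param skip_normalization bypass all filtering and normalization.
#' @return the processed \code{AnnotatedMatrix}.
#' @export
preprocess_pipeline <- function(m, p = qc_params(), skip_normalization = FALSE) {
  if (skip_normalization) return(m)
  m <- filter_cells(m, p)
  m <- filter_genes(m, p)
  m <- normalize_cpm_log1p(m, p$target_sum)
  scale_unit_variance(m)
}
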