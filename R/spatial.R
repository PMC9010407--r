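#' Read per-cell spatial centroids
#'
#' Expects columns \code{cell_id}, \code{x}, \code{y} (pixels, origin
#' top-left with y increasing downward, the microscopy convention); extra
#' columns are ignored, file order is preserved.
#'
#' @param path CSV file path.
#' @return data.frame of class \code{SpatialMap} with columns
#'   \code{cell_id}, \code{x}, \code{y}.
#' @export
read_spatial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  for (col in c("cell_id", "x", "y"))
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", basename(path), call. = FALSE)
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " at row ", which(is.na(v))[1], " of ",
           basename(path), call. = FALSE)
    df[[col]] <- v
  }
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in ", basename(path), ": ",
         df$cell_id[duplicated(df$cell_id)][1], call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in ", basename(path), call. = FALSE)
  out <- df[, c("cell_id", "x", "y")]
  class(out) <- c("SpatialMap", "data.frame")
  out
}

#' Deterministic cluster colour palette
#'
#' Assigns each cluster id a visually distinct colour; the same partition
#' always yields the same palette, so the expression-embedding panel and
#' the spatial panel of \code{\link{render_side_by_side}} stay
#' colour-matched.
#'
#' @param part a canonicalized \code{Partition}.
#' @return named character vector mapping cluster id to hex colour.
#' @export
cluster_palette <- function(part) {
  ids <- sort(unique(part$labels))
  k <- length(ids)
  if (k == 0) stop("empty partition", call. = FALSE)
  cols <- grDevices::hcl(h = seq(15, 375, length.out = k + 1)[seq_len(k)],
                         l = seq(65, 45, length.out = k),
                         c = 100)
  stats::setNames(cols, ids)
}

#' Write a palette as TSV
#'
#' @param palette named colour vector from \code{\link{cluster_palette}}.
#' @param path output TSV with columns cluster, color.
#' @return invisibly, \code{path}.
#' @export
write_palette_tsv <- function(palette, path) {
  utils::write.table(
    data.frame(cluster = names(palette), color = unname(palette)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Side-by-side embedding and spatial cluster view
#'
#' Renders a two-panel PNG: the 2-D expression embedding on the left and
#' the spatial centroid scatter on the right, points coloured by the same
#' deterministic cluster palette in both panels so spatial organization can
#' be read off against expression clusters. The spatial panel uses image
#' coordinates (y axis reversed). Rendering is a pure function of its
#' inputs.
#'
#' @param embedding_2d cells x 2 numeric matrix, rows named by cell id (or
#'   aligned by order with \code{spatial}).
#' @param spatial a \code{SpatialMap} covering the same cells.
#' @param part a \code{Partition} aligned with the embedding rows.
#' @param out_path output PNG path.
#' @param width,height,dpi device geometry.
#' @return invisibly, the palette used.
#' @export
render_side_by_side <- function(embedding_2d, spatial, part, out_path,
                                width = 10, height = 5, dpi = 100) {
  embedding_2d <- as.matrix(embedding_2d)
  if (length(part$labels) == 0) stop("empty partition", call. = FALSE)
  if (nrow(embedding_2d) != length(part$labels))
    stop("embedding rows (", nrow(embedding_2d), ") != partition length (",
         length(part$labels), ")", call. = FALSE)
  ids <- rownames(embedding_2d)
  if (is.null(ids)) ids <- spatial$cell_id
  missing <- setdiff(ids, spatial$cell_id)
  if (length(missing))
    stop("spatial map lacks ", length(missing), " cell id(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  sp <- spatial[match(ids, spatial$cell_id), ]
  pal <- cluster_palette(part)
  cl <- factor(part$labels, levels = names(pal))
  d1 <- data.frame(x = embedding_2d[, 1], y = embedding_2d[, 2], cluster = cl)
  d2 <- data.frame(x = sp$x, y = sp$y, cluster = cl)
  g1 <- ggplot2::ggplot(d1, ggplot2::aes(x = x, y = y, colour = cluster)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::labs(title = "Embedding", x = "dim 1", y = "dim 2",
                  colour = "cluster") +
    ggplot2::theme_bw()
  g2 <- ggplot2::ggplot(d2, ggplot2::aes(x = x, y = y, colour = cluster)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_reverse() +  # image convention: origin top-left, y down
    ggplot2::labs(title = "Spatial", x = "x (px)", y = "y (px)",
                  colour = "cluster") +
    ggplot2::theme_bw()
  fig <- patchwork::wrap_plots(g1, g2, nrow = 1, guides = "collect")
  suppressMessages(ggplot2::ggsave(out_path, fig, width = width,
                                   height = height, dpi = dpi,
                                   device = grDevices::png, units = "in"))
  invisible(pal)
}
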