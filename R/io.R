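#' Read a MatrixMarket matrix with barcode/feature sidecars
#'
#' Reads the 10x-style triplet of files (matrix.mtx, barcodes.tsv,
#' features.tsv) into an \code{AnnotatedMatrix} oriented cells x features.
#' Both on-disk orientations are found in the wild, so orientation is
#' inferred from the sidecar lengths; a square matrix is ambiguous and
#' requires \code{cells_in_rows} to be stated explicitly.
#'
#' @param matrix_path path to the MatrixMarket file.
#' @param barcodes_path path to the one-column cell barcode file.
#' @param features_path path to the feature id file (first column used).
#' @param cells_in_rows \code{NA} to infer orientation from sidecar lengths;
#'   \code{TRUE}/\code{FALSE} to force it (required when the matrix is square
#'   with equally many barcodes and features).
#' @return an \code{AnnotatedMatrix}; the values are also stored in layer
#'   \code{"counts"}.
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path,
                     cells_in_rows = NA) {
  for (f in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  mat <- Matrix::readMM(matrix_path)
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  feat_tab <- utils::read.table(features_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  features <- feat_tab[[1]]
  nb <- length(barcodes); nf <- length(features)
  fits_cells_rows <- nrow(mat) == nb && ncol(mat) == nf
  fits_cells_cols <- nrow(mat) == nf && ncol(mat) == nb
  if (!fits_cells_rows && !fits_cells_cols)
    stop("dimension mismatch: ", basename(matrix_path), " is ", nrow(mat),
         " x ", ncol(mat), " but ", basename(barcodes_path), " has ", nb,
         " barcodes and ", basename(features_path), " has ", nf, " features",
         call. = FALSE)
  if (fits_cells_rows && fits_cells_cols && is.na(cells_in_rows))
    stop("matrix is square with equally many barcodes and features; ",
         "pass cells_in_rows = TRUE or FALSE to disambiguate orientation",
         call. = FALSE)
  orient_rows <- if (!is.na(cells_in_rows)) isTRUE(cells_in_rows) else fits_cells_rows
  if (!orient_rows) mat <- Matrix::t(mat)
  am <- AnnotatedMatrix(mat, cell_ids = barcodes, feature_ids = features)
  am$layers[["counts"]] <- am$values
  if (ncol(feat_tab) >= 2) am$feature_meta$name <- feat_tab[[2]]
  am
}

#' Write an AnnotatedMatrix as MatrixMarket plus sidecars
#'
#' @param m an \code{AnnotatedMatrix}.
#' @param matrix_path,barcodes_path,features_path output paths.
#' @param layer which layer to write (default the main values).
#' @return invisibly, \code{matrix_path}.
#' @export
write_mtx <- function(m, matrix_path, barcodes_path, features_path,
                      layer = NULL) {
  vals <- if (is.null(layer)) m$values else m$layers[[layer]]
  if (is.null(vals)) stop("layer '", layer, "' not present", call. = FALSE)
  sp <- methods::as(Matrix::Matrix(as.matrix(vals), sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, matrix_path)
  writeLines(m$cell_ids, barcodes_path)
  writeLines(m$feature_ids, features_path)
  invisible(matrix_path)
}

#' Read a dense CSV matrix
#'
#' Expects a header row and a leading id column; the body must be numeric
#' and rectangular.
#'
#' @param path CSV file path.
#' @param cells_in_rows \code{TRUE} if rows are cells (default); \code{FALSE}
#'   if the file stores features in rows, in which case it is transposed.
#' @return an \code{AnnotatedMatrix} with layer \code{"counts"} set when all
#'   values are non-negative.
#' @export
read_csv_matrix <- function(path, cells_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(vapply(fields, length, 1L) != width)
  if (length(ragged))
    stop("ragged CSV: line ", ragged[1], " of ", basename(path), " has ",
         length(fields[[ragged[1]]]), " fields, expected ", width,
         call. = FALSE)
  header <- fields[[1]][-1]
  body <- fields[-1]
  ids <- vapply(body, `[[`, "", 1L)
  num <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(width - 1L)))
  num <- matrix(num, ncol = length(body))  # robust to single-column bodies
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value at line ", bad[2] + 1L, ", column ",
         bad[1] + 1L, " of ", basename(path), call. = FALSE)
  }
  mat <- t(num)  # rows of file x data columns
  rownames(mat) <- ids; colnames(mat) <- header
  if (!cells_in_rows) mat <- t(mat)
  am <- AnnotatedMatrix(mat)
  if (min_value(am$values) >= 0) am$layers[["counts"]] <- am$values
  am
}

#' Write per-cell labels as a two-column TSV
#'
#' @param m an \code{AnnotatedMatrix} whose \code{cell_meta} holds the labels.
#' @param label_key column name in \code{cell_meta}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_labels_tsv <- function(m, label_key, path) {
  if (!label_key %in% names(m$cell_meta))
    stop("label key '", label_key, "' not found; available: ",
         if (ncol(m$cell_meta)) paste(names(m$cell_meta), collapse = ", ")
         else "(none)", call. = FALSE)
  df <- data.frame(cell_id = m$cell_ids, label = m$cell_meta[[label_key]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labels written by \code{write_labels_tsv}
#'
#' @param path two-column TSV with header \code{cell_id}, \code{label}.
#' @return data.frame with columns \code{cell_id} and \code{label}.
#' @export
read_labels_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", NA))
}

#' Export an embedding as CSV (cell_id + coordinates)
#'
#' @param m an \code{AnnotatedMatrix}.
#' @param name embedding name.
#' @param path output CSV.
#' @return invisibly, \code{path}.
#' @export
write_embedding_csv <- function(m, name, path) {
  emb <- m$embeddings[[name]]
  if (is.null(emb))
    stop("embedding '", name, "' not found; available: ",
         paste(names(m$embeddings), collapse = ", "), call. = FALSE)
  df <- data.frame(cell_id = m$cell_ids, emb, check.names = FALSE)
  names(df)[-1] <- paste0("dim", seq_len(ncol(emb)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a neighbour graph as an edge-list TSV
#'
#' @param graph a \code{NeighborGraph}.
#' @param path output TSV with columns \code{from}, \code{to} (1-based).
#' @return invisibly, \code{path}.
#' @export
write_edges_tsv <- function(graph, path) {
  df <- data.frame(from = graph$edges[, 1], to = graph$edges[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
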