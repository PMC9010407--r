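#' Gene-range extension parameters
#'
#' A peak is credited to a gene when it overlaps the gene's span extended by
#' \code{downstream_bp} past the 3' end and \code{upstream_bp} before the 5'
#' end (both strand-aware by default).
#'
#' @param downstream_bp base pairs past the 3' end (default 5000).
#' @param upstream_bp base pairs before the 5' end (default 1000).
#' @return a list of class \code{ExtensionParams}.
#' @export
extension_params <- function(downstream_bp = 5000, upstream_bp = 1000) {
  if (downstream_bp < 0 || upstream_bp < 0)
    stop("extensions must be >= 0", call. = FALSE)
  structure(list(downstream_bp = downstream_bp, upstream_bp = upstream_bp),
            class = c("ExtensionParams", "list"))
}

#' Parse gene records from a GTF file
#'
#' Reads GENCODE-dialect GTF gene records into a table of gene-level spans.
#' GTF 1-based inclusive coordinates are converted to 0-based half-open.
#' Records on unplaced contigs are retained as-is; records without a strand
#' are skipped with a warning; duplicate gene ids are an error.
#'
#' @param path GTF file path.
#' @return data.frame with columns \code{gene_id}, \code{gene_name},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand}.
#' @export
parse_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .gtf_prescan(path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("failed to parse GTF ", basename(path), ": ",
                        conditionMessage(e), call. = FALSE))
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (!length(gr)) stop("no gene records in ", basename(path), call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning(sum(strand == "*"), " gene record(s) without strand skipped")
    gr <- gr[strand != "*"]
    strand <- strand[strand != "*"]
  }
  ids <- gr$gene_id
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else ids
  data.frame(gene_id = ids,
             gene_name = ifelse(is.na(gene_name), ids, gene_name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
             end = GenomicRanges::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

# cheap field-count check so format problems get a line number
.gtf_prescan <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nf < 9]
  if (length(bad))
    stop("malformed GTF line ", bad[1], " in ", basename(path), ": expected ",
         "9 tab-separated fields, found ", nf[match(bad[1], body)],
         call. = FALSE)
  invisible(TRUE)
}

#' Extend a gene range, strand-aware
#'
#' For + strand genes the window is [start - upstream, end + downstream);
#' for - strand genes the roles of the two extensions are mirrored:
#' [start - downstream, end + upstream). The lower bound is clipped at 0.
#'
#' @param genes data.frame as from \code{\link{parse_gtf_genes}} (one or
#'   more rows).
#' @param p an \code{ExtensionParams}.
#' @param strand_aware set \code{FALSE} to apply upstream/downstream in
#'   genomic coordinate order regardless of strand.
#' @return a \code{GenomicIntervalSet} of extended windows, one per gene.
#' @export
extend_range <- function(genes, p = extension_params(), strand_aware = TRUE) {
  minus <- strand_aware & genes$strand == "-"
  lo_ext <- ifelse(minus, p$downstream_bp, p$upstream_bp)
  hi_ext <- ifelse(minus, p$upstream_bp, p$downstream_bp)
  genomic_interval(genes$chrom,
                   pmax(0, genes$start - lo_ext),
                   genes$end + hi_ext,
                   genes$strand)
}

#' Parse coordinate-encoded peak identifiers
#'
#' Accepts the common dialects \code{"chr1:100-200"}, \code{"chr1_100_200"}
#' and \code{"chr1-100-200"}; coordinates are taken as 0-based half-open.
#'
#' @param feature_ids character vector of peak ids.
#' @return a \code{GenomicIntervalSet} with strand \code{"."}.
#' @export
parse_peak_ids <- function(feature_ids) {
  rx <- "^(.*?)[:_-](\\d+)[-_](\\d+)$"
  ok <- grepl(rx, feature_ids, perl = TRUE)
  if (!all(ok))
    stop("unparseable peak id(s): ",
         paste(utils::head(feature_ids[!ok], 5), collapse = ", "),
         call. = FALSE)
  chrom <- sub(rx, "\\1", feature_ids, perl = TRUE)
  start <- as.numeric(sub(rx, "\\2", feature_ids, perl = TRUE))
  end <- as.numeric(sub(rx, "\\3", feature_ids, perl = TRUE))
  genomic_interval(chrom, start, end, ".")
}

# 0-based half-open -> GRanges (1-based closed)
.to_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

#' Gene-activity matrix from a peak-by-cell accessibility matrix
#'
#' Entry (cell, gene) is the sum of that cell's counts over every peak whose
#' interval overlaps the extended gene window by at least 1 bp. A peak
#' overlapping several extended genes contributes its full count to each;
#' genes with no overlapping peak are retained as all-zero columns.
#'
#' @param peaks_by_cells an \code{AnnotatedMatrix} of cells x peaks with
#'   coordinate-encoded feature ids.
#' @param genes data.frame as from \code{\link{parse_gtf_genes}}.
#' @param p an \code{ExtensionParams}.
#' @param harmonize_chr when \code{TRUE}, "chr"-prefix differences between
#'   peak and gene chromosome names are reconciled (never done silently).
#' @param strand_aware passed to \code{\link{extend_range}}.
#' @return an \code{AnnotatedMatrix} of cells x genes with the activity
#'   scores in layer \code{"counts"}.
#' @export
gene_activity_matrix <- function(peaks_by_cells, genes,
                                 p = extension_params(),
                                 harmonize_chr = FALSE, strand_aware = TRUE) {
  if (!nrow(genes)) stop("need at least one gene", call. = FALSE)
  peaks <- parse_peak_ids(peaks_by_cells$feature_ids)
  ext <- extend_range(genes, p, strand_aware = strand_aware)
  if (harmonize_chr) {
    strip <- function(x) sub("^chr", "", x)
    peaks$chrom <- strip(peaks$chrom)
    ext$chrom <- strip(ext$chrom)
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.to_granges(peaks), .to_granges(ext),
                                minoverlap = 1L))
  if (!length(hits) &&
      !any(peaks$chrom %in% ext$chrom))
    stop("no peak-gene overlaps and no shared chromosome names (peaks: ",
         paste(utils::head(unique(peaks$chrom), 3), collapse = ", "),
         "; genes: ", paste(utils::head(unique(ext$chrom), 3), collapse = ", "),
         "); consider harmonize_chr = TRUE to reconcile 'chr' prefixes",
         call. = FALSE)
  # sparse peak x gene assignment matrix; activity = counts %*% assignment
  assign_mat <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits), x = 1,
    dims = c(nrow(peaks), nrow(genes)))
  cts <- peaks_by_cells$layers[["counts"]]
  if (is.null(cts)) cts <- peaks_by_cells$values
  activity <- as.matrix(Matrix::Matrix(as.matrix(cts), sparse = TRUE) %*% assign_mat)
  dimnames(activity) <- list(peaks_by_cells$cell_ids, genes$gene_id)
  am <- AnnotatedMatrix(activity, cell_ids = peaks_by_cells$cell_ids,
                        feature_ids = genes$gene_id,
                        cell_meta = peaks_by_cells$cell_meta,
                        feature_meta = data.frame(
                          name = genes$gene_name, row.names = genes$gene_id))
  am$layers[["counts"]] <- am$values
  am
}

#' scATAC pipeline: gene activity, normalization, scaling
#'
#' Builds the cell-by-gene activity matrix from a peak matrix and a GTF,
#' then count-normalizes, log1p-transforms and scales it, leaving it ready
#' for \code{\link{reduce_pca}} and \code{\link{leiden}}.
#'
#' @param peaks_by_cells cells x peaks \code{AnnotatedMatrix}.
#' @param gtf_path GTF with gene records.
#' @param p an \code{ExtensionParams}.
#' @param target_sum per-cell total for normalization.
#' @param ... passed to \code{\link{gene_activity_matrix}}.
#' @return the processed \code{AnnotatedMatrix}.
#' @export
atac_pipeline <- function(peaks_by_cells, gtf_path, p = extension_params(),
                          target_sum = 1e5, ...) {
  genes <- parse_gtf_genes(gtf_path)
  act <- gene_activity_matrix(peaks_by_cells, genes, p, ...)
  act <- normalize_cpm_log1p(act, target_sum)
  scale_unit_variance(act)
}
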