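#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic
#' \deqn{t = \frac{\bar{x} - \bar{y}}{\sqrt{s_x^2/n_x + s_y^2/n_y}}}
#' with sample (ddof = 1) variances, Welch-Satterthwaite degrees of
#' freedom, and a two-sided p-value from Student's t distribution.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return list with \code{t}, \code{df}, \code{p} (all \code{NaN} when the
#'   pooled variance term is zero or a sample is too small).
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(list(t = NaN, df = NaN, p = NaN))
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = NaN, df = NaN, p = NaN))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# vectorised Welch across the columns of a matrix, rows split by group
.welch_t_matrix <- function(x_in, x_out) {
  nx <- nrow(x_in); ny <- nrow(x_out)
  mx <- colMeans(x_in); my <- colMeans(x_out)
  vx <- colSums(sweep(x_in, 2, mx)^2) / (nx - 1)
  vy <- colSums(sweep(x_out, 2, my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  t[zero & mx == my] <- 0
  p[zero & mx == my] <- 1
  df[zero & mx == my] <- nx + ny - 2
  t[zero & mx != my] <- NaN
  p[zero & mx != my] <- NaN
  list(t = t, df = df, p = p)
}

#' Cluster-versus-rest differential expression
#'
#' Per-gene Welch's t-test comparing the cells of one cluster against all
#' other cells, on normalized log values (pre-scaling; a zero-mean scaled
#' matrix is degenerate for fold-change computation). P-values are
#' Benjamini-Hochberg adjusted across genes; the log2 fold change is
#' computed on de-logged means with a pseudocount of 1:
#' \code{log2((mean(expm1(in)) + 1) / (mean(expm1(rest)) + 1))}.
#'
#' @param m an \code{AnnotatedMatrix} with normalized log values.
#' @param part a \code{Partition} over its cells.
#' @param cluster_id the cluster to contrast against the rest.
#' @return data.frame of class \code{DEResult} with columns \code{gene_id},
#'   \code{t_stat}, \code{p_value}, \code{q_value}, \code{log2_fc}, in the
#'   matrix's gene order. Genes with undefined statistics carry \code{NaN}
#'   p-values and are excluded from BH adjustment and from ranking.
#' @export
de_cluster_vs_rest <- function(m, part, cluster_id) {
  if (length(part$labels) != n_cells(m))
    stop("partition covers ", length(part$labels), " cells but the matrix ",
         "has ", n_cells(m), call. = FALSE)
  in_c <- part$labels == cluster_id
  if (sum(in_c) < 2 || sum(!in_c) < 2)
    stop("cluster ", cluster_id, " needs >= 2 cells on each side (has ",
         sum(in_c), " vs ", sum(!in_c), ")", call. = FALSE)
  x <- as.matrix(m$values)
  res <- .welch_t_matrix(x[in_c, , drop = FALSE], x[!in_c, , drop = FALSE])
  q <- rep(NaN, length(res$p))
  ok <- !is.nan(res$p)
  q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  mean_in <- colMeans(expm1(x[in_c, , drop = FALSE]))
  mean_out <- colMeans(expm1(x[!in_c, , drop = FALSE]))
  out <- data.frame(gene_id = m$feature_ids, t_stat = res$t,
                    p_value = res$p, q_value = q,
                    log2_fc = log2((mean_in + 1) / (mean_out + 1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Select top marker genes by fold change
#'
#' Ranks genes by log2 fold change descending (up-regulated markers), ties
#' broken by smaller p-value then by gene id, and returns the top \code{n}.
#' When fewer genes exist than requested — the spatial-proteomics case with
#' a handful of protein channels — all are returned. Genes with undefined
#' p-values are excluded.
#'
#' @param results a \code{DEResult} data.frame.
#' @param n number of markers (default 500).
#' @param absolute rank by absolute fold change instead of signed.
#' @return character vector of gene ids.
#' @export
top_markers <- function(results, n = 500, absolute = FALSE) {
  if (!nrow(results)) stop("empty DE results", call. = FALSE)
  r <- results[!is.nan(results$p_value), , drop = FALSE]
  fc <- if (absolute) abs(r$log2_fc) else r$log2_fc
  ord <- order(-fc, r$p_value, r$gene_id)
  utils::head(r$gene_id[ord], n)
}

#' Read a GMT gene-set collection
#'
#' Each line is term name, description, then member genes, tab-separated.
#' Duplicate genes within a term are deduplicated; terms left empty are
#' dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list mapping term name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", basename(path))
    return(stats::setNames(list(), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short))
    stop("GMT line ", short[1], " of ", basename(path),
         " has fewer than 3 fields", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty term(s) dropped: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  sets
}

#' Gene-set overrepresentation test
#'
#' For each term, a one-sided hypergeometric test of seeing at least the
#' observed overlap between the query gene list and the term, given the
#' query size, term size and background universe size. Q-values are BH
#' adjusted across terms; rows are sorted by ascending p.
#'
#' @param query_genes character vector of query genes (e.g. top markers).
#' @param gene_sets named list as from \code{\link{read_gmt}}.
#' @param background_size size of the gene universe; must be at least
#'   \code{|query union term|} for every term.
#' @return data.frame of class \code{EnrichmentResult} with columns
#'   \code{term_name}, \code{overlap_count}, \code{term_size},
#'   \code{p_value}, \code{q_value}, \code{overlapping_genes}
#'   (comma-joined).
#' @export
enrich <- function(query_genes, gene_sets, background_size) {
  query_genes <- unique(query_genes)
  nq <- length(query_genes)
  rows <- lapply(names(gene_sets), function(term) {
    genes <- gene_sets[[term]]
    if (background_size < length(unique(c(query_genes, genes))))
      stop("background_size = ", background_size, " is smaller than ",
           "|query union term| for term '", term, "'", call. = FALSE)
    ov <- intersect(query_genes, genes)
    k <- length(ov); ts <- length(genes)
    p <- stats::phyper(k - 1, ts, background_size - ts, nq,
                       lower.tail = FALSE)
    data.frame(term_name = term, overlap_count = k, term_size = ts,
               p_value = p,
               overlapping_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_name = character(0), overlap_count = integer(0),
                      term_size = integer(0), p_value = numeric(0),
                      overlapping_genes = character(0))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_name),
             c("term_name", "overlap_count", "term_size", "p_value",
               "q_value", "overlapping_genes")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Write a DE or enrichment table as TSV
#'
#' @param tab a \code{DEResult} or \code{EnrichmentResult} data.frame.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
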