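#' Synthetic-fixture specification
#'
#' Parameters of the synthetic-data generators that give every pipeline
#' stage a download-free test surface: clustered negative-binomial counts
#' with planted marker genes, optional dropout, spatially coherent cluster
#' blobs, and a reference/query pair with corrupted reference labels for
#' the label-transfer experiment.
#'
#' Defaults are chosen to emulate a small but non-trivial scRNA-seq
#' experiment: 300 cells, 2000 genes, 5 cell types, 10% of genes
#' up-regulated 4-fold (log2 fc 2) per type, negative-binomial dispersion
#' 0.5 and 30% dropout, with sparse low base expression (lognormal means
#' around 0.5 counts) as in real droplet data — enough noise that recovery
#' of the planted structure is informative rather than automatic.
#'
#' @param n_cells,n_genes,n_clusters matrix geometry and planted types.
#' @param de_fraction fraction of genes up-regulated per cluster.
#' @param de_log2fc planted effect size (log2 fold change).
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param dropout_rate probability of zeroing an observed count.
#' @param seed integer seed; all generators are pure functions of the spec.
#' @param spatial_layout \code{"blobs"} or \code{"none"}.
#' @param transfer_noise fraction of reference labels corrupted in
#'   \code{\link{make_transfer_pair}}.
#' @return a list of class \code{FixtureSpec}.
#' @export
fixture_spec <- function(n_cells = 300, n_genes = 2000, n_clusters = 5,
                         de_fraction = 0.1, de_log2fc = 2,
                         nb_dispersion = 0.5, dropout_rate = 0.3,
                         seed = 0L, spatial_layout = "none",
                         transfer_noise = 0) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_clusters >= 1,
            de_fraction >= 0, de_fraction <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            transfer_noise >= 0, transfer_noise <= 1,
            nb_dispersion > 0)
  if (n_clusters > n_cells)
    stop("n_clusters (", n_clusters, ") exceeds n_cells (", n_cells, ")",
         call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                 seed = as.integer(seed),
                 spatial_layout = match.arg(spatial_layout,
                                            c("none", "blobs")),
                 transfer_noise = transfer_noise),
            class = c("FixtureSpec", "list"))
}

# per-gene base means and per-cluster marker blocks shared by the count
# generators; deterministic in the spec's seed alone
.fixture_model <- function(spec) {
  withr::with_seed(spec$seed, {
    base_mu <- exp(stats::rnorm(spec$n_genes, mean = log(0.5), sd = 0.5))
    n_mark <- max(1L, round(spec$de_fraction * spec$n_genes))
    markers <- lapply(seq_len(spec$n_clusters) - 1L, function(j)
      (seq(j * n_mark, length.out = n_mark) %% spec$n_genes) + 1L)
    truth <- sort(rep_len(seq_len(spec$n_clusters) - 1L, spec$n_cells))
    truth <- sample(truth)
    list(base_mu = base_mu, markers = markers, truth = truth)
  })
}

.draw_counts <- function(spec, model, truth, gene_shift = NULL, rng_tag = 0L) {
  fold <- 2^spec$de_log2fc
  mu_by_cluster <- lapply(seq_len(spec$n_clusters), function(jj) {
    mu <- model$base_mu
    mu[model$markers[[jj]]] <- mu[model$markers[[jj]]] * fold
    if (!is.null(gene_shift)) mu <- mu * gene_shift
    mu
  })
  n <- length(truth)
  withr::with_seed(spec$seed + 7L * rng_tag + 1L, {
    counts <- matrix(0, n, spec$n_genes)
    for (i in seq_len(n)) {
      mu <- mu_by_cluster[[truth[i] + 1L]]
      counts[i, ] <- stats::rnbinom(spec$n_genes, mu = mu,
                                    size = 1 / spec$nb_dispersion)
    }
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(counts)) < spec$dropout_rate,
                     nrow = n)
      counts[drop] <- 0
    }
    counts
  })
}

#' Clustered negative-binomial count fixture
#'
#' Generates counts for \code{n_cells} cells in \code{n_clusters} planted
#' types: each type up-regulates its own block of
#' \code{de_fraction * n_genes} marker genes by \code{2^de_log2fc}, on top
#' of shared lognormal base means, with negative-binomial sampling and
#' optional dropout. The truth partition is returned alongside.
#'
#' @param spec a \code{FixtureSpec}.
#' @return list with \code{matrix} (an \code{AnnotatedMatrix} with layer
#'   \code{"counts"} and the truth in \code{cell_meta$truth}),
#'   \code{truth} (a \code{Partition}), and \code{markers} (list of marker
#'   gene indices per cluster).
#' @export
make_counts <- function(spec = fixture_spec()) {
  model <- .fixture_model(spec)
  counts <- .draw_counts(spec, model, model$truth)
  rownames(counts) <- sprintf("cell%04d", seq_len(spec$n_cells))
  colnames(counts) <- sprintf("gene%04d", seq_len(spec$n_genes))
  am <- AnnotatedMatrix(counts,
                        cell_meta = data.frame(truth = model$truth))
  am$layers[["counts"]] <- am$values
  list(matrix = am, truth = partition(model$truth), markers = model$markers)
}

#' QC parameters scaled to a fixture's geometry
#'
#' The default QC bounds target experiment-scale data; fixtures are far
#' smaller, so tests use bounds proportionate to the fixture: at least 10
#' expressed genes per cell and 5 expressing cells per gene, with the
#' upper bounds left open at the fixture's own dimensions.
#'
#' @param spec a \code{FixtureSpec}.
#' @return a \code{QCParams}.
#' @export
fixture_qc_params <- function(spec) {
  qc_params(min_genes_per_cell = 10, max_genes_per_cell = spec$n_genes,
            min_cells_per_gene = 5, max_cells_per_gene = spec$n_cells)
}

#' scATAC fixture with an exact brute-force oracle
#'
#' Builds a small peak-by-cell matrix with coordinate-encoded peak ids over
#' a few toy chromosomes, a matching toy GTF with genes on both strands,
#' and the brute-force cell-by-gene expectation computed by a double loop
#' over all (peak, gene) overlap tests. Some peaks are placed to straddle
#' or exactly abut extended gene boundaries so clipping and half-open
#' conventions get exercised.
#'
#' @param spec a \code{FixtureSpec} (\code{n_cells} and \code{seed} used;
#'   peak/gene counts are fixed at ~50/~20).
#' @param p the \code{ExtensionParams} the oracle assumes.
#' @param gtf_path where to write the toy GTF (default: tempfile).
#' @return list with \code{peaks} (cells x peaks \code{AnnotatedMatrix}),
#'   \code{gtf_path}, \code{genes} (parsed gene table), and \code{oracle}
#'   (the expected cells x genes activity matrix).
#' @export
make_atac_fixture <- function(spec = fixture_spec(n_cells = 30),
                              p = extension_params(),
                              gtf_path = tempfile(fileext = ".gtf")) {
  n_genes <- 20L; n_peaks <- 50L
  chroms <- c("chr1", "chr2", "chr3")
  withr::with_seed(spec$seed + 101L, {
    g_chrom <- sample(chroms, n_genes, replace = TRUE)
    g_start <- sample(0:80000, n_genes)  # 0-based
    g_len <- sample(1000:3000, n_genes, replace = TRUE)
    g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                        gene_name = sprintf("Gene%03d", seq_len(n_genes)),
                        chrom = g_chrom, start = g_start,
                        end = g_start + g_len, strand = g_strand,
                        stringsAsFactors = FALSE)
    ext <- extend_range(genes, p)
    p_chrom <- sample(chroms, n_peaks, replace = TRUE)
    p_start <- sample(0:99000, n_peaks)
    p_len <- sample(200:500, n_peaks, replace = TRUE)
    # boundary placements against the first few extended genes:
    # peak starting exactly at the extended end (no overlap, half-open),
    # peak ending exactly at the extended start (no overlap),
    # peak overlapping the extended start by exactly 1 bp
    p_chrom[1] <- ext$chrom[1]; p_start[1] <- ext$end[1]
    p_chrom[2] <- ext$chrom[2]; p_start[2] <- max(0, ext$start[2] - p_len[2])
    p_chrom[3] <- ext$chrom[3]; p_start[3] <- max(0, ext$start[3] - p_len[3] + 1)
    p_end <- p_start + p_len
    counts <- matrix(stats::rnbinom(spec$n_cells * n_peaks, mu = 2,
                                    size = 2), nrow = spec$n_cells)
  })
  # GTF: 1-based inclusive
  gtf <- sprintf(
    '%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_name)
  writeLines(c("##toy annotation", gtf), gtf_path)
  peak_ids <- sprintf("%s:%d-%d", p_chrom, p_start, p_end)
  rownames(counts) <- sprintf("cell%04d", seq_len(spec$n_cells))
  colnames(counts) <- peak_ids
  peaks <- AnnotatedMatrix(counts)
  peaks$layers[["counts"]] <- peaks$values
  ext <- extend_range(genes, p)
  oracle <- matrix(0, spec$n_cells, n_genes,
                   dimnames = list(rownames(counts), genes$gene_id))
  for (pk in seq_len(n_peaks)) {
    for (gn in seq_len(n_genes)) {
      if (p_chrom[pk] == ext$chrom[gn] &&
          max(p_start[pk], ext$start[gn]) < min(p_end[pk], ext$end[gn])) {
        oracle[, gn] <- oracle[, gn] + counts[, pk]
      }
    }
  }
  list(peaks = peaks, gtf_path = gtf_path, genes = genes, oracle = oracle)
}

#' Reference/query pair for the label-transfer experiment
#'
#' Two draws from the same clustered count model over partially (80%)
#' overlapping gene sets, built to emulate the three difficulties of real
#' reference-based annotation at once:
#'
#' \itemize{
#' \item \strong{Sibling types.} The first three types form a family
#'   sharing a common marker program, distinguished only by small private
#'   marker blocks. In the query batch the private blocks are attenuated
#'   (a batch effect compressing the distinction), so unsupervised
#'   clustering of the query tends to merge the siblings, while the
#'   reference-fit projection — where the distinction is intact — still
#'   separates them for neighbour voting.
#' \item \strong{Concentrated annotation noise.} The corrupted fraction
#'   (\code{transfer_noise}) of reference labels is not spread uniformly:
#'   it fills up from the most abundant, highest-index type downwards,
#'   mostly mislabelled as the adjacent type, as a systematic expert
#'   error would be. Voting therefore merges the noisy types at low
#'   confidence, leaving the clean types at high confidence — exactly the
#'   contrast the least-noisy-cluster freezing rule keys on.
#' \item \strong{Mild query shift.} A small per-gene multiplicative
#'   shift distinguishes the batches.
#' }
#'
#' Cluster sizes are uneven (proportions 0.2/0.2/0.2/0.1/0.3 of
#' \code{n_cells} for 5 types), as in real tissue.
#'
#' @param spec a \code{FixtureSpec}.
#' @return list with \code{reference} (counts \code{AnnotatedMatrix};
#'   noisy labels in \code{cell_meta$label}, clean truth in
#'   \code{cell_meta$truth}), \code{query} (counts; truth in
#'   \code{cell_meta$truth}) and \code{truth} (the query's truth
#'   \code{Partition}).
#' @export
make_transfer_pair <- function(spec = fixture_spec(transfer_noise = 0.3)) {
  n <- spec$n_cells; K <- spec$n_clusters; ng <- spec$n_genes
  if (K < 4) stop("the transfer fixture needs at least 4 cell types",
                  call. = FALSE)
  fold <- 2^spec$de_log2fc
  # uneven type abundances: the last type is the most abundant (and the
  # one annotation noise concentrates in), the second-last is rare
  props <- c(rep(0.6 / (K - 2), K - 2), 0.1, 0.3)
  sizes <- round(props * n)
  sizes[K] <- n - sum(sizes[-K])
  type_seq <- rep(seq_len(K) - 1L, times = sizes)
  # marker layout: a sibling family (types 0..K-3) shares a common block
  # and carries small private blocks; the last two types have full blocks
  n_mark <- max(2L, round(spec$de_fraction * ng))
  n_common <- max(1L, round(0.2 * n_mark))
  n_priv <- n_mark - n_common
  nxt <- 0L
  take <- function(len) {
    blk <- seq(nxt + 1L, length.out = len)
    nxt <<- nxt + len
    blk
  }
  common_blk <- take(n_common)
  priv_blk <- lapply(seq_len(K - 2), function(j) take(n_priv))
  full_blk <- lapply(1:2, function(j) take(n_mark))
  mu_for <- function(type, attenuate) {
    boost <- rep(1, ng)
    if (type <= K - 3) {
      boost[common_blk] <- fold
      # the query batch attenuates the sibling-distinguishing program
      boost[priv_blk[[type + 1L]]] <- if (attenuate) fold^0.5 else fold
    } else {
      boost[full_blk[[type - (K - 3L)]]] <- fold
    }
    boost
  }
  withr::with_seed(spec$seed + 13L, {
    base_mu <- exp(stats::rnorm(ng, mean = log(0.5), sd = 0.5))
    truth_ref <- sample(type_seq)
    truth_qry <- sample(type_seq)
    gene_shift <- exp(stats::rnorm(ng, 0, 0.05))
    # systematic annotation noise: the corrupted fraction fills up from
    # the most abundant (highest-index) type downwards; a corrupted cell
    # is usually mislabelled as the adjacent type, occasionally as type 0
    noisy <- truth_ref
    n_flip <- round(spec$transfer_noise * n)
    if (n_flip > 0) {
      cand <- order(-truth_ref, stats::runif(n))
      flip <- cand[seq_len(n_flip)]
      to_adjacent <- stats::runif(n_flip) < 0.8
      noisy[flip] <- ifelse(to_adjacent,
                            ifelse(truth_ref[flip] == K - 2L, K - 3L, K - 2L),
                            ifelse(truth_ref[flip] == 0L, 1L, 0L))
    }
  })
  draw <- function(truth, shift, attenuate, tag) {
    withr::with_seed(spec$seed + 7L * tag + 1L, {
      counts <- matrix(0, length(truth), ng)
      boosts <- lapply(seq_len(K) - 1L, mu_for, attenuate = attenuate)
      for (i in seq_along(truth)) {
        mu <- base_mu * boosts[[truth[i] + 1L]]
        if (!is.null(shift)) mu <- mu * shift
        counts[i, ] <- stats::rnbinom(ng, mu = mu,
                                      size = 1 / spec$nb_dispersion)
      }
      if (spec$dropout_rate > 0)
        counts[matrix(stats::runif(length(counts)) < spec$dropout_rate,
                      nrow(counts))] <- 0
      counts
    })
  }
  ref_counts <- draw(truth_ref, NULL, attenuate = FALSE, tag = 1L)
  qry_counts <- draw(truth_qry, gene_shift, attenuate = TRUE, tag = 2L)
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  # each side keeps 90% so the intersection is 80%; the private blocks are
  # taken from the high-index (non-marker) end so no type loses its
  # planted markers in the shared space
  n_drop <- round(0.1 * ng)
  idx <- seq_len(ng)
  ref_keep <- idx <= ng - n_drop
  qry_keep <- idx <= ng - 2 * n_drop | idx > ng - n_drop
  mk <- function(counts, keep, prefix, meta) {
    counts <- counts[, keep, drop = FALSE]
    rownames(counts) <- sprintf("%s%04d", prefix, seq_len(nrow(counts)))
    colnames(counts) <- gene_ids[keep]
    am <- AnnotatedMatrix(counts, cell_meta = meta)
    am$layers[["counts"]] <- am$values
    am
  }
  reference <- mk(ref_counts, ref_keep, "ref",
                  data.frame(label = noisy, truth = truth_ref))
  query <- mk(qry_counts, qry_keep, "qry", data.frame(truth = truth_qry))
  list(reference = reference, query = query, truth = partition(truth_qry))
}

#' Spatial blob coordinates aligned to a count fixture
#'
#' Places each planted cluster of \code{\link{make_counts}} at a Gaussian
#' blob (sd 40 px) around centres spaced on a circle of radius 350 px in a
#' 1000 x 1000 px tile, so centres are pairwise >= 300 px apart for up to
#' 7 clusters. Coordinates align with the fixture's cell ids.
#'
#' @param spec a \code{FixtureSpec} with \code{spatial_layout = "blobs"}.
#' @return a \code{SpatialMap}.
#' @export
make_spatial_fixture <- function(spec) {
  if (spec$spatial_layout != "blobs")
    stop("spatial fixture requires spatial_layout = 'blobs'", call. = FALSE)
  fx <- make_counts(spec)
  K <- spec$n_clusters
  ang <- 2 * pi * (seq_len(K) - 1) / K
  cx <- 500 + 350 * cos(ang)
  cy <- 500 + 350 * sin(ang)
  withr::with_seed(spec$seed + 29L, {
    x <- cx[fx$truth$labels + 1L] + stats::rnorm(spec$n_cells, 0, 40)
    y <- cy[fx$truth$labels + 1L] + stats::rnorm(spec$n_cells, 0, 40)
  })
  out <- data.frame(cell_id = fx$matrix$cell_ids,
                    x = pmin(pmax(x, 0), 1000), y = pmin(pmax(y, 0), 1000))
  class(out) <- c("SpatialMap", "data.frame")
  out
}
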