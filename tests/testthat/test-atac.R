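write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

test_that("GTF gene records convert to 0-based half-open intervals", {
  p <- write_toy_gtf(c(
    "#!annotation toy",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"A\"; gene_name \"GeneA\";",
    "chr2\tsrc\tgene\t500\t900\t.\t-\t.\tgene_id \"B\"; gene_name \"GeneB\";",
    "chr2\tsrc\texon\t500\t600\t.\t-\t.\tgene_id \"B\";",
    "chrUn_scaffold\tsrc\tgene\t10\t20\t.\t+\t.\tgene_id \"C\"; gene_name \"GeneC\";"))
  genes <- parse_gtf_genes(p)
  expect_equal(nrow(genes), 3L)
  expect_equal(genes$start[genes$gene_id == "A"], 1000)
  expect_equal(genes$end[genes$gene_id == "A"], 2000)
  expect_equal(genes$strand, c("+", "-", "+"))
  expect_equal(genes$chrom[3], "chrUn_scaffold")  # unplaced contig retained
})

test_that("GTF parsing rejects duplicates and reports malformed lines", {
  dup <- write_toy_gtf(c(
    "chr1\ts\tgene\t1\t10\t.\t+\t.\tgene_id \"A\";",
    "chr1\ts\tgene\t20\t30\t.\t+\t.\tgene_id \"A\";"))
  expect_error(parse_gtf_genes(dup), "duplicate gene_id: A")
  bad <- write_toy_gtf(c(
    "chr1\ts\tgene\t1\t10\t.\t+\t.\tgene_id \"A\";",
    "chr1\tbroken line without tabs"))
  expect_error(parse_gtf_genes(bad), "line 2")
  nostrand <- write_toy_gtf(c(
    "chr1\ts\tgene\t1\t10\t.\t+\t.\tgene_id \"A\";",
    "chr1\ts\tgene\t20\t30\t.\t.\t.\tgene_id \"B\";"))
  expect_warning(genes <- parse_gtf_genes(nostrand), "without strand")
  expect_equal(genes$gene_id, "A")
})

test_that("range extension is strand-aware and clips at zero", {
  genes <- data.frame(gene_id = c("p", "m", "edge"),
                      gene_name = c("p", "m", "edge"),
                      chrom = "chr1",
                      start = c(10000, 10000, 500),
                      end = c(20000, 20000, 600),
                      strand = c("+", "-", "+"))
  ext <- extend_range(genes, extension_params(5000, 1000))
  expect_equal(ext$start, c(9000, 5000, 0))
  expect_equal(ext$end, c(25000, 21000, 5600))
  # strand antisymmetry: flipping the strand swaps the two extensions
  flipped <- genes
  flipped$strand <- c("-", "+", "-")
  ext_f <- extend_range(flipped, extension_params(5000, 1000))
  expect_equal(ext_f$start[1:2], ext$start[2:1])
  expect_equal(ext_f$end[1:2], ext$end[2:1])
  # strand-agnostic mode applies upstream/downstream in coordinate order
  ext_n <- extend_range(genes, extension_params(5000, 1000),
                        strand_aware = FALSE)
  expect_equal(ext_n$start, c(9000, 9000, 0))
})

test_that("peak id parsing accepts the three dialects and flags garbage", {
  iv <- parse_peak_ids(c("chr1:100-200", "chr1_100_200", "chr1-100-200"))
  expect_equal(iv$chrom, rep("chr1", 3))
  expect_equal(iv$start, rep(100, 3))
  expect_equal(iv$end, rep(200, 3))
  expect_error(parse_peak_ids(c("chr1:100-200", "chrX:abc-200")),
               "chrX:abc-200")
})

test_that("gene activity equals the brute-force overlap oracle", {
  fx <- make_atac_fixture(fixture_spec(n_cells = 12, seed = 3))
  act <- gene_activity_matrix(fx$peaks, fx$genes)
  expect_equal(as.matrix(act$values), fx$oracle, ignore_attr = TRUE)
  # repeat across seeds so strand, clipping, and boundary placements vary
  for (s in c(7, 19, 42)) {
    fx2 <- make_atac_fixture(fixture_spec(n_cells = 8, seed = s))
    act2 <- gene_activity_matrix(fx2$peaks, fx2$genes)
    expect_equal(as.matrix(act2$values), fx2$oracle, ignore_attr = TRUE)
  }
})

test_that("a peak overlapping two genes is counted in both", {
  genes <- data.frame(gene_id = c("g1", "g2"), gene_name = c("g1", "g2"),
                      chrom = "chr1", start = c(1000, 1400),
                      end = c(1500, 2000), strand = "+")
  counts <- matrix(c(3, 5), 2, 1,
                   dimnames = list(c("c1", "c2"), "chr1:1200-1450"))
  peaks <- AnnotatedMatrix(counts)
  peaks$layers[["counts"]] <- peaks$values
  act <- gene_activity_matrix(peaks, genes, extension_params(0, 0))
  expect_equal(as.matrix(act$values),
               cbind(g1 = c(3, 5), g2 = c(3, 5)), ignore_attr = TRUE)
  # conservation: total activity >= total counts of overlapping peaks,
  # equality only without multi-assignment
  expect_equal(sum(act$values), 2 * sum(counts))
})

test_that("all-zero gene columns are retained and chr mismatch is diagnosed", {
  genes <- data.frame(gene_id = c("hit", "miss"),
                      gene_name = c("hit", "miss"),
                      chrom = c("chr1", "chr9"),
                      start = c(100, 100), end = c(300, 300), strand = "+")
  counts <- matrix(1:2, 2, 1,
                   dimnames = list(c("c1", "c2"), "chr1:150-250"))
  peaks <- AnnotatedMatrix(counts)
  peaks$layers[["counts"]] <- peaks$values
  act <- gene_activity_matrix(peaks, genes, extension_params(0, 0))
  expect_equal(unname(as.matrix(act$values)[, "miss"]), c(0, 0))

  # bare "1" vs "chr1": zero overlaps in total plus disjoint chromosome
  # names triggers the harmonization hint; the flag fixes it
  colnames(counts) <- "1:150-250"
  peaks2 <- AnnotatedMatrix(counts)
  peaks2$layers[["counts"]] <- peaks2$values
  expect_error(gene_activity_matrix(peaks2, genes, extension_params(0, 0)),
               "harmonize")
  act2 <- gene_activity_matrix(peaks2, genes, extension_params(0, 0),
                               harmonize_chr = TRUE)
  expect_equal(unname(as.matrix(act2$values)[, "hit"]), c(1, 2))
})

test_that("the atac pipeline produces a scaled clustering-ready matrix", {
  fx <- make_atac_fixture(fixture_spec(n_cells = 20, seed = 1))
  out <- atac_pipeline(fx$peaks, fx$gtf_path, target_sum = 1e4)
  expect_equal(dim(out), c(20L, nrow(fx$genes)))
  expect_true(all(abs(colMeans(as.matrix(out$values))) < 1e-10))
  # zero-activity cell is caught by normalization with its id
  fx$peaks$layers[["counts"]][3, ] <- 0
  fx$peaks$values[3, ] <- 0
  expect_error(atac_pipeline(fx$peaks, fx$gtf_path), "cell0003")
})
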