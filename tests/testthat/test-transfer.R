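make_blob_reference <- function(seed = 1, n_per = 30, shift = 8) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 12), n_per, 12),
               matrix(rnorm(n_per * 12) + shift, n_per, 12))
  })
  AnnotatedMatrix(x, cell_ids = sprintf("r%03d", seq_len(2 * n_per)),
                  feature_ids = sprintf("g%02d", 1:12),
                  cell_meta = data.frame(label = rep(0:1, each = n_per)))
}

test_that("fit_transfer intersects genes in reference order", {
  ref <- make_blob_reference()
  model <- fit_transfer(ref, "label", ref$feature_ids, n_components = 5)
  expect_equal(model$overlapping_genes, ref$feature_ids)
  half <- ref$feature_ids[c(1, 3, 5, 7, 9, 11)]
  model2 <- fit_transfer(ref, "label", rev(half), n_components = 5)
  expect_equal(model2$overlapping_genes, half)  # reference order, not query
  expect_error(fit_transfer(ref, "label", c("x1", "x2")), "intersection")
  expect_error(fit_transfer(ref, "missing", ref$feature_ids), "label key")
})

test_that("self-transfer with k = 1 is the identity on labels", {
  ref <- make_blob_reference(seed = 2)
  model <- fit_transfer(ref, "label", ref$feature_ids, n_components = 10)
  res <- transfer_labels(model, ref, k = 1)
  expect_equal(ari(res$labels, ref$cell_meta$label), 1)
  expect_equal(res$confidence, rep(1, n_cells(ref)))
  expect_error(transfer_labels(model, ref, k = 1000), "reference cells")
})

test_that("query cells from one blob are all labelled as that blob", {
  ref <- make_blob_reference(seed = 3)
  withr::with_seed(4, q <- matrix(rnorm(20 * 12) + 8, 20, 12))
  query <- AnnotatedMatrix(q, cell_ids = sprintf("q%02d", 1:20),
                           feature_ids = ref$feature_ids)
  model <- fit_transfer(ref, "label", query$feature_ids, n_components = 10)
  res <- transfer_labels(model, query, k = 15)
  expect_equal(res$labels, rep(1, 20))
})

test_that("reference-statistic scaling reproduces the reference embedding", {
  ref <- make_blob_reference(seed = 5)
  model <- fit_transfer(ref, "label", ref$feature_ids, n_components = 8)
  res <- transfer_labels(model, ref, k = 1)
  expect_lt(max(abs(res$embedding - model$reference_embedding)), 1e-8)
})

test_that("transfer is equivariant under query cell permutation", {
  ref <- make_blob_reference(seed = 6)
  withr::with_seed(7, q <- rbind(matrix(rnorm(60), 5, 12),
                                 matrix(rnorm(60) + 8, 5, 12)))
  query <- AnnotatedMatrix(q, cell_ids = sprintf("q%02d", 1:10),
                           feature_ids = ref$feature_ids)
  model <- fit_transfer(ref, "label", query$feature_ids, n_components = 6)
  res <- transfer_labels(model, query, k = 5)
  perm <- c(4, 9, 1, 10, 2, 8, 3, 6, 5, 7)
  res_p <- transfer_labels(model, am_subset(query, cells = perm), k = 5)
  expect_equal(res_p$labels, res$labels[perm])
  expect_equal(res_p$confidence, res$confidence[perm])
})

test_that("correct cells carry higher confidence than mislabelled ones", {
  withr::with_seed(8, {
    n_per <- 40
    x <- rbind(matrix(rnorm(n_per * 10, sd = 1.6), n_per, 10),
               matrix(rnorm(n_per * 10, mean = 3, sd = 1.6), n_per, 10))
    labels <- rep(0:1, each = n_per)
    noisy <- labels
    flip <- sample(2 * n_per, round(0.05 * 2 * n_per))
    noisy[flip] <- 1 - noisy[flip]
  })
  ref <- AnnotatedMatrix(x, cell_ids = sprintf("r%03d", 1:80),
                         feature_ids = sprintf("g%02d", 1:10),
                         cell_meta = data.frame(label = noisy))
  model <- fit_transfer(ref, "label", ref$feature_ids, n_components = 5)
  res <- transfer_labels(model, ref, k = 15)
  correct <- res$labels == labels
  expect_gt(mean(res$confidence[correct]), mean(res$confidence[!correct]))
})

test_that("cluster freezing follows median confidence with an override", {
  part <- partition(c(0, 0, 1, 1, 2, 2))
  all_sure <- structure(list(labels = part$labels,
                             confidence = rep(1, 6)),
                        class = c("TransferResult", "list"))
  expect_true(all(select_frozen_clusters(all_sure, part)$frozen))

  mixed <- all_sure
  mixed$confidence <- c(1, 1, 0.5, 0.5, 0.95, 0.95)
  fr <- select_frozen_clusters(mixed, part, 0.9)
  expect_equal(fr$frozen, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))

  ov <- select_frozen_clusters(mixed, part, 0.9, override = c(1))
  expect_equal(ov$frozen, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_error(select_frozen_clusters(mixed, part, 1.5), "in \\(0, 1\\]")
})

test_that("cell-id label copy assigns matches and flags the rest", {
  src <- AnnotatedMatrix(matrix(0, 3, 2), cell_ids = c("a", "b", "c"),
                         feature_ids = c("f1", "f2"),
                         cell_meta = data.frame(ct = c("B", "T", "NK")))
  tgt10 <- AnnotatedMatrix(matrix(0, 10, 2),
                           cell_ids = c("a", "b", "c", paste0("z", 1:7)),
                           feature_ids = c("f1", "f2"))
  # extend source so 7 of 10 ids match
  src7 <- AnnotatedMatrix(matrix(0, 7, 2),
                          cell_ids = c("a", "b", "c", "z1", "z2", "z3", "z4"),
                          feature_ids = c("f1", "f2"),
                          cell_meta = data.frame(ct = letters[1:7]))
  out <- suppressMessages(copy_labels_by_cell_id(src7, tgt10, "ct"))
  expect_equal(attr(out, "n_matched"), 7L)
  expect_equal(sum(out$cell_meta$ct == "unassigned"), 3L)

  same <- suppressMessages(copy_labels_by_cell_id(src, am_subset(tgt10, 1:3),
                                                  "ct"))
  expect_equal(same$cell_meta$ct, c("B", "T", "NK"))

  disjoint <- AnnotatedMatrix(matrix(0, 2, 2), cell_ids = c("q1", "q2"),
                              feature_ids = c("f1", "f2"))
  expect_warning(suppressMessages(
    none <- copy_labels_by_cell_id(src, disjoint, "ct")), "no shared")
  expect_equal(none$cell_meta$ct, rep("unassigned", 2))
})

test_that("transfer TSV export carries cell id, label, and confidence", {
  ref <- make_blob_reference(seed = 9)
  model <- fit_transfer(ref, "label", ref$feature_ids, n_components = 5)
  res <- transfer_labels(model, ref, k = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_transfer_tsv(ref, res, p)
  back <- utils::read.delim(p)
  expect_equal(names(back), c("cell_id", "label", "confidence"))
  expect_equal(nrow(back), n_cells(ref))
})
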