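# Annotation, per-sample splitting, cross-well merging, conservation.

make_classified_well <- function(n_cells = 40, seed = 1, well_id = "W1") {
  cfg <- sim_config(n_cells = n_cells, rng_seed = seed)
  sim <- simulate_count_matrix(cfg)
  expr <- simulate_expression_well(cfg, sim$truth_cells)
  cuts <- compute_cutoffs(sim$counts, rng_seed = seed)
  cats <- binarize_and_categorize(sim$counts, cuts)
  sheet <- sample_sheet(cfg$taglist$tag_name, cfg$sample_names)
  list(well = expr$well, cats = cats, sheet = sheet, counts = sim$counts,
       truth = sim$truth_cells, cfg = cfg)
}

test_that("annotation fills metadata and seeded UUIDs reproduce", {
  x <- make_classified_well(seed = 51)
  ann <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 7)
  md <- ann$cell_metadata
  expect_setequal(c("well_id", "hash_category", "tag_name", "sample_name",
                    "cell_uuid"), names(md))
  expect_true(all(md$well_id == "W1"))
  singles <- md$hash_category == "singlet"
  expect_true(all(!is.na(md$sample_name[singles])))
  expect_true(all(is.na(md$sample_name[!singles])))
  ann2 <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 7)
  expect_identical(md$cell_uuid, ann2$cell_metadata$cell_uuid)
  ann3 <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 8)
  expect_false(any(md$cell_uuid == ann3$cell_metadata$cell_uuid))
  # different wells never collide
  annW2 <- annotate_well(x$well, x$cats, "W2", sheet = x$sheet, uuid_seed = 7)
  expect_identical(length(unique(c(md$cell_uuid, annW2$cell_metadata$cell_uuid))),
                   2L * nrow(md))
})

test_that("matrix barcodes missing from the classification become no_hash", {
  x <- make_classified_well(seed = 52)
  cats_cut <- x$cats[-(1:3), ]
  class(cats_cut) <- class(x$cats)
  attr(cats_cut, "tag_names") <- attr(x$cats, "tag_names")
  expect_warning(ann <- annotate_well(x$well, cats_cut, "W1", uuid_seed = 1),
                 "no_hash")
  dropped <- x$cats$cell_barcode[1:3]
  expect_true(all(ann$cell_metadata$hash_category[
    ann$cell_barcodes %in% dropped] == "no_hash"))
})

test_that("split routes cells by sample and conserves everything", {
  x <- make_classified_well(n_cells = 60, seed = 53)
  ann <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 3)
  out <- withr::local_tempdir()
  res <- split_by_hash(ann, x$sheet, out)
  parts <- lapply(res$files, read_10x_h5)
  expect_identical(sum(vapply(parts, function(p) ncol(p$matrix), integer(1))),
                   ncol(ann$matrix))
  expect_identical(sum(vapply(parts, function(p) sum(p$matrix), numeric(1))),
                   sum(ann$matrix))
  # per-gene conservation across the partition
  gene_sums <- Reduce(`+`, lapply(parts, function(p) Matrix::rowSums(p$matrix)))
  expect_equal(unname(gene_sums), unname(Matrix::rowSums(ann$matrix)))
  # non-singlets pooled into one labeled file
  ns <- parts[["non_singlet"]]
  expect_true(all(ns$cell_metadata$hash_category != "singlet"))
  for (s in setdiff(names(parts), "non_singlet")) {
    expect_true(all(parts[[s]]$cell_metadata$sample_name == s))
    expect_true(all(parts[[s]]$cell_metadata$hash_category == "singlet"))
  }
  # a singlet tag absent from the sheet is a configuration error
  bad_sheet <- x$sheet[-1, ]
  class(bad_sheet) <- class(x$sheet)
  if (any(ann$cell_metadata$tag_name == x$sheet$tag_name[1] &
          ann$cell_metadata$hash_category == "singlet"))
    expect_error(split_by_hash(ann, bad_sheet, withr::local_tempdir()),
                 x$sheet$tag_name[1])
})

test_that("merging one well's splits reconstructs it up to column order", {
  x <- make_classified_well(n_cells = 50, seed = 54)
  ann <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 5)
  sdir <- withr::local_tempdir(); mdir <- withr::local_tempdir()
  split_by_hash(ann, x$sheet, sdir)
  res <- merge_by_sample(sdir, mdir)
  merged <- lapply(res$files, read_10x_h5)
  all_uuid <- unlist(lapply(merged, function(m) m$cell_metadata$cell_uuid))
  expect_setequal(all_uuid, ann$cell_metadata$cell_uuid)
  # reassemble and compare in uuid order
  big <- do.call(cbind, lapply(merged, function(m) m$matrix))
  ord_a <- order(all_uuid)
  ord_b <- order(ann$cell_metadata$cell_uuid)
  expect_equal(as.matrix(big[, ord_a]), as.matrix(ann$matrix[, ord_b]),
               ignore_attr = TRUE)
})

test_that("merge concatenates wells in order and validates features", {
  x1 <- make_classified_well(n_cells = 30, seed = 55)
  x2 <- make_classified_well(n_cells = 35, seed = 56)
  sheet <- x1$sheet
  sdir <- withr::local_tempdir(); mdir <- withr::local_tempdir()
  a1 <- annotate_well(x1$well, x1$cats, "W1", sheet = sheet, uuid_seed = 9)
  a2 <- annotate_well(x2$well, x2$cats, "W2", sheet = sheet, uuid_seed = 9)
  split_by_hash(a1, sheet, sdir)
  split_by_hash(a2, sheet, sdir)
  res <- merge_by_sample(sdir, mdir)
  m1 <- read_10x_h5(res$files[[setdiff(names(res$files), "non_singlet")[1]]])
  expect_identical(sort(unique(m1$cell_metadata$well_id)),
                   sort(intersect(c("W1", "W2"), m1$cell_metadata$well_id)))
  # well order then barcode order within each well
  wid <- m1$cell_metadata$well_id
  expect_true(!is.unsorted(wid))
  for (w in unique(wid))
    expect_false(is.unsorted(m1$cell_barcodes[wid == w]))
  # feature mismatch is rejected with the offending feature index
  bad <- x2$well
  bad$features$id[5] <- "DIFFERENT"
  abad <- annotate_well(bad, x2$cats, "W3", sheet = sheet, uuid_seed = 2)
  sdir2 <- withr::local_tempdir()
  split_by_hash(a1, sheet, sdir2)
  split_by_hash(abad, sheet, sdir2)
  expect_error(merge_by_sample(sdir2, withr::local_tempdir()),
               "feature list mismatch")
})

test_that("well report summarizes categories, reads and per-tag RNA", {
  x <- make_classified_well(n_cells = 50, seed = 57)
  ann <- annotate_well(x$well, x$cats, "W1", sheet = x$sheet, uuid_seed = 4)
  rep <- well_report(ann, x$counts)
  expect_identical(rep$n_cells, 50L)
  expect_equal(Reduce(`+`, rep$fraction_per_category), 1, tolerance = 1e-9)
  expect_equal(Reduce(`+`, rep$hto_read_fraction_per_category), 1,
               tolerance = 1e-9)
  # detected-genes definition: strictly positive counts
  expect_identical(unname(Matrix::colSums(ann$matrix > 0)[1]),
                   sum(ann$matrix[, 1] > 0))
  # median RNA for a two-cell tag equals the midpoint
  m <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(1000, 3000),
                            dims = c(2, 2))
  feats <- tibble::tibble(id = c("G1", "G2"), name = c("g1", "g2"),
                          feature_type = rep("Gene Expression", 2))
  md <- tibble::tibble(well_id = c("W", "W"),
                       hash_category = c("singlet", "singlet"),
                       tag_name = c("HT1", "HT1"),
                       cell_uuid = c("u1", "u2"))
  toy <- well_matrix(m, feats, c("AC", "GT"), md)
  r <- well_report(toy)
  expect_equal(r$rna_umis_by_tag$HT1$median, 2000)
  expect_equal(r$genes_detected_by_tag$HT1$median, 1)
})
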