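# 1-D 2-means, cutoff derivation, and category assignment.

test_that("two_means_1d solves hand-checkable instances exactly", {
  r <- two_means_1d(c(1, 2, 10, 11))
  expect_equal(r$lower_center, 1.5)
  expect_equal(r$upper_center, 10.5)
  expect_identical(r$labels, c(1L, 1L, 2L, 2L))

  r <- two_means_1d(c(5, 5, 5, 9))
  expect_identical(r$labels, c(1L, 1L, 1L, 2L))
  expect_equal(r$lower_center, 5)
  expect_equal(r$upper_center, 9)

  # labels follow input order, not sorted order
  r <- two_means_1d(c(10, 1, 11, 2))
  expect_identical(r$labels, c(2L, 1L, 2L, 1L))
  expect_error(two_means_1d(c(3, 3, 3)), "distinct")
})

test_that("two_means_1d matches the exhaustive sorted-split oracle", {
  set.seed(13)
  for (r in 1:40) {
    n <- sample(2:60, 1)
    x <- switch(1 + r %% 3,
                rnorm(n), round(rlnorm(n, 3, 1)), c(rnorm(n %/% 2 + 1), rnorm(n %/% 2 + 1, 8)))
    if (length(unique(x)) < 2) next
    got <- two_means_1d(x)
    want <- oracle_two_means(x)
    expect_equal(got$withinss, want$cost, tolerance = 1e-9)
    expect_equal(sum(got$labels == 1L), want$split)
  }
})

test_that("unimodal cutoff equals back-transformed mean + k*sd, any log base", {
  counts <- withr::with_seed(5, round(rlnorm(1000, log(100), 0.4)))
  cut <- compute_cutoff(counts, rng_seed = 2)
  expect_identical(cut$method, "unimodal_mean2sd")
  lg <- log(counts[counts >= 10])
  expect_equal(cut$cutoff, exp(mean(lg) + 2 * sd(lg)), tolerance = 1e-12)
  # base-10 log gives the same count-scale cutoff
  l10 <- log10(counts[counts >= 10])
  expect_equal(cut$cutoff, 10^(mean(l10) + 2 * sd(l10)), tolerance = 1e-9)
})

test_that("bimodal cutoff is the minimum count of the upper cluster", {
  neg <- withr::with_seed(8, round(rlnorm(500, log(15), 0.3)))
  pos <- withr::with_seed(9, round(rlnorm(500, log(2000), 0.3)))
  cut <- compute_cutoff(c(neg, pos), rng_seed = 3)
  expect_identical(cut$method, "bimodal_kmeans")
  expect_identical(cut$cutoff, min(pos))
  expect_gt(exp(cut$center_hi_log - cut$center_lo_log), 4)
})

test_that("modes separated less than fourfold pass nothing", {
  a <- withr::with_seed(10, round(rlnorm(600, log(30), 0.15)))
  b <- withr::with_seed(11, round(rlnorm(600, log(90), 0.15)))
  cut <- compute_cutoff(c(a, b), rng_seed = 4)
  expect_identical(cut$method, "none_passing")
  expect_identical(cut$cutoff, max(c(a, b)) + 1)
  expect_equal(sum(c(a, b) >= cut$cutoff), 0)
})

test_that("low-count tags are insufficient_data and nothing passes", {
  cut <- compute_cutoff(rep(c(1, 5, 9), 100), rng_seed = 1)
  expect_identical(cut$method, "insufficient_data")
  expect_identical(cut$cutoff, Inf)
  # a few values >= 10 but fewer than min_values
  cut <- compute_cutoff(c(rep(2, 50), 11, 12, 13), rng_seed = 1)
  expect_identical(cut$method, "insufficient_data")
})

test_that("categorization follows the passing-count rule with >= semantics", {
  umi <- rbind(c(500, 3, 0), c(500, 500, 2), c(100, 99, 0), c(0, 0, 0),
               c(500, 500, 500))
  rownames(umi) <- paste0("BC", 1:5)
  colnames(umi) <- c("HT1", "HT2", "HT3")
  counts <- hto_counts(umi)
  cuts <- tibble::tibble(tag_name = c("HT1", "HT2", "HT3"),
                         cutoff = c(100, 100, 100))
  cats <- binarize_and_categorize(counts, cuts)
  got <- setNames(as.character(cats$category), cats$cell_barcode)
  expect_identical(got[["BC1"]], "singlet")
  expect_identical(got[["BC2"]], "doublet")
  expect_identical(got[["BC3"]], "singlet")   # 100 >= 100 passes, 99 fails
  expect_identical(got[["BC4"]], "no_hash")
  expect_identical(got[["BC5"]], "multiplet")
  expect_identical(cats$assigned_tags[cats$cell_barcode == "BC2"], "HT1;HT2")
  expect_identical(cats$top_tag_count[cats$cell_barcode == "BC1"], 500L)
  expect_identical(cats$second_tag_count[cats$cell_barcode == "BC1"], 3L)
})

test_that("categorization commutes with barcode permutation", {
  set.seed(21)
  umi <- matrix(rpois(60, 50), 20, 3,
                dimnames = list(replicate(20, paste(sample(c("A","C","G","T"), 8,
                                                           TRUE), collapse = "")),
                                c("HT1", "HT2", "HT3")))
  cuts <- tibble::tibble(tag_name = colnames(umi), cutoff = c(40, 55, 60))
  a <- binarize_and_categorize(hto_counts(umi), cuts)
  perm <- sample(nrow(umi))
  b <- binarize_and_categorize(hto_counts(umi[perm, ]), cuts)
  expect_identical(dplyr::arrange(tibble::as_tibble(a), cell_barcode),
                   dplyr::arrange(tibble::as_tibble(b), cell_barcode))
})

test_that("raising a cutoff never turns no_hash into a positive category", {
  set.seed(22)
  umi <- matrix(rpois(90, 30), 30, 3,
                dimnames = list(sprintf("BC%02d", 1:30), c("HT1", "HT2", "HT3")))
  counts <- hto_counts(umi)
  lo <- tibble::tibble(tag_name = colnames(umi), cutoff = c(20, 25, 30))
  hi <- dplyr::mutate(lo, cutoff = cutoff + 10)
  a <- binarize_and_categorize(counts, lo)
  b <- binarize_and_categorize(counts, hi)
  was_none <- a$category == "no_hash"
  expect_true(all(b$category[was_none] == "no_hash"))
})

test_that("classification metrics keep a stable schema", {
  umi <- rbind(c(500, 3), c(400, 1), c(300, 2), c(500, 500))
  rownames(umi) <- paste0("BC", 1:4); colnames(umi) <- c("HT1", "HT2")
  cats <- binarize_and_categorize(
    hto_counts(umi), tibble::tibble(tag_name = c("HT1", "HT2"), cutoff = c(100, 100)))
  m <- classification_metrics(cats)
  expect_identical(m$total_barcodes, 4L)
  expect_identical(m$singlet, 3L)
  expect_identical(m$doublet, 1L)
  expect_identical(m$multiplet, 0L)   # empty categories present, zero-valued
  expect_identical(m$no_hash, 0L)
  expect_equal(m$fractions$singlet, 0.75)
  expect_identical(m$tag_passing$HT1, 4L)
})

test_that("cutoff table methods tidy, glance and plot", {
  sim <- simulate_count_matrix(sim_config(n_cells = 400, rng_seed = 31))
  cuts <- compute_cutoffs(sim$counts, rng_seed = 5)
  expect_s3_class(tidy(cuts), "tbl_df")
  g <- glance(cuts)
  expect_identical(g$n_tags, 6L)
  expect_identical(g$n_bimodal + g$n_unimodal + g$n_none_passing +
                     g$n_insufficient, 6L)
  p <- autoplot(cuts, sim$counts)
  expect_s3_class(p, "ggplot")
})
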