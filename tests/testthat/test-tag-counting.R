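# Read parsing, barcode/hashtag matching, UMI deduplication and the trie.

test_that("parse_read slices by layout, truncates long reads, tallies short", {
  pairs <- tibble::tibble(
    read_id = c("a", "b", "c"),
    r1_seq = c(strrep("A", 28), strrep("A", 27), paste0(strrep("C", 28), strrep("G", 63))),
    r1_qual = c(strrep("F", 28), strrep("F", 27), strrep("F", 91)),
    r2_seq = c(strrep("C", 15), strrep("C", 15), strrep("T", 15)),
    r2_qual = c(strrep("F", 15), strrep("F", 15), strrep("F", 15)))
  p <- parse_read(pairs)
  expect_identical(p$cb[1], strrep("A", 16))
  expect_identical(p$umi[1], strrep("A", 12))
  expect_identical(p$tag_seq[1], strrep("C", 15))
  expect_true(p$too_short[2])
  # a 91 bp R1 uses only its first 28 bases
  expect_identical(p$cb[3], strrep("C", 16))
  expect_identical(p$umi[3], strrep("C", 12))
})

test_that("sequence trie stores membership with payloads", {
  seqs <- c("ACGT", "ACGG", "TTTT")
  tr <- sequence_trie(seqs, payloads = 1:3)
  expect_identical(trie_contains(tr, c("ACGT", "ACGA", "TTTT", "ACG")),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(trie_size(tr), 3L)
  trie_insert(tr, "ACGA")
  expect_true(trie_contains(tr, "ACGA"))
  expect_identical(trie_size(tr), 4L)  # insert mutates in place
  trie_insert(tr, "ACGA")              # re-insertion is idempotent
  expect_identical(trie_size(tr), 4L)
})

test_that("barcode matching: exact wins, low-quality rescue, high-quality none", {
  wl <- c(strrep("A", 16), paste0("CC", strrep("A", 14)))
  layout <- read_layout()
  # exact match regardless of terrible quality
  got <- match_cell_barcode(strrep("A", 16), rep(2L, 16), wl, layout)
  expect_identical(as.character(got), strrep("A", 16))
  expect_identical(attr(got, "status"), "exact")
  # single low-quality mismatch rescued
  cb <- paste0("C", strrep("A", 15))
  q <- c(10L, rep(37L, 15))
  got <- match_cell_barcode(cb, q, wl, layout)
  expect_identical(as.character(got), strrep("A", 16))
  expect_identical(attr(got, "status"), "corrected")
  # same mismatch at high quality is not rescued
  got <- match_cell_barcode(cb, rep(30L, 16), wl, layout)
  expect_true(is.na(got))
  expect_identical(attr(got, "status"), "invalid")
  # two whitelist barcodes reachable -> ambiguous
  cb2 <- paste0("CA", strrep("A", 14))   # pos2 A->C gives wl[2]; pos1 C->A gives wl[1]
  got <- match_cell_barcode(cb2, c(10L, 10L, rep(37L, 14)), wl, layout)
  expect_true(is.na(got))
  expect_identical(attr(got, "status"), "ambiguous")
  # quality strings are accepted too (',' = Q11)
  got <- match_cell_barcode(cb, paste0(",", strrep("F", 15)), wl, layout)
  expect_identical(as.character(got), strrep("A", 16))
  # trie-backed whitelist gives identical results
  tr <- sequence_trie(wl)
  got <- match_cell_barcode(cb, q, tr, layout)
  expect_identical(as.character(got), strrep("A", 16))
})

test_that("hashtag matching tolerates one mismatch, never two", {
  tl <- tiny_taglist()
  expect_identical(as.integer(match_hashtag("AAAAAAAAAAAAAAA", tl)), 1L)
  one_off <- "AAAAAAATAAAAAAA"
  expect_identical(as.integer(match_hashtag(one_off, tl)), 1L)
  two_off <- "AAAAAAATTAAAAAA"
  expect_true(is.na(match_hashtag(two_off, tl)))
  # ambiguity when a taglist violates spacing
  close_tl <- suppressWarnings(taglist(c("T1", "T2"),
                                       c("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAC")))
  got <- match_hashtag("AAAAAAAAAAAAAAG", close_tl)
  expect_true(is.na(got))
  expect_identical(attr(got, "status"), "ambiguous")
})

count_toy_well <- function(pairs, wl, tl, scope = "barcode_tag") {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_raw_fastq(pairs$read_id, pairs$r1_seq, pairs$r1_qual,
                  file.path(d, "t_R1.fastq"))
  write_raw_fastq(pairs$read_id, pairs$r2_seq, pairs$r2_qual,
                  file.path(d, "t_R2.fastq"))
  count_well(file.path(d, "t_R1.fastq"), file.path(d, "t_R2.fastq"),
             wl, tl, dedup_scope = scope)
}

toy_pairs <- function(cb, umi, tag) {
  n <- length(cb)
  tibble::tibble(read_id = sprintf("r%03d", seq_len(n)),
                 r1_seq = paste0(cb, umi),
                 r1_qual = strrep("F", 28),
                 r2_seq = tag,
                 r2_qual = strrep("F", 15))
}

test_that("UMI deduplication counts first occurrences only", {
  tl <- tiny_taglist()
  bc <- strrep("A", 16)
  u1 <- strrep("C", 12); u2 <- strrep("G", 12)
  pairs <- toy_pairs(rep(bc, 3), c(u1, u1, u2), rep(tl$tag_seq[1], 3))
  counts <- count_toy_well(pairs, bc, tl)
  expect_identical(unname(counts$umi[1, ]), c(2L, 0L, 0L))
  expect_identical(unname(counts$reads[1, ]), c(3L, 0L, 0L))
  expect_identical(counts$metrics$pairs_counted, 3)
})

test_that("scope 'barcode' suppresses a UMI reappearing under another tag", {
  tl <- tiny_taglist()
  bc <- strrep("A", 16)
  u1 <- strrep("C", 12)
  pairs <- toy_pairs(rep(bc, 2), c(u1, u1), tl$tag_seq[1:2])
  per_tag <- count_toy_well(pairs, bc, tl, "barcode_tag")
  expect_identical(unname(per_tag$umi[1, ]), c(1L, 1L, 0L))
  per_bc <- count_toy_well(pairs, bc, tl, "barcode")
  expect_identical(unname(per_bc$umi[1, ]), c(1L, 0L, 0L))
  expect_identical(unname(per_bc$reads[1, ]), c(1L, 1L, 0L))
})

test_that("UMI sequence errors are never corrected (distinct UMIs count twice)", {
  tl <- tiny_taglist()
  bc <- strrep("A", 16)
  u <- strrep("C", 12)
  u_err <- paste0("G", strrep("C", 11))
  pairs <- toy_pairs(rep(bc, 2), c(u, u_err), rep(tl$tag_seq[1], 2))
  counts <- count_toy_well(pairs, bc, tl)
  expect_identical(unname(counts$umi[1, ]), c(2L, 0L, 0L))
})

test_that("short pairs and unmatched reads are tallied, conservation holds", {
  tl <- tiny_taglist()
  bc <- strrep("A", 16)
  good <- toy_pairs(bc, strrep("C", 12), tl$tag_seq[1])
  shrt <- tibble::tibble(read_id = "s1", r1_seq = strrep("A", 20),
                         r1_qual = strrep("F", 20),
                         r2_seq = strrep("C", 15), r2_qual = strrep("F", 15))
  badcb <- toy_pairs(strrep("T", 16), strrep("C", 12), tl$tag_seq[1])
  badtag <- toy_pairs(bc, strrep("A", 12), strrep("T", 15))
  pairs <- dplyr::bind_rows(good, shrt, badcb, badtag)
  counts <- count_toy_well(pairs, bc, tl)
  m <- counts$metrics
  expect_identical(m$total_read_pairs, 4)
  expect_identical(m$pairs_dropped_short, 1)
  expect_identical(m$pairs_barcode_invalid, 1)
  expect_identical(m$pairs_tag_invalid, 1)
  expect_identical(m$pairs_counted, 1)
  expect_identical(m$total_read_pairs,
                   m$pairs_counted + m$pairs_dropped_short +
                     m$pairs_barcode_invalid + m$pairs_barcode_ambiguous +
                     m$pairs_tag_invalid + m$pairs_tag_ambiguous)
  # the tag-failing read still counts toward the barcode's read total
  expect_identical(unname(counts$total_reads), 2L)
  expect_error(count_toy_well(pairs, character(0), tl), "whitelist is empty")
})

test_that("count_well matches the brute-force set-based oracle", {
  for (r in 1:6) {
    cfg <- sim_config(n_cells = 25, rng_seed = 300 + r,
                      reads_per_umi = 3,
                      positive_mode = c(log(15), 0.5),
                      negative_mode = c(log(3), 0.6),
                      tag_error_rate = c(0, 0.1)[1 + r %% 2],
                      tag_error2_rate = c(0, 0.05)[1 + r %% 2],
                      cb_lowq_error_rate = 0.05,
                      cb_highq_error_rate = 0.03)
    sim <- simulate_hto_fastq(cfg, withr::local_tempdir())
    wl <- load_barcode_whitelist(sim$whitelist)
    pairs <- read_paired_fastq(sim$r1, sim$r2)
    for (scope in c("barcode_tag", "barcode")) {
      got <- count_well(sim$r1, sim$r2, wl, sim$taglist, dedup_scope = scope)
      want <- oracle_count_well(pairs, wl, sim$taglist, dedup_scope = scope)
      expect_identical(got$umi, want$umi)
      expect_identical(got$reads, want$reads)
      expect_identical(unname(got$total_reads), unname(want$total_reads))
    }
  }
})

test_that("appending reads never decreases UMI counts; chunking is irrelevant", {
  cfg <- sim_config(n_cells = 30, rng_seed = 91, reads_per_umi = 3,
                    positive_mode = c(log(15), 0.5),
                    negative_mode = c(log(3), 0.6))
  sim <- simulate_hto_fastq(cfg, withr::local_tempdir(), compress = FALSE)
  wl <- load_barcode_whitelist(sim$whitelist)
  full <- count_well(sim$r1, sim$r2, wl, sim$taglist)
  tiny_chunks <- count_well(sim$r1, sim$r2, wl, sim$taglist, chunk_size = 17)
  expect_identical(full$umi, tiny_chunks$umi)
  expect_identical(full$metrics, tiny_chunks$metrics)
  # prefix of the stream: counts can only grow as reads append
  l1 <- readLines(sim$r1); l2 <- readLines(sim$r2)
  half <- (length(l1) %/% 8) * 4
  d <- withr::local_tempdir()
  writeLines(l1[1:half], file.path(d, "h_R1.fastq"))
  writeLines(l2[1:half], file.path(d, "h_R2.fastq"))
  part <- count_well(file.path(d, "h_R1.fastq"), file.path(d, "h_R2.fastq"),
                     wl, sim$taglist)
  common <- intersect(rownames(part$umi), rownames(full$umi))
  expect_true(all(full$umi[common, ] >= part$umi[common, ]))
})
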