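# Ground-truthed synthetic data: paired HTO FASTQ, HTO count matrices and
# expression wells emulating a pooled Cell Hashing experiment.

# BioLegend TotalSeq-A hashing antibody barcodes (15 bp, widely spaced)
TOTALSEQ_A_HASHTAGS <- c(
  HT1 = "GTCAACTCTTTAGCG", HT2 = "TGATGGCCTATTGGG", HT3 = "TTCCGCCTCTCTTTG",
  HT4 = "AGTAAGTTCAGCGTA", HT5 = "AAGTATCGTTTCGCA", HT6 = "GGTTGCCAGATGTCA",
  HT7 = "TGTCTTTCCTGCCAG", HT8 = "CTCCTCTGCAATTAC", HT9 = "CAGTAGTCACGGTCA",
  HT10 = "ATTGACCCGCGTTAG")

#' Default hashing taglist
#'
#' @param n_tags Number of hashtags (up to 10 commercial barcode sequences).
#' @return A [taglist()].
#' @export
default_taglist <- function(n_tags = 6L) {
  stopifnot(n_tags >= 1L, n_tags <= length(TOTALSEQ_A_HASHTAGS))
  taglist(names(TOTALSEQ_A_HASHTAGS)[seq_len(n_tags)],
          unname(TOTALSEQ_A_HASHTAGS[seq_len(n_tags)]))
}

#' Simulation configuration
#'
#' Defines the conditions of a simulated pooled hashing experiment: cells
#' per well, hashtags and their sample assignments, doublet and no-hash
#' rates, the two log-normal count modes (bound antibody signal vs ambient
#' background), sequencing-depth and error-injection parameters.
#'
#' Defaults emulate a hashing library sequenced to the usual ~2,000 reads
#' per cell: around 160 bound UMIs per cell for the labeling tag against an
#' ambient background of ~8 UMIs for each other tag (20-fold mode separation
#' on the count scale), ~10 reads per UMI, an 8% doublet rate, and 2% of
#' cells with no hash.
#'
#' @param n_cells Cells per well (default 1000).
#' @param n_wells Number of wells (default 1).
#' @param taglist A [taglist()] (default 6 commercial hashtags).
#' @param sample_names Sample labels, one per tag.
#' @param doublet_rate,no_hash_rate Fractions of cells (defaults 0.08, 0.02).
#' @param reads_per_umi Mean reads per UMI (each UMI emits `1 + Poisson`
#'   reads; default 10).
#' @param positive_mode,negative_mode Log-scale `c(meanlog, sdlog)` pairs
#'   for the bound and background count modes.
#' @param gap Optional `c(lo, hi)`: counts are kept out of this open
#'   interval so the two modes are perfectly separable (default off).
#' @param tag_error_rate Per-read probability of a 1-base tag substitution.
#' @param tag_error2_rate Per-read probability of a 2-base tag substitution.
#' @param cb_lowq_error_rate Per-read probability of a barcode substitution
#'   at a low-quality (Q11) position.
#' @param cb_highq_error_rate Per-read probability of a barcode substitution
#'   at a high-quality (Q37) position.
#' @param n_genes Genes in simulated expression matrices (default 500).
#' @param rna_depth_meanlog,rna_depth_sdlog Log-normal per-cell RNA depth.
#' @param rng_seed Integer seed; every simulated artifact is a deterministic
#'   function of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000L, n_wells = 1L,
                       taglist = default_taglist(6L),
                       sample_names = paste0("sample", seq_len(nrow(taglist))),
                       doublet_rate = 0.08, no_hash_rate = 0.02,
                       reads_per_umi = 10,
                       positive_mode = c(meanlog = log(160), sdlog = 0.5),
                       negative_mode = c(meanlog = log(8), sdlog = 0.6),
                       gap = NULL,
                       tag_error_rate = 0, tag_error2_rate = 0,
                       cb_lowq_error_rate = 0, cb_highq_error_rate = 0,
                       n_genes = 500L,
                       rna_depth_meanlog = log(2000), rna_depth_sdlog = 0.4,
                       rng_seed = 1L) {
  rates <- c(doublet_rate, no_hash_rate, tag_error_rate, tag_error2_rate,
             cb_lowq_error_rate, cb_highq_error_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            doublet_rate + no_hash_rate < 1,
            positive_mode[1] > negative_mode[1],
            length(sample_names) == nrow(taglist))
  structure(list(
    n_cells = as.integer(n_cells), n_wells = as.integer(n_wells),
    taglist = taglist, sample_names = as.character(sample_names),
    doublet_rate = doublet_rate, no_hash_rate = no_hash_rate,
    reads_per_umi = reads_per_umi,
    positive_mode = positive_mode, negative_mode = negative_mode, gap = gap,
    tag_error_rate = tag_error_rate, tag_error2_rate = tag_error2_rate,
    cb_lowq_error_rate = cb_lowq_error_rate,
    cb_highq_error_rate = cb_highq_error_rate,
    n_genes = as.integer(n_genes),
    rna_depth_meanlog = rna_depth_meanlog, rna_depth_sdlog = rna_depth_sdlog,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

# k distinct random DNA sequences of given length (indices sampled without
# replacement so sequences are unique by construction; len <= 12)
random_distinct_seqs <- function(k, len) {
  stopifnot(4^len <= .Machine$integer.max)
  ints <- sample.int(4^len, k) - 1L
  cols <- vector("list", len)
  for (p in seq_len(len)) {
    cols[[len - p + 1L]] <- DNA_BASES[ints %% 4L + 1L]
    ints <- ints %/% 4L
  }
  do.call(paste0, cols)
}

# n random barcodes of length len with pairwise Hamming distance >= 2
# (no barcode in another's 1-neighborhood), so single-base correction is
# always unambiguous
random_whitelist <- function(n, len = 16L) {
  half <- len %/% 2L
  make <- function(k) {
    paste0(random_distinct_seqs(k, half), random_distinct_seqs(k, len - half))
  }
  bc <- make(n)
  repeat {
    # a pair of barcodes within Hamming distance <= 2 shares a sequence
    # between their distance-<=1 neighborhoods; resample either member
    nbhd <- neighborhood1(bc)
    dup_seq <- unique(nbhd$seq[duplicated(nbhd$seq)])
    if (!length(dup_seq)) break
    bad <- unique(nbhd$origin[nbhd$seq %in% dup_seq])
    bc[bad] <- make(length(bad))
  }
  sort(bc)
}

# all distance-<=1 variants (including self) with originating index
neighborhood1 <- function(seqs) {
  len <- nchar(seqs[1])
  out_seq <- c(seqs)
  out_org <- seq_along(seqs)
  for (p in seq_len(len)) {
    cur <- substr(seqs, p, p)
    for (b in DNA_BASES) {
      keep <- cur != b
      v <- seqs[keep]
      substr(v, p, p) <- b
      out_seq <- c(out_seq, v)
      out_org <- c(out_org, which(keep))
    }
  }
  list(seq = out_seq, origin = out_org)
}

# assign categories and true tags to cells
assign_truth_cells <- function(cfg, barcodes, well_id) {
  n <- length(barcodes)
  ntag <- nrow(cfg$taglist)
  u <- runif(n)
  category <- ifelse(u < cfg$doublet_rate, "doublet",
                     ifelse(u < cfg$doublet_rate + cfg$no_hash_rate,
                            "no_hash", "singlet"))
  tag1 <- sample.int(ntag, n, replace = TRUE)
  tag2 <- ((tag1 - 1L + sample.int(ntag - 1L, n, replace = TRUE)) %% ntag) + 1L
  true_tags <- ifelse(
    category == "singlet", cfg$taglist$tag_name[tag1],
    ifelse(category == "doublet",
           paste(cfg$taglist$tag_name[pmin(tag1, tag2)],
                 cfg$taglist$tag_name[pmax(tag1, tag2)], sep = ";"),
           ""))
  tibble::tibble(well_id = well_id, cell_barcode = barcodes,
                 true_category = category, true_tags = true_tags)
}

# draw a counts matrix (cells x tags) given truth assignments
draw_true_counts <- function(cfg, truth) {
  n <- nrow(truth)
  ntag <- nrow(cfg$taglist)
  tags <- cfg$taglist$tag_name
  pos_set <- strsplit(truth$true_tags, ";", fixed = TRUE)
  draw <- function(k, mode, positive) {
    x <- round(rlnorm(k, mode[1], mode[2]))
    if (positive) x <- pmax(x, 1)
    if (!is.null(cfg$gap)) {
      if (positive) x <- pmax(x, ceiling(cfg$gap[2]))
      else x <- pmin(x, floor(cfg$gap[1]))
    }
    x
  }
  m <- matrix(draw(n * ntag, cfg$negative_mode, FALSE), n, ntag,
              dimnames = list(truth$cell_barcode, tags))
  pos_idx <- cbind(rep(seq_len(n), lengths(pos_set)),
                   match(unlist(pos_set), tags))
  if (nrow(pos_idx))
    m[pos_idx] <- draw(nrow(pos_idx), cfg$positive_mode, TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Simulate an HTO count matrix with ground truth
#'
#' Draws per-tag counts directly (no reads): each cell's labeling tag(s) get
#' positive-mode counts, all others background-mode counts. A direct fixture
#' for the classification stage.
#'
#' @param config A [sim_config()].
#' @param well_id Label recorded in the truth table.
#' @return List: `counts` (an [hto_counts()]), `truth_cells` (tibble with
#'   per-cell true category and tags).
#' @export
simulate_count_matrix <- function(config, well_id = "well1") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    barcodes <- random_whitelist(config$n_cells)
    truth <- assign_truth_cells(config, barcodes, well_id)
    m <- draw_true_counts(config, truth)
    list(counts = hto_counts(m), truth_cells = truth)
  })
}

#' Simulate paired HTO FASTQ files with ground truth
#'
#' Emulates a hashed 10x well: whitelist barcodes (pairwise Hamming
#' distance >= 2), per-cell true tag assignments, per-(cell, tag) UMI counts
#' from the two log-normal modes, each UMI emitted as `1 + Poisson` reads,
#' and sequencing errors injected per read at the configured rates. Base
#' qualities are Q37 everywhere except at injected low-quality error
#' positions (Q11), so the Q<20 correction rule is exercised from both
#' sides. Reads are written in a deterministic shuffled order.
#'
#' Error injection is constructed to be fully recoverable or fully fatal:
#' single-base tag errors and low-quality barcode errors are always
#' correctable (tag spacing >= 3, whitelist spacing >= 2), while two-base tag
#' errors and high-quality barcode errors always drop the read.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory for the FASTQ pair and side files.
#' @param well_id Well label used in file names and truth tables.
#' @param compress Write gzip FASTQ (default TRUE).
#' @return List with paths (`r1`, `r2`, `whitelist`), the `taglist`, and
#'   tibbles `truth_cells` (per-cell category/tags), `truth_umis`
#'   (per-(cell, tag) true UMI counts) and `truth_reads` (per-read cell,
#'   tag, UMI and injected error type).
#' @export
simulate_hto_fastq <- function(config, out_dir, well_id = "well1",
                               compress = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  withr::with_seed(cfg$rng_seed, {
    barcodes <- random_whitelist(cfg$n_cells)
    truth <- assign_truth_cells(cfg, barcodes, well_id)
    m <- draw_true_counts(cfg, truth)
    ntag <- ncol(m)
    # molecules: one row per (cell, tag) with count > 0
    nz <- which(m > 0, arr.ind = TRUE)
    mol_cell <- nz[, 1]; mol_tag <- nz[, 2]; mol_n <- m[nz]
    # distinct UMIs within each (cell, tag)
    umi_cell <- rep(mol_cell, mol_n)
    umi_tag <- rep(mol_tag, mol_n)
    total_umis <- length(umi_cell)
    umi_seq <- random_distinct_seqs(total_umis, 12L)  # globally distinct
    # reads per UMI
    reads_per <- 1L + rpois(total_umis, cfg$reads_per_umi - 1)
    rd_cell <- rep(umi_cell, reads_per)
    rd_tag <- rep(umi_tag, reads_per)
    rd_umi <- rep(umi_seq, reads_per)
    nread <- length(rd_cell)
    # error type per read (mutually exclusive)
    er <- runif(nread)
    p1 <- cfg$tag_error_rate; p2 <- p1 + cfg$tag_error2_rate
    p3 <- p2 + cfg$cb_lowq_error_rate; p4 <- p3 + cfg$cb_highq_error_rate
    etype <- ifelse(er < p1, "tag1", ifelse(er < p2, "tag2",
             ifelse(er < p3, "cb_lowq", ifelse(er < p4, "cb_highq", "none"))))
    cb_seq <- barcodes[rd_cell]
    tag_seq <- cfg$taglist$tag_seq[rd_tag]
    qual_r1 <- strrep("F", 16L + 12L)
    r1_qual <- rep(qual_r1, nread)
    # single-base tag errors (always within distance 1 of the true tag)
    mut1 <- which(etype == "tag1")
    if (length(mut1))
      tag_seq[mut1] <- substitute_bases(tag_seq[mut1], 1L)
    mut2 <- which(etype == "tag2")
    if (length(mut2)) {
      tag_seq[mut2] <- substitute_bases(tag_seq[mut2], 2L)
      # guard: a 2-error tag must never land within distance 1 of any tag
      # (cannot occur when tags are spaced >= 4 apart, but enforced anyway)
      min_dist_to_tags <- function(ss) {
        ch <- do.call(rbind, strsplit(ss, "", fixed = TRUE))
        mins <- rep(Inf, length(ss))
        for (t in cfg$taglist$tag_seq) {
          tc <- strsplit(t, "", fixed = TRUE)[[1]]
          mins <- pmin(mins, colSums(t(ch) != tc))
        }
        mins
      }
      repeat {
        viol <- which(min_dist_to_tags(tag_seq[mut2]) <= 1L)
        if (!length(viol)) break
        tag_seq[mut2[viol]] <-
          substitute_bases(cfg$taglist$tag_seq[rd_tag[mut2[viol]]], 2L)
      }
    }
    lowq <- which(etype == "cb_lowq")
    if (length(lowq)) {
      pos <- sample.int(16L, length(lowq), replace = TRUE)
      cb_seq[lowq] <- substitute_at(cb_seq[lowq], pos)
      # mark the mutated base as Q11 (< 20) so correction is eligible
      for (p in unique(pos)) {
        w <- which(pos == p)
        q <- r1_qual[lowq[w]]
        substr(q, p, p) <- ","
        r1_qual[lowq[w]] <- q
      }
    }
    highq <- which(etype == "cb_highq")
    if (length(highq)) {
      pos <- sample.int(16L, length(highq), replace = TRUE)
      cb_seq[highq] <- substitute_at(cb_seq[highq], pos)  # quality stays Q37
    }
    ord <- sample.int(nread)
    ids <- sprintf("read%08d", seq_len(nread))
    pairs <- tibble::tibble(
      read_id = ids,
      r1_seq = paste0(cb_seq, rd_umi)[ord],
      r1_qual = r1_qual[ord],
      r2_seq = tag_seq[ord],
      r2_qual = rep(strrep("F", nchar(tag_seq[1])), nread))
    ext <- if (compress) ".fastq.gz" else ".fastq"
    r1 <- file.path(out_dir, paste0(well_id, "_R1", ext))
    r2 <- file.path(out_dir, paste0(well_id, "_R2", ext))
    write_paired_fastq(pairs, r1, r2)
    wl_path <- file.path(out_dir, paste0(well_id, "_barcodes.tsv"))
    writeLines(barcodes, wl_path)
    truth_umis <- tibble::tibble(
      cell_barcode = barcodes[umi_cell],
      tag_name = cfg$taglist$tag_name[umi_tag],
      umi = umi_seq)
    truth_reads <- tibble::tibble(
      read_id = ids,
      cell_barcode = barcodes[rd_cell[ord]],
      tag_name = cfg$taglist$tag_name[rd_tag[ord]],
      umi = rd_umi[ord],
      error_type = etype[ord])
    list(r1 = r1, r2 = r2, whitelist = wl_path, taglist = cfg$taglist,
         truth_cells = truth, true_counts = m,
         truth_umis = truth_umis, truth_reads = truth_reads)
  })
}

# substitute k (1 or 2) random distinct positions of each sequence
substitute_bases <- function(seqs, k) {
  len <- nchar(seqs[1])
  n <- length(seqs)
  p1 <- sample.int(len, n, replace = TRUE)
  seqs <- substitute_at(seqs, p1)
  if (k >= 2L) {
    p2 <- ((p1 - 1L + sample.int(len - 1L, n, replace = TRUE)) %% len) + 1L
    seqs <- substitute_at(seqs, p2)
  }
  seqs
}

# substitute position pos[i] of seqs[i] with a random different base
substitute_at <- function(seqs, pos) {
  cur_i <- match(substr(seqs, pos, pos), DNA_BASES)
  cur_i[is.na(cur_i)] <- sample.int(4L, sum(is.na(cur_i)), replace = TRUE)
  alt <- DNA_BASES[((cur_i - 1L + sample.int(3L, length(seqs), replace = TRUE)) %% 4L) + 1L]
  for (p in unique(pos)) {
    w <- which(pos == p)
    s <- seqs[w]
    substr(s, p, p) <- alt[w]
    seqs[w] <- s
  }
  seqs
}

#' Simulate a sparse expression matrix for a well
#'
#' Per-cell RNA depth is log-normal; counts are distributed over a fixed
#' gene-abundance profile (so per-cell totals match the recorded truth
#' exactly).
#'
#' @param config A [sim_config()].
#' @param truth_cells Truth tibble from a prior simulate call (its barcodes
#'   define the columns).
#' @param path Optional HDF5 output path.
#' @param rng_seed Seed; defaults to `config$rng_seed + 101`.
#' @return List: `well` (a [well_matrix()]), `truth_rna` (tibble of per-cell
#'   true totals), and `path` if written.
#' @export
simulate_expression_well <- function(config, truth_cells, path = NULL,
                                     rng_seed = config$rng_seed + 101L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth_cells)
  g <- config$n_genes
  withr::with_seed(rng_seed, {
    depth <- pmax(1L, round(rlnorm(n, config$rna_depth_meanlog,
                                   config$rna_depth_sdlog)))
    abundance <- rlnorm(g, 0, 1.5)
    prob <- abundance / sum(abundance)
    counts <- vapply(seq_len(n), function(i)
      as.integer(stats::rmultinom(1L, depth[i], prob)), integer(g))
    m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    features <- tibble::tibble(id = sprintf("GENE%04d", seq_len(g)),
                               name = sprintf("Gene-%04d", seq_len(g)),
                               feature_type = rep("Gene Expression", g))
    well <- well_matrix(m, features, truth_cells$cell_barcode)
    if (!is.null(path)) write_10x_h5(well, path)
    list(well = well,
         truth_rna = tibble::tibble(cell_barcode = truth_cells$cell_barcode,
                                    true_rna_umis = as.integer(depth)),
         path = path)
  })
}
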