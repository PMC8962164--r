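# Shared fixtures and independent brute-force oracles.

# a tiny taglist with controlled spacing
tiny_taglist <- function() {
  taglist(c("HT1", "HT2", "HT3"),
          c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGG"))
}

# write a FASTQ file from raw record fields (independent of ShortRead)
write_raw_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, path)
  path
}

# brute-force HTO counter: per-read loops, linear scans and plain R
# environments as sets; no tries, no vectorized matching
oracle_count_well <- function(pairs, whitelist, taglist, layout = read_layout(),
                              dedup_scope = "barcode_tag") {
  wl <- as.character(whitelist)
  tags <- taglist$tag_seq
  seen_bc <- character(0)
  umi_seen <- new.env(parent = emptyenv())
  umi_counts <- list()
  read_counts <- list()
  totals <- list()
  bump <- function(lst, key, tag) {
    if (is.null(lst[[key]])) lst[[key]] <- integer(length(tags))
    lst[[key]][tag] <- lst[[key]][tag] + 1L
    lst
  }
  for (i in seq_len(nrow(pairs))) {
    r1 <- pairs$r1_seq[i]; r2 <- pairs$r2_seq[i]
    if (nchar(r1) < layout$cb_len + layout$umi_len ||
        nchar(r2) < layout$tag_len) next
    cb <- substr(r1, 1, layout$cb_len)
    umi <- substr(r1, layout$cb_len + 1, layout$cb_len + layout$umi_len)
    tg <- substr(r2, 1, layout$tag_len)
    # barcode: exact, else one low-quality substitution with a unique hit
    hit <- NA_character_
    if (any(wl == cb)) {
      hit <- cb
    } else {
      q <- as.integer(charToRaw(substr(pairs$r1_qual[i], 1, layout$cb_len))) - 33L
      cands <- character(0)
      for (p in which(q < layout$qual_threshold)) {
        for (b in setdiff(c("A", "C", "G", "T"), substr(cb, p, p))) {
          v <- cb
          substr(v, p, p) <- b
          if (any(wl == v)) cands <- c(cands, v)
        }
      }
      cands <- unique(cands)
      if (length(cands) == 1L) hit <- cands
    }
    if (is.na(hit)) next
    totals[[hit]] <- (if (is.null(totals[[hit]])) 0L else totals[[hit]]) + 1L
    # tag: unique tag within Hamming distance 1
    dists <- vapply(tags, function(t)
      sum(strsplit(t, "")[[1]] != strsplit(tg, "")[[1]]), integer(1))
    w <- which(dists <= 1L)
    if (length(w) != 1L) next
    read_counts <- bump(read_counts, hit, w)
    key <- if (dedup_scope == "barcode_tag") paste(hit, w, umi) else paste(hit, umi)
    if (is.null(umi_seen[[key]])) {
      umi_seen[[key]] <- TRUE
      umi_counts <- bump(umi_counts, hit, w)
    }
  }
  bcs <- sort(names(totals))
  um <- matrix(0L, length(bcs), length(tags),
               dimnames = list(bcs, taglist$tag_name))
  rm_ <- um
  for (b in bcs) {
    if (!is.null(umi_counts[[b]])) um[b, ] <- umi_counts[[b]]
    if (!is.null(read_counts[[b]])) rm_[b, ] <- read_counts[[b]]
  }
  list(umi = um, reads = rm_,
       total_reads = vapply(bcs, function(b) totals[[b]], integer(1)))
}

# exhaustive sorted-split 2-means oracle: recompute each split's cost naively
oracle_two_means <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  for (k in seq_len(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    cost <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (is.null(best) || cost < best$cost - 1e-12 ||
        abs(cost - best$cost) <= 1e-12) {
      best <- list(cost = cost, split = k, lower = mean(a), upper = mean(b))
    }
  }
  best
}

default_layout <- read_layout()
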