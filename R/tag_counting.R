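# The counting core: parse read pairs, match cell barcodes with
# quality-aware single-mismatch correction, match hashtags with one-mismatch
# tolerance, deduplicate UMIs, and tabulate counts.

#' Parse a read pair into barcode, UMI and tag segments
#'
#' Slices read 1 into cell barcode and UMI and takes the hashtag from the
#' start of read 2. Pairs whose reads are shorter than the layout requires
#' are skipped (`NA` segments), never an error; [count_well()] tallies them.
#' Longer reads (e.g. full-length R1 from permissive base masks) are simply
#' truncated to the layout.
#'
#' @param pairs Tibble of read pairs (see [read_paired_fastq()]).
#' @param layout A [read_layout()].
#' @return The input tibble with added columns `cb`, `cb_qual`, `umi`,
#'   `tag_seq` (`NA` for short pairs) and `too_short`.
#' @export
parse_read <- function(pairs, layout = read_layout()) {
  need1 <- layout$cb_len + layout$umi_len
  too_short <- nchar(pairs$r1_seq) < need1 | nchar(pairs$r2_seq) < layout$tag_len
  cb <- ifelse(too_short, NA_character_, substr(pairs$r1_seq, 1L, layout$cb_len))
  cbq <- ifelse(too_short, NA_character_, substr(pairs$r1_qual, 1L, layout$cb_len))
  umi <- ifelse(too_short, NA_character_,
                substr(pairs$r1_seq, layout$cb_len + 1L, need1))
  tag <- ifelse(too_short, NA_character_, substr(pairs$r2_seq, 1L, layout$tag_len))
  dplyr::mutate(pairs, cb = cb, cb_qual = cbq, umi = umi, tag_seq = tag,
                too_short = too_short)
}

# Pack equal-length sequences over {A,C,G,T,N} into exact doubles, base 5.
# 5^12 * n_keys stays far below 2^53 for any realistic whitelist.
encode_seq5 <- function(seqs, len) {
  if (!length(seqs)) return(numeric(0))
  lut <- rep(4, 256)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  m <- matrix(lut[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L],
              nrow = len)
  as.vector(5^(seq_len(len) - 1) %*% m)
}

# Vectorized barcode matching with quality-aware correction.
# Returns a list: matched (chr, NA if unmatched), status
# ("exact", "corrected", "invalid", "ambiguous").
match_cb_vec <- function(cb, cb_qual, whitelist, qual_threshold) {
  match_cb_vec_lazy(cb, function(i) cb_qual[i], whitelist, qual_threshold)
}

# as match_cb_vec, but quality strings are fetched lazily (only for reads
# that fail the exact lookup) via qual_fun(indices)
match_cb_vec_lazy <- function(cb, qual_fun, whitelist, qual_threshold) {
  status <- rep("invalid", length(cb))
  matched <- rep(NA_character_, length(cb))
  hit <- !is.na(match(cb, whitelist))
  matched[hit] <- cb[hit]
  status[hit] <- "exact"
  todo <- which(!hit)
  if (length(todo)) {
    # Phred scores for all failed reads at once (fixed-width quality strings)
    qs <- qual_fun(todo)
    cb_len <- nchar(cb[1])
    qmat <- matrix(as.integer(charToRaw(paste(qs, collapse = ""))) - 33L,
                   nrow = cb_len)
    low <- qmat < qual_threshold
    nlow <- colSums(low)
    keep <- which(nlow > 0L)
    if (length(keep)) {
      # one row per (read, low-quality position)
      reads2 <- rep(todo[keep], nlow[keep])
      lw <- low[, keep, drop = FALSE]
      poss <- ((which(lw) - 1L) %% cb_len) + 1L   # column-major: row indices
      s <- cb[reads2]
      curi <- match(substr(s, poss, poss), DNA_BASES)
      n_base <- is.na(curi)           # N (or other): try all four bases
      curi[n_base] <- 4L
      offs <- if (any(n_base)) 0:3 else 1:3
      idx <- integer(0); var <- character(0)
      pieces_i <- vector("list", length(offs))
      pieces_v <- vector("list", length(offs))
      for (j in seq_along(offs)) {
        o <- offs[j]
        sel <- if (o == 0L) which(n_base) else seq_along(s)
        if (!length(sel)) { pieces_i[[j]] <- integer(0); pieces_v[[j]] <- character(0); next }
        alt <- DNA_BASES[((curi[sel] - 1L + o) %% 4L) + 1L]
        v <- s[sel]
        substr(v, poss[sel], poss[sel]) <- alt
        same <- v == s[sel]           # N rows: offset may reproduce base 4 ("T")? never equals "N"
        pieces_i[[j]] <- reads2[sel][!same]
        pieces_v[[j]] <- v[!same]
      }
      idx <- unlist(pieces_i, use.names = FALSE)
      var <- unlist(pieces_v, use.names = FALSE)
      vhit <- !is.na(match(var, whitelist))
      if (any(vhit)) {
        iv <- idx[vhit]; vv <- var[vhit]
        d <- duplicated(paste(iv, vv, sep = "\r"))
        iv <- iv[!d]; vv <- vv[!d]
        u <- unique(iv)
        cnt <- tabulate(match(iv, u), length(u))
        single <- u[cnt == 1L]
        matched[single] <- vv[match(single, iv)]
        status[single] <- "corrected"
        amb <- u[cnt > 1L]
        status[amb] <- "ambiguous"
      }
    }
  }
  list(matched = matched, status = status)
}

#' Match a cell barcode against a whitelist
#'
#' An exact whitelist member is returned unchanged (exact match wins
#' regardless of quality). Otherwise every position whose Phred score is
#' below `layout$qual_threshold` is considered: each alternative base is
#' substituted and looked up; if exactly one distinct whitelist barcode is
#' reachable it is returned, otherwise the barcode is unmatched (`NA`), with
#' status `"invalid"` (no candidate) or `"ambiguous"` (several candidates).
#' Mismatches at high-quality bases are never rescued. `N` bases count as
#' mismatches at their position, never as wildcards.
#'
#' @param cb Cell barcode sequence (single string).
#' @param cb_qual Quality string (Sanger encoding) or integer Phred vector.
#' @param whitelist A `barcode_whitelist`, plain character vector, or
#'   [sequence_trie()].
#' @param layout A [read_layout()].
#' @return The matched whitelist barcode, or `NA` with attribute `status`.
#' @export
match_cell_barcode <- function(cb, cb_qual, whitelist, layout = read_layout()) {
  if (inherits(whitelist, "sequence_trie")) {
    lookup <- function(s) trie_contains(whitelist, s)
  } else {
    lookup <- function(s) !is.na(match(s, whitelist))
  }
  if (nchar(cb) != layout$cb_len)
    stop("barcode length does not match layout", call. = FALSE)
  if (is.character(cb_qual)) cb_qual <- phred_scores(cb_qual)
  if (lookup(cb))
    return(structure(cb, status = "exact"))
  cand <- character(0)
  for (p in which(cb_qual < layout$qual_threshold)) {
    cur <- substr(cb, p, p)
    for (b in setdiff(DNA_BASES, cur)) {
      v <- cb
      substr(v, p, p) <- b
      if (lookup(v)) cand <- c(cand, v)
    }
  }
  cand <- unique(cand)
  if (length(cand) == 1L) return(structure(cand, status = "corrected"))
  structure(NA_character_,
            status = if (length(cand)) "ambiguous" else "invalid")
}

# Vectorized hashtag matching: exact hash lookup, then a distance-1 scan
# over the (small) taglist. Returns list(index, status).
match_tag_vec <- function(tag_seq, tags) {
  idx <- match(tag_seq, tags)
  status <- rep("exact", length(idx))
  status[is.na(idx)] <- "invalid"
  todo <- which(is.na(idx))
  if (length(todo)) {
    tag_len <- nchar(tags[1])
    qmat <- matrix(charToRaw(paste(tag_seq[todo], collapse = "")),
                   nrow = tag_len)
    n_hit1 <- integer(length(todo))
    hit1 <- integer(length(todo))
    for (t in seq_along(tags)) {
      tc <- charToRaw(tags[t])
      d <- colSums(qmat != tc)
      w <- d <= 1L
      n_hit1 <- n_hit1 + w
      hit1[w] <- t
    }
    one <- n_hit1 == 1L
    idx[todo[one]] <- hit1[one]
    status[todo[one]] <- "mismatch1"
    status[todo[n_hit1 > 1L]] <- "ambiguous"
  }
  list(index = idx, status = status)
}

#' Match a hashtag sequence against a taglist
#'
#' Returns the unique tag within Hamming distance 1 of the query, or `NA`.
#' Two or more tags within distance 1 (possible only when the taglist
#' violates the distance-3 spacing) yield `NA` with status `"ambiguous"`.
#'
#' @param tag_seq Hashtag sequence(s) observed on read 2.
#' @param taglist A [taglist()].
#' @return Integer index into the taglist (NA if unmatched), with attribute
#'   `status`.
#' @export
match_hashtag <- function(tag_seq, taglist) {
  stopifnot(inherits(taglist, "hash_taglist"))
  bad <- nchar(tag_seq) != attr(taglist, "tag_len")
  if (any(bad))
    stop("tag sequence length does not match the taglist", call. = FALSE)
  res <- match_tag_vec(tag_seq, taglist$tag_seq)
  structure(res$index, status = res$status)
}

#' Count hashtag UMIs per cell barcode from paired FASTQ
#'
#' The counter core: streams read pairs, matches the cell barcode against
#' the whitelist (exact, then single low-quality-base correction), matches
#' the hashtag with one-mismatch tolerance, and counts each first-seen UMI
#' once. No UMI sequence-error correction is performed: hashtag barcodes are
#' spaced at Hamming distance >= 3, so error correction at the UMI level is
#' unnecessary for hashing applications.
#'
#' Deduplication scope `"barcode_tag"` (default) counts a UMI once per
#' (cell barcode, tag) pair; `"barcode"` counts a UMI once per cell barcode,
#' crediting the tag of its first occurrence.
#'
#' @param path_r1,path_r2 Paired FASTQ paths (plain or gzip).
#' @param whitelist A `barcode_whitelist` (or character vector of barcodes).
#' @param taglist A [taglist()].
#' @param layout A [read_layout()].
#' @param dedup_scope `"barcode_tag"` or `"barcode"`.
#' @param chunk_size FASTQ records per streamed chunk.
#' @return An [hto_counts()] with UMI counts, read counts, per-barcode read
#'   totals and run metrics: `total_read_pairs`, `pairs_dropped_short`,
#'   `pairs_valid_barcode`, `pairs_barcode_invalid`,
#'   `pairs_barcode_ambiguous`, `pairs_valid_tag` (= `pairs_counted`),
#'   `pairs_tag_invalid`, `pairs_tag_ambiguous`, `pairs_dropped_ambiguous`,
#'   `pairs_counted`. These tallies partition the input:
#'   `total = counted + short + barcode_invalid + barcode_ambiguous +
#'   tag_invalid + tag_ambiguous`.
#' @export
count_well <- function(path_r1, path_r2, whitelist, taglist,
                       layout = read_layout(),
                       dedup_scope = c("barcode_tag", "barcode"),
                       chunk_size = 1e5) {
  dedup_scope <- match.arg(dedup_scope)
  stopifnot(inherits(taglist, "hash_taglist"))
  wl <- as.character(whitelist)
  if (!length(wl)) stop("whitelist is empty", call. = FALSE)
  if (!nrow(taglist)) stop("taglist is empty", call. = FALSE)
  for (p in c(path_r1, path_r2))
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
  tags <- taglist$tag_seq
  ntag <- length(tags)
  need1 <- layout$cb_len + layout$umi_len
  met <- c(total_read_pairs = 0, pairs_dropped_short = 0,
           pairs_valid_barcode = 0, pairs_barcode_invalid = 0,
           pairs_barcode_ambiguous = 0, pairs_valid_tag = 0,
           pairs_tag_invalid = 0, pairs_tag_ambiguous = 0)
  cb_idx_all <- list(); tag_idx_all <- list(); umi_all <- list()
  valid_cb_idx_all <- list()
  s1 <- ShortRead::FastqStreamer(path_r1, n = chunk_size)
  s2 <- ShortRead::FastqStreamer(path_r2, n = chunk_size)
  on.exit({close(s1); close(s2)}, add = TRUE)
  n_seen <- 0L
  repeat {
    c1 <- ShortRead::yield(s1)
    c2 <- ShortRead::yield(s2)
    n1 <- length(c1); n2 <- length(c2)
    if (n1 != n2)
      stop(sprintf(
        "R1/R2 record counts diverge after record %d (chunk of %d vs %d)",
        n_seen + min(n1, n2), n1, n2), call. = FALSE)
    if (n1 == 0L) break
    if (!all(ShortRead::id(c1) == ShortRead::id(c2))) {
      id1 <- read_id_token(as.character(ShortRead::id(c1)))
      id2 <- read_id_token(as.character(ShortRead::id(c2)))
      mism <- which(id1 != id2)
      if (length(mism))
        stop(sprintf("R1/R2 read ids differ at record %d: '%s' vs '%s'",
                     n_seen + mism[1], id1[mism[1]], id2[mism[1]]),
             call. = FALSE)
    }
    n_seen <- n_seen + n1
    met["total_read_pairs"] <- met["total_read_pairs"] + n1
    short <- Biostrings::width(c1) < need1 | Biostrings::width(c2) < layout$tag_len
    met["pairs_dropped_short"] <- met["pairs_dropped_short"] + sum(short)
    keep <- which(!short)
    if (!length(keep)) next
    r1 <- as.character(Biostrings::subseq(ShortRead::sread(c1)[keep], 1L, need1))
    cb <- substr(r1, 1L, layout$cb_len)
    umi <- substr(r1, layout$cb_len + 1L, need1)
    tagseq <- as.character(Biostrings::subseq(ShortRead::sread(c2)[keep],
                                              1L, layout$tag_len))
    qual_fun <- function(i) {
      # quality strings for a subset of kept reads, fetched lazily
      as.character(Biostrings::subseq(
        Biostrings::quality(Biostrings::quality(c1))[keep][i],
        1L, layout$cb_len))
    }
    cbres <- match_cb_vec_lazy(cb, qual_fun, wl, layout$qual_threshold)
    met["pairs_barcode_invalid"] <- met["pairs_barcode_invalid"] +
      sum(cbres$status == "invalid")
    met["pairs_barcode_ambiguous"] <- met["pairs_barcode_ambiguous"] +
      sum(cbres$status == "ambiguous")
    ok <- !is.na(cbres$matched)
    met["pairs_valid_barcode"] <- met["pairs_valid_barcode"] + sum(ok)
    if (!any(ok)) next
    cbm <- cbres$matched[ok]
    tagres <- match_tag_vec(tagseq[ok], tags)
    met["pairs_tag_invalid"] <- met["pairs_tag_invalid"] +
      sum(tagres$status == "invalid")
    met["pairs_tag_ambiguous"] <- met["pairs_tag_ambiguous"] +
      sum(tagres$status == "ambiguous")
    tok <- !is.na(tagres$index)
    met["pairs_valid_tag"] <- met["pairs_valid_tag"] + sum(tok)
    valid_cb_idx_all[[length(valid_cb_idx_all) + 1L]] <- match(cbm, wl)
    if (!any(tok)) next
    k <- length(cb_idx_all) + 1L
    cb_idx_all[[k]] <- match(cbm[tok], wl)
    tag_idx_all[[k]] <- tagres$index[tok]
    umi_all[[k]] <- umi[ok][tok]
  }
  cb_idx <- unlist(cb_idx_all, use.names = FALSE)
  tag_idx <- unlist(tag_idx_all, use.names = FALSE)
  umis <- unlist(umi_all, use.names = FALSE)
  valid_cb <- unlist(valid_cb_idx_all, use.names = FALSE)
  seen <- sort(unique(valid_cb))
  if (!length(seen)) seen <- integer(0)
  bc <- wl[seen]
  nb <- length(bc)
  umi_m <- matrix(0L, nb, ntag, dimnames = list(bc, taglist$tag_name))
  read_m <- umi_m
  total_reads <- integer(nb)
  if (length(valid_cb))
    total_reads <- as.integer(tabulate(match(valid_cb, seen), nb))
  if (length(cb_idx)) {
    row <- match(cb_idx, seen)
    cell <- (tag_idx - 1L) * nb + row
    read_m[] <- tabulate(cell, nb * ntag)
    # dedup keys: UMIs pack exactly into doubles (5 symbols per base, well
    # inside the 2^53 integer range together with the barcode/tag index)
    ucode <- encode_seq5(umis, layout$umi_len)
    base <- 5^layout$umi_len
    key <- if (dedup_scope == "barcode_tag") {
      ((cb_idx - 1) * ntag + tag_idx) * base + ucode
    } else {
      cb_idx * base + ucode
    }
    first <- !duplicated(key)
    umi_m[] <- tabulate(cell[first], nb * ntag)
  }
  met["pairs_counted"] <- met[["pairs_valid_tag"]]
  met["pairs_dropped_ambiguous"] <- met[["pairs_barcode_ambiguous"]] +
    met[["pairs_tag_ambiguous"]]
  hto_counts(umi_m, reads = read_m, total_reads = total_reads,
             metrics = as.list(met))
}
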