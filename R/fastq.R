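# Paired FASTQ input. ShortRead does the parsing; this layer enforces pair
# synchronization and presents read pairs as tibbles (or a chunked stream).

# strip a read id to its comparable token: first whitespace-delimited word,
# without a trailing /1 or /2 mate marker
read_id_token <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Stream synchronized read pairs from two FASTQ files
#'
#' Returns a closure that yields successive chunks of read pairs as tibbles
#' with columns `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual` (quality
#' as Sanger-encoded strings), and `NULL` when both files are exhausted.
#' Record identifiers and record counts are checked for synchronization.
#'
#' @param path_r1,path_r2 FASTQ paths (plain or gzip).
#' @param chunk_size Records per chunk (default 1e6).
#' @return A function yielding tibbles then `NULL`.
#' @export
fastq_pair_stream <- function(path_r1, path_r2, chunk_size = 1e6) {
  for (p in c(path_r1, path_r2))
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
  s1 <- ShortRead::FastqStreamer(path_r1, n = chunk_size)
  s2 <- ShortRead::FastqStreamer(path_r2, n = chunk_size)
  done <- FALSE
  n_seen <- 0L
  function() {
    if (done) return(NULL)
    c1 <- ShortRead::yield(s1)
    c2 <- ShortRead::yield(s2)
    n1 <- length(c1); n2 <- length(c2)
    if (n1 != n2) {
      close(s1); close(s2); done <<- TRUE
      stop(sprintf(
        "R1/R2 record counts diverge after record %d (chunk of %d vs %d)",
        n_seen + min(n1, n2), n1, n2), call. = FALSE)
    }
    if (n1 == 0L) {
      close(s1); close(s2); done <<- TRUE
      return(NULL)
    }
    id1 <- read_id_token(as.character(ShortRead::id(c1)))
    id2 <- read_id_token(as.character(ShortRead::id(c2)))
    mism <- which(id1 != id2)
    if (length(mism)) {
      close(s1); close(s2); done <<- TRUE
      stop(sprintf("R1/R2 read ids differ at record %d: '%s' vs '%s'",
                   n_seen + mism[1], id1[mism[1]], id2[mism[1]]), call. = FALSE)
    }
    n_seen <<- n_seen + n1
    tibble::tibble(
      read_id = id1,
      r1_seq = as.character(ShortRead::sread(c1)),
      r1_qual = as.character(Biostrings::quality(Biostrings::quality(c1))),
      r2_seq = as.character(ShortRead::sread(c2)),
      r2_qual = as.character(Biostrings::quality(Biostrings::quality(c2))))
  }
}

#' Read all synchronized pairs from two FASTQ files
#'
#' Materializes [fastq_pair_stream()] into one tibble. Suitable for
#' fixture-sized inputs; [count_well()] streams instead.
#'
#' @inheritParams fastq_pair_stream
#' @return A tibble of read pairs.
#' @export
read_paired_fastq <- function(path_r1, path_r2, chunk_size = 1e6) {
  st <- fastq_pair_stream(path_r1, path_r2, chunk_size)
  out <- list()
  while (!is.null(chunk <- st())) out[[length(out) + 1L]] <- chunk
  if (!length(out)) {
    return(tibble::tibble(read_id = character(), r1_seq = character(),
                          r1_qual = character(), r2_seq = character(),
                          r2_qual = character()))
  }
  dplyr::bind_rows(out)
}

#' Write read pairs to a pair of FASTQ files
#'
#' @param pairs Tibble as returned by [read_paired_fastq()].
#' @param path_r1,path_r2 Output paths; `.gz` suffix triggers compression.
#' @return Invisibly, the two paths.
#' @export
write_paired_fastq <- function(pairs, path_r1, path_r2) {
  w <- function(seqs, quals, ids, path) {
    sr <- ShortRead::ShortReadQ(
      sread = Biostrings::DNAStringSet(seqs),
      quality = ShortRead::FastqQuality(quals),
      id = Biostrings::BStringSet(ids))
    ShortRead::writeFastq(sr, path, mode = "w",
                          compress = grepl("\\.gz$", path))
  }
  w(pairs$r1_seq, pairs$r1_qual, pairs$read_id, path_r1)
  w(pairs$r2_seq, pairs$r2_qual, pairs$read_id, path_r2)
  invisible(c(path_r1, path_r2))
}
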