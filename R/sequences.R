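# Sequence utilities: Hamming distances, read layout, and a DNA prefix tree.

DNA_BASES <- c("A", "C", "G", "T")

#' Read layout of a hashing library
#'
#' Describes where the cell barcode, UMI and hashtag sit in a read pair of a
#' 10x 3' Cell Hashing library: read 1 carries the cell barcode followed by
#' the UMI, read 2 starts with the hashtag sequence.
#'
#' @param cb_len Cell barcode length in bases (default 16, 10x v3 chemistry).
#' @param umi_len UMI length in bases (default 12, 10x v3 chemistry).
#' @param tag_len Hashtag length in bases (default 15, TotalSeq-A).
#' @param qual_threshold Phred score below which a barcode base is considered
#'   low quality and eligible for mismatch correction (default 20).
#' @return A `read_layout` object (a named list).
#' @export
read_layout <- function(cb_len = 16L, umi_len = 12L, tag_len = 15L,
                        qual_threshold = 20L) {
  cb_len <- as.integer(cb_len); umi_len <- as.integer(umi_len)
  tag_len <- as.integer(tag_len); qual_threshold <- as.integer(qual_threshold)
  if (any(c(cb_len, umi_len, tag_len) <= 0L))
    stop("all read layout lengths must be positive", call. = FALSE)
  structure(list(cb_len = cb_len, umi_len = umi_len, tag_len = tag_len,
                 qual_threshold = qual_threshold),
            class = "read_layout")
}

#' Pairwise Hamming distances between equal-length sequences
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Integer matrix of pairwise Hamming distances.
#' @export
hamming_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  out <- matrix(0L, n, n, dimnames = list(seqs, seqs))
  for (i in seq_len(n)) {
    if (i < n) {
      d <- colSums(t(chars[(i + 1):n, , drop = FALSE]) != chars[i, ])
      out[i, (i + 1):n] <- d
      out[(i + 1):n, i] <- d
    }
  }
  out
}

# Hamming distance from one sequence to each of several (equal length)
hamming_to <- function(seq, seqs) {
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  as.integer(colSums(t(chars) != a))
}

#' DNA prefix tree (trie)
#'
#' A trie over the alphabet A, C, G, T, N storing fixed-length sequences with
#' optional integer payloads. Membership lookup walks one node per base, so
#' cost is bounded by sequence length and independent of the number of stored
#' sequences. The bulk counting path uses R's hashed lookup over the same key
#' set; the trie backs the single-sequence matching operations and mirrors
#' the data structure used by compiled hashing counters.
#'
#' @param sequences Character vector of sequences to insert.
#' @param payloads Optional integer payloads, one per sequence.
#' @return A `sequence_trie` object.
#' @export
sequence_trie <- function(sequences = character(), payloads = NULL) {
  root <- new.env(parent = emptyenv(), size = 5L)
  meta <- new.env(parent = emptyenv())
  meta$n <- 0L
  trie <- structure(list(root = root, meta = meta), class = "sequence_trie")
  if (length(sequences))
    trie <- trie_insert(trie, sequences, payloads)
  trie
}

#' Number of sequences stored in a trie
#'
#' @param trie A [sequence_trie()].
#' @return Integer count of stored (terminal) sequences.
#' @export
trie_size <- function(trie) {
  stopifnot(inherits(trie, "sequence_trie"))
  trie$meta$n
}

#' Insert sequences into a trie
#'
#' @param trie A [sequence_trie()].
#' @param sequences Sequences to insert.
#' @param payloads Optional integer payloads.
#' @return The trie (modified in place; returned for chaining).
#' @export
trie_insert <- function(trie, sequences, payloads = NULL) {
  stopifnot(inherits(trie, "sequence_trie"))
  if (is.null(payloads)) payloads <- rep(NA_integer_, length(sequences))
  added <- 0L
  for (k in seq_along(sequences)) {
    node <- trie$root
    for (ch in strsplit(sequences[[k]], "", fixed = TRUE)[[1]]) {
      nxt <- node[[ch]]
      if (is.null(nxt)) {
        nxt <- new.env(parent = emptyenv(), size = 5L)
        assign(ch, nxt, envir = node)
      }
      node <- nxt
    }
    if (is.null(node$.terminal)) added <- added + 1L
    node$.terminal <- TRUE
    node$.payload <- payloads[[k]]
  }
  trie$meta$n <- trie$meta$n + added
  trie
}

#' Test trie membership
#'
#' @param trie A [sequence_trie()].
#' @param sequences Character vector of query sequences.
#' @return Logical vector: is each sequence stored in the trie?
#' @export
trie_contains <- function(trie, sequences) {
  stopifnot(inherits(trie, "sequence_trie"))
  vapply(sequences, function(s) {
    node <- trie$root
    for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
      node <- node[[ch]]
      if (is.null(node)) return(FALSE)
    }
    isTRUE(node$.terminal)
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
print.sequence_trie <- function(x, ...) {
  cat("<sequence_trie> storing", trie_size(x), "sequences\n")
  invisible(x)
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("<read_layout> cb %d bp + umi %d bp (R1), tag %d bp (R2), Q<%d correctable\n",
              x$cb_len, x$umi_len, x$tag_len, x$qual_threshold))
  invisible(x)
}

# Phred scores (Sanger, offset 33) from a quality string, as integer vector
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}
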