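# Taglists (hashtag name -> sequence) and cell-barcode whitelists.

#' Construct a validated taglist
#'
#' A taglist maps hashtag names to their barcode sequences. Names and
#' sequences must be unique; commercially available hashtag barcodes are
#' spaced at Hamming distance >= 3 so that single-mismatch matching is
#' unambiguous, and a warning is raised when a taglist violates that spacing.
#'
#' @param tag_name Character vector of hashtag names.
#' @param tag_seq Character vector of hashtag sequences (uppercased on input).
#' @param tag_len Expected sequence length (default 15).
#' @return A `hash_taglist`: a tibble with columns `tag_name`, `tag_seq` and a
#'   `min_distance` attribute holding the minimum pairwise Hamming distance.
#' @export
taglist <- function(tag_name, tag_seq, tag_len = 15L) {
  tag_name <- as.character(tag_name)
  tag_seq <- toupper(as.character(tag_seq))
  if (length(tag_name) != length(tag_seq))
    stop("tag_name and tag_seq lengths differ", call. = FALSE)
  if (!length(tag_name)) stop("empty taglist", call. = FALSE)
  bad_len <- nchar(tag_seq) != tag_len
  if (any(bad_len))
    stop(sprintf("taglist sequence length != %d for: %s", tag_len,
                 paste(tag_name[bad_len], collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tag_name))
    stop("duplicate tag names in taglist", call. = FALSE)
  if (anyDuplicated(tag_seq))
    stop("duplicate tag sequences in taglist", call. = FALSE)
  if (any(!strsplit(paste(tag_seq, collapse = ""), "")[[1]] %in%
          c(DNA_BASES, "N")))
    stop("taglist sequences may contain only A/C/G/T/N", call. = FALSE)
  min_d <- if (length(tag_seq) > 1L) {
    dm <- hamming_matrix(tag_seq)
    min(dm[upper.tri(dm)])
  } else tag_len
  if (min_d < 3L)
    warning(sprintf(
      "minimum pairwise Hamming distance between hashtags is %d (< 3); single-mismatch tag matching may be ambiguous",
      min_d), call. = FALSE)
  out <- tibble::tibble(tag_name = tag_name, tag_seq = tag_seq)
  structure(out, min_distance = as.integer(min_d), tag_len = as.integer(tag_len),
            class = c("hash_taglist", class(out)))
}

#' Load a taglist from a delimited file
#'
#' Accepts comma- or tab-delimited text with a name column and a sequence
#' column; a header line is auto-detected (a row whose second field is not a
#' plausible DNA sequence is treated as a header).
#'
#' @param path Path to the taglist file.
#' @param tag_len Expected hashtag length (default 15).
#' @return A [taglist()].
#' @export
load_taglist <- function(path, tag_len = 15L) {
  if (!file.exists(path)) stop("taglist file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("taglist file is empty: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "\t"
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("taglist format error at line %d: expected 2 delimited fields",
                 which(bad)[1]), call. = FALSE)
  nm <- trimws(vapply(parts, `[[`, character(1), 1L))
  sq <- trimws(vapply(parts, `[[`, character(1), 2L))
  is_seq <- grepl("^[ACGTNacgtn]+$", sq[1]) && nchar(sq[1]) == tag_len
  if (!is_seq) { nm <- nm[-1]; sq <- sq[-1] }   # header row
  taglist(nm, sq, tag_len = tag_len)
}

#' Load a cell-barcode whitelist
#'
#' Reads a Cell Ranger style `barcodes.tsv` file (one barcode per line,
#' optionally gzip-compressed). A trailing GEM-well suffix such as `-1` is
#' stripped, since raw reads carry bare barcodes.
#'
#' @param path Path to the whitelist file.
#' @param cb_len Expected barcode length (default 16).
#' @return A sorted character vector of unique barcodes, class
#'   `barcode_whitelist`.
#' @export
load_barcode_whitelist <- function(path, cb_len = 16L) {
  if (!file.exists(path)) stop("whitelist file not found: ", path, call. = FALSE)
  bc <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, warn = FALSE)
  bc <- trimws(bc)
  bc <- bc[nzchar(bc)]
  bc <- sub("-\\d+$", "", bc)
  bc <- toupper(bc)
  if (!length(bc)) stop("whitelist is empty: ", path, call. = FALSE)
  bad <- nchar(bc) != cb_len
  if (any(bad))
    stop(sprintf("whitelist barcode length != %d at line %d", cb_len,
                 which(bad)[1]), call. = FALSE)
  bc <- sort(unique(bc))
  structure(bc, cb_len = as.integer(cb_len), class = "barcode_whitelist")
}

#' @export
print.hash_taglist <- function(x, ...) {
  cat(sprintf("<hash_taglist> %d tags, %d bp, min pairwise Hamming distance %d\n",
              nrow(x), attr(x, "tag_len"), attr(x, "min_distance")))
  NextMethod()
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("<barcode_whitelist> %d barcodes of %d bp\n",
              length(x), attr(x, "cb_len")))
  invisible(x)
}
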