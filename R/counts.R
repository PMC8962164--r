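# The HTO count matrix container and its CSV serialization.

#' Construct an HTO count object
#'
#' Holds deduplicated UMI counts (and, when produced by [count_well()], raw
#' read counts) per cell barcode and hashtag, plus run metrics. Barcodes are
#' kept in lexicographic order for deterministic output.
#'
#' @param umi Integer matrix, barcodes x tags, of deduplicated UMI counts.
#'   Row names are cell barcodes, column names tag names.
#' @param reads Optional integer matrix of read counts, same shape.
#' @param total_reads Optional integer vector: reads per barcode that matched
#'   the whitelist (including reads whose tag failed to match).
#' @param metrics Named list of run metrics.
#' @return An `hto_counts` object.
#' @export
hto_counts <- function(umi, reads = NULL, total_reads = NULL, metrics = list()) {
  stopifnot(is.matrix(umi), !is.null(colnames(umi)))
  rn <- rownames(umi)
  if (is.null(rn)) {
    if (nrow(umi) > 0L)
      stop("count matrix rows must be named by cell barcode", call. = FALSE)
    rn <- character(0)
  }
  ord <- order(rn, method = "radix")
  umi <- umi[ord, , drop = FALSE]
  storage.mode(umi) <- "integer"
  if (!is.null(reads)) {
    stopifnot(identical(dim(reads), dim(umi)))
    reads <- reads[ord, , drop = FALSE]
    storage.mode(reads) <- "integer"
    if (any(umi > reads))
      stop("UMI counts exceed read counts", call. = FALSE)
  }
  if (is.null(total_reads)) {
    total_reads <- if (!is.null(reads)) rowSums(reads) else rowSums(umi)
  } else {
    stopifnot(length(total_reads) == nrow(umi))
    total_reads <- total_reads[ord]
  }
  structure(list(cell_barcodes = rn[ord],
                 tag_names = colnames(umi),
                 umi = umi, reads = reads,
                 total_reads = as.integer(total_reads),
                 metrics = metrics),
            class = "hto_counts")
}

#' @export
print.hto_counts <- function(x, ...) {
  cat(sprintf("<hto_counts> %d cell barcodes x %d tags, %s UMIs total\n",
              nrow(x$umi), ncol(x$umi), format(sum(x$umi), big.mark = ",")))
  if (length(x$metrics))
    cat("  metrics:", paste(names(x$metrics), unlist(x$metrics), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an HTO count matrix into long form
#'
#' @param x An `hto_counts` object.
#' @param ... Unused.
#' @return A tibble with one row per (cell barcode, tag).
#' @export
tidy.hto_counts <- function(x, ...) {
  out <- tibble::tibble(
    cell_barcode = rep(x$cell_barcodes, times = length(x$tag_names)),
    tag_name = rep(x$tag_names, each = length(x$cell_barcodes)),
    umi_count = as.integer(x$umi))
  if (!is.null(x$reads)) out$read_count <- as.integer(x$reads)
  out
}

#' One-row summary of an HTO counting run
#'
#' @param x An `hto_counts` object.
#' @param ... Unused.
#' @return A one-row tibble of run metrics and dimensions.
#' @export
glance.hto_counts <- function(x, ...) {
  tibble::as_tibble(c(list(n_barcodes = nrow(x$umi), n_tags = ncol(x$umi),
                           total_umis = sum(x$umi)), x$metrics))
}

#' @export
as_tibble.hto_counts <- function(x, ...) {
  wide <- tibble::as_tibble(as.data.frame(x$umi))
  dplyr::bind_cols(tibble::tibble(cell_barcode = x$cell_barcodes,
                                  total_reads = x$total_reads), wide)
}

#' HTO count histograms per tag
#'
#' Log-scale histograms of per-barcode UMI counts for each hashtag, the
#' standard visual check of hashing signal bimodality. Zero counts are
#' dropped from the plot.
#'
#' @param object An `hto_counts` object.
#' @param bins Number of histogram bins (default 50).
#' @param ... Unused.
#' @return A ggplot object faceted by tag.
#' @export
autoplot.hto_counts <- function(object, bins = 50, ...) {
  df <- tidy(object)
  df <- df[df$umi_count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$umi_count)) +
    ggplot2::geom_histogram(bins = bins, fill = "seagreen") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~tag_name, scales = "free_y") +
    ggplot2::labs(x = "UMI count per cell barcode (log scale)", y = "barcodes")
}

#' Write HTO counts as CSV
#'
#' Fixed dialect: header `cell_barcode,total_reads,<tag...>`, one row per
#' barcode in lexicographic order, plain integers, no quoting, LF line
#' endings. Bit-identical output for identical input.
#'
#' @param counts An [hto_counts()] object (non-empty tag set).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "hto_counts"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("cell_barcode", "total_reads", counts$tag_names),
                  collapse = ",")
  body <- character(0)
  if (nrow(counts$umi)) {
    cols <- c(list(counts$cell_barcodes, counts$total_reads),
              lapply(seq_len(ncol(counts$umi)),
                     function(j) counts$umi[, j]))
    body <- do.call(paste, c(cols, sep = ","))
  }
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read HTO counts written by [write_counts_csv()]
#'
#' @param path CSV path.
#' @return An [hto_counts()] object (UMI counts and per-barcode read totals;
#'   per-tag read counts are not serialized in the CSV).
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  need <- c("cell_barcode", "total_reads")
  if (!all(need %in% names(df)))
    stop("counts CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  tag_cols <- setdiff(names(df), need)
  if (!length(tag_cols))
    stop("counts CSV contains no tag columns", call. = FALSE)
  umi <- as.matrix(df[tag_cols])
  rownames(umi) <- df$cell_barcode
  hto_counts(umi, total_reads = as.integer(df$total_reads))
}
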