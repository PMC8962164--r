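# Annotate per-well expression matrices with hash assignments and UUIDs,
# split wells into per-sample files, and merge samples across wells.

NON_SINGLET <- "non_singlet"

#' Build a sample sheet
#'
#' Maps each hashtag to the sample it labels. Each tag maps to exactly one
#' sample; a sample may be labeled by several tags only if explicitly
#' allowed (technical replicates are normally kept distinct).
#'
#' @param tag_name Character vector of hashtag names.
#' @param sample_name Character vector of sample names, same length.
#' @param allow_shared_samples Allow one sample name across several tags.
#' @return A `sample_sheet` tibble.
#' @export
sample_sheet <- function(tag_name, sample_name, allow_shared_samples = FALSE) {
  stopifnot(length(tag_name) == length(sample_name))
  if (anyDuplicated(tag_name))
    stop("each tag may appear once in the sample sheet", call. = FALSE)
  if (!allow_shared_samples && anyDuplicated(sample_name))
    stop("sample names repeat across tags; set allow_shared_samples = TRUE ",
         "if this is intended", call. = FALSE)
  out <- tibble::tibble(tag_name = as.character(tag_name),
                        sample_name = as.character(sample_name))
  structure(out, class = c("sample_sheet", class(out)))
}

#' Load a sample sheet CSV (columns `tag_name`, `sample_name`)
#'
#' @param path CSV path.
#' @param allow_shared_samples Passed to [sample_sheet()].
#' @return A `sample_sheet` tibble.
#' @export
load_sample_sheet <- function(path, allow_shared_samples = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("tag_name", "sample_name") %in% names(df)))
    stop("sample sheet needs columns tag_name, sample_name", call. = FALSE)
  sample_sheet(df$tag_name, df$sample_name, allow_shared_samples)
}

# deterministic v5 (name-based) UUIDs under a seed-derived namespace
seeded_uuids <- function(names, uuid_seed) {
  ns <- uuid::UUIDfromName("00000000-0000-0000-0000-000000000000",
                           paste0("hashdemux-", uuid_seed))
  vapply(names, function(nm) uuid::UUIDfromName(ns, nm), character(1),
         USE.NAMES = FALSE)
}

#' Annotate a well matrix with hash assignments and cell UUIDs
#'
#' Joins the classification onto the matrix columns and assigns every cell a
#' universally unique identifier so that cell barcodes never collide between
#' wells after merging. Matrix barcodes absent from the classification are
#' assigned `no_hash` (with a tally in the `n_unmatched_barcodes` attribute).
#'
#' @param well A [well_matrix()].
#' @param categories A `hash_categories` tibble for the same well.
#' @param well_id Well identifier recorded per cell.
#' @param sheet Optional [sample_sheet()]; adds a `sample_name` column for
#'   singlets.
#' @param uuid_seed Integer seed for reproducible UUIDs (name-based v5,
#'   derived from seed, well and barcode); `NULL` for random UUIDs.
#' @return The annotated `well_matrix`.
#' @export
annotate_well <- function(well, categories, well_id, sheet = NULL,
                          uuid_seed = NULL) {
  stopifnot(inherits(well, "well_matrix"),
            inherits(categories, "hash_categories"))
  if (anyDuplicated(well$cell_barcodes))
    stop("duplicate cell barcodes within one well", call. = FALSE)
  idx <- match(well$cell_barcodes, categories$cell_barcode)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched)
    warning(sprintf("%d matrix barcodes missing from the classification; assigned no_hash",
                    n_unmatched), call. = FALSE)
  category <- as.character(categories$category)[idx]
  category[is.na(category)] <- "no_hash"
  assigned <- categories$assigned_tags[idx]
  assigned[is.na(assigned)] <- ""
  md <- well$cell_metadata
  md$well_id <- rep(as.character(well_id), length(well$cell_barcodes))
  md$hash_category <- category
  md$tag_name <- assigned
  if (!is.null(sheet)) {
    md$sample_name <- ifelse(
      category == "singlet",
      sheet$sample_name[match(assigned, sheet$tag_name)],
      NA_character_)
  }
  md$cell_uuid <- if (is.null(uuid_seed)) {
    uuid::UUIDgenerate(n = length(well$cell_barcodes))
  } else {
    seeded_uuids(paste(well_id, well$cell_barcodes, sep = ":"), uuid_seed)
  }
  out <- well_matrix(well$matrix, well$features, well$cell_barcodes, md)
  attr(out, "n_unmatched_barcodes") <- n_unmatched
  out
}

subset_well <- function(well, cols) {
  well_matrix(well$matrix[, cols, drop = FALSE], well$features,
              well$cell_barcodes[cols],
              well$cell_metadata[cols, , drop = FALSE])
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Split an annotated well into per-sample HDF5 files
#'
#' Singlet cells are routed to one file per sample; doublet, multiplet and
#' no-hash cells all go to a single non-singlet file, labeled by category in
#' their metadata, so that every input cell is accounted for. Counts are
#' preserved exactly (column subsets).
#'
#' @param well An [annotate_well()]-annotated `well_matrix` (needs
#'   `hash_category`, `tag_name`, `cell_uuid`, `well_id` metadata).
#' @param sheet A [sample_sheet()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list: `files` (named HDF5 paths), `report` (cell and
#'   count tallies per output, also written as
#'   `<well>_split_metrics.json`).
#' @export
split_by_hash <- function(well, sheet, out_dir) {
  stopifnot(inherits(well, "well_matrix"))
  md <- well$cell_metadata
  need <- c("well_id", "hash_category", "tag_name", "cell_uuid")
  if (!all(need %in% names(md)))
    stop("well is not annotated; run annotate_well() first", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  well_id <- md$well_id[1]
  singlet <- md$hash_category == "singlet"
  tags <- md$tag_name[singlet]
  missing_tags <- setdiff(unique(tags), sheet$tag_name)
  if (length(missing_tags))
    stop("tags absent from the sample sheet: ",
         paste(missing_tags, collapse = ", "), call. = FALSE)
  sample_of <- sheet$sample_name[match(md$tag_name, sheet$tag_name)]
  dest <- ifelse(singlet, sample_of, NON_SINGLET)
  files <- list()
  outputs <- list()
  for (d in unique(dest)) {
    cols <- which(dest == d)
    sub <- subset_well(well, cols)
    sub$cell_metadata$sample_label <- rep(d, length(cols))
    f <- file.path(out_dir, paste0(sanitize_name(well_id), "_",
                                   sanitize_name(d), ".h5"))
    write_10x_h5(sub, f)
    files[[d]] <- f
    outputs[[d]] <- list(n_cells = length(cols),
                         total_counts = sum(sub$matrix))
  }
  report <- list(well_id = well_id,
                 n_cells_in = ncol(well$matrix),
                 total_counts_in = sum(well$matrix),
                 outputs = outputs)
  write_metrics_report(report, file.path(out_dir,
                                         paste0(sanitize_name(well_id),
                                                "_split_metrics.json")))
  invisible(list(files = files, report = report))
}

#' Merge per-well split files by sample
#'
#' Concatenates, for each sample label, the per-well HDF5 files written by
#' [split_by_hash()] into one file per sample (plus one for the pooled
#' non-singlet cells). All inputs must share an identical feature list;
#' columns are concatenated in well order then barcode order, metadata
#' alongside.
#'
#' @param files Character vector of HDF5 paths (or a directory containing
#'   `*.h5` split outputs).
#' @param out_dir Output directory.
#' @return Invisibly, a list: `files` (merged paths by sample), `report`
#'   (per-sample totals and per-well category counts, also written as
#'   `merge_metrics.json`).
#' @export
merge_by_sample <- function(files, out_dir) {
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.h5$", full.names = TRUE)
  if (!length(files)) stop("no input files to merge", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wells <- lapply(files, read_10x_h5)
  labels <- vapply(wells, function(w) {
    lb <- unique(w$cell_metadata$sample_label)
    if (length(lb) != 1L)
      stop("input file mixes sample labels; not a split output", call. = FALSE)
    lb
  }, character(1))
  ref <- wells[[1]]$features
  for (k in seq_along(wells)) {
    f <- wells[[k]]$features
    if (!identical(f$id, ref$id)) {
      div <- which(f$id != ref$id)[1]
      if (is.na(div)) div <- min(nrow(f), nrow(ref)) + 1L
      stop(sprintf("feature list mismatch in %s at feature %d", files[k], div),
           call. = FALSE)
    }
  }
  ord <- order(vapply(wells, function(w) w$cell_metadata$well_id[1], character(1)))
  out_files <- list()
  per_sample <- list()
  for (lb in unique(labels[ord])) {
    ws <- wells[ord][labels[ord] == lb]
    m <- do.call(cbind, lapply(ws, function(w) w$matrix))
    bc <- unlist(lapply(ws, function(w) w$cell_barcodes), use.names = FALSE)
    md <- dplyr::bind_rows(lapply(ws, function(w) w$cell_metadata))
    if (anyDuplicated(md$cell_uuid))
      stop("duplicate cell UUIDs while merging '", lb, "'", call. = FALSE)
    merged <- well_matrix(m, ref, bc, md)
    f <- file.path(out_dir, paste0(sanitize_name(lb), ".h5"))
    write_10x_h5(merged, f)
    out_files[[lb]] <- f
    per_sample[[lb]] <- list(
      n_cells = ncol(m), total_counts = sum(m),
      cells_per_well = as.list(table(md$well_id)))
  }
  all_md <- dplyr::bind_rows(lapply(wells, function(w) w$cell_metadata))
  per_well <- lapply(split(all_md$hash_category, all_md$well_id), function(cats) {
    as.list(table(factor(cats, levels = c("singlet", "doublet", "multiplet",
                                          "no_hash"))))
  })
  report <- list(samples = per_sample, category_counts_by_well = per_well)
  write_metrics_report(report, file.path(out_dir, "merge_metrics.json"))
  invisible(list(files = out_files, report = report))
}

#' Per-well QC report
#'
#' Summarizes a classified well: cell counts and fractions per hash
#' category, the fraction of HTO reads attributed to each category, and
#' per-hashtag distributions (quartiles) of RNA UMIs per cell and detected
#' genes per cell.
#'
#' @param well An annotated [well_matrix()].
#' @param counts The well's [hto_counts()] (used for read-usage metrics);
#'   optional.
#' @return A nested metrics list.
#' @export
well_report <- function(well, counts = NULL) {
  md <- well$cell_metadata
  stopifnot("hash_category" %in% names(md))
  lev <- c("singlet", "doublet", "multiplet", "no_hash")
  cat_f <- factor(md$hash_category, levels = lev)
  n_cat <- table(cat_f)
  total <- ncol(well$matrix)
  out <- list(
    well_id = if ("well_id" %in% names(md)) md$well_id[1] else NA,
    n_cells = total,
    cells_per_category = lapply(as.list(n_cat), as.integer),
    fraction_per_category = lapply(as.list(n_cat), function(k)
      as.integer(k) / total))
  if (!is.null(counts)) {
    idx <- match(well$cell_barcodes, counts$cell_barcodes)
    reads <- counts$total_reads[idx]
    reads[is.na(reads)] <- 0L
    tot_reads <- sum(reads)
    out$hto_read_fraction_per_category <- lapply(
      split(reads, cat_f), function(r)
        if (tot_reads > 0) sum(r) / tot_reads else 0)
  }
  rna <- Matrix::colSums(well$matrix)
  genes <- Matrix::colSums(well$matrix > 0)
  qs <- function(v) {
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    list(q25 = q[1], median = q[2], q75 = q[3])
  }
  singlet <- md$hash_category == "singlet" & !is.na(md$tag_name) &
    md$tag_name != ""
  by_tag <- split(seq_len(total)[singlet], md$tag_name[singlet])
  out$rna_umis_by_tag <- lapply(by_tag, function(i) qs(rna[i]))
  out$genes_detected_by_tag <- lapply(by_tag, function(i) qs(genes[i]))
  out
}
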