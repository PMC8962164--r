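# Cell Ranger v3 style HDF5 feature-barcode matrices, plus a parallel
# metadata group for per-cell annotations.

#' Construct a well matrix
#'
#' A features x cells sparse count matrix with feature annotation and
#' per-cell metadata, mirroring a Cell Ranger filtered feature-barcode
#' matrix for one 10x well.
#'
#' @param matrix A `dgCMatrix` (features x cells) of non-negative integer
#'   counts.
#' @param features Tibble with columns `id`, `name`, `feature_type`, one row
#'   per matrix row.
#' @param cell_barcodes Character vector, one per matrix column.
#' @param cell_metadata Optional tibble of per-cell annotations (one row per
#'   matrix column); created empty when omitted.
#' @return A `well_matrix` object.
#' @export
well_matrix <- function(matrix, features, cell_barcodes, cell_metadata = NULL) {
  matrix <- methods::as(methods::as(matrix, "CsparseMatrix"), "generalMatrix")
  features <- tibble::as_tibble(features)
  stopifnot(all(c("id", "name", "feature_type") %in% names(features)),
            nrow(features) == nrow(matrix),
            length(cell_barcodes) == ncol(matrix))
  if (any(matrix@x < 0) || any(matrix@x != round(matrix@x)))
    stop("well matrix counts must be non-negative integers", call. = FALSE)
  if (is.null(cell_metadata))
    cell_metadata <- tibble::tibble(.rows = length(cell_barcodes))
  cell_metadata <- tibble::as_tibble(cell_metadata)
  if (nrow(cell_metadata) != length(cell_barcodes))
    stop("cell_metadata rows must match the number of cells", call. = FALSE)
  structure(list(matrix = matrix, features = features,
                 cell_barcodes = as.character(cell_barcodes),
                 cell_metadata = cell_metadata),
            class = "well_matrix")
}

#' @export
print.well_matrix <- function(x, ...) {
  cat(sprintf("<well_matrix> %d features x %d cells, %s counts, metadata: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              format(sum(x$matrix), big.mark = ","),
              if (ncol(x$cell_metadata)) paste(names(x$cell_metadata), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
dim.well_matrix <- function(x) dim(x$matrix)

#' Tidy per-cell summary of a well matrix
#'
#' @param x A `well_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per cell: barcode, total RNA UMIs, number of
#'   detected genes, and any cell metadata columns.
#' @export
tidy.well_matrix <- function(x, ...) {
  out <- tibble::tibble(cell_barcode = x$cell_barcodes,
                        rna_umis = Matrix::colSums(x$matrix),
                        genes_detected = Matrix::colSums(x$matrix > 0))
  dplyr::bind_cols(out, x$cell_metadata)
}

h5_read_or_schema_error <- function(path, name) {
  ok <- tryCatch({rhdf5::h5read(path, name)}, error = function(e) NULL)
  if (is.null(ok))
    stop(sprintf("HDF5 schema error in %s: missing dataset '%s'", path, name),
         call. = FALSE)
  ok
}

#' Read a 10x-style HDF5 feature-barcode matrix
#'
#' Expects the Cell Ranger v3 matrix schema: one top group holding CSC sparse
#' datasets (`data`, `indices`, `indptr`, `shape`), `barcodes`, and a
#' `features` subgroup (`id`, `name`, `feature_type`). A sibling `metadata`
#' group written by [write_10x_h5()] is restored into `cell_metadata` when
#' present.
#'
#' @param path HDF5 file path.
#' @return A [well_matrix()].
#' @export
read_10x_h5 <- function(path) {
  if (!file.exists(path)) stop("HDF5 file not found: ", path, call. = FALSE)
  on.exit(rhdf5::H5close(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  top <- setdiff(groups, "metadata")
  if (length(top) != 1L)
    stop("HDF5 schema error: expected one matrix group, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  g <- paste0("/", top)
  data <- as.vector(h5_read_or_schema_error(path, paste0(g, "/data")))
  indices <- as.vector(h5_read_or_schema_error(path, paste0(g, "/indices")))
  indptr <- as.vector(h5_read_or_schema_error(path, paste0(g, "/indptr")))
  shape <- as.vector(h5_read_or_schema_error(path, paste0(g, "/shape")))
  barcodes <- as.character(h5_read_or_schema_error(path, paste0(g, "/barcodes")))
  fid <- as.character(h5_read_or_schema_error(path, paste0(g, "/features/id")))
  fname <- as.character(h5_read_or_schema_error(path, paste0(g, "/features/name")))
  ftype <- as.character(h5_read_or_schema_error(path, paste0(g, "/features/feature_type")))
  if (length(shape) != 2L || length(indptr) != shape[2] + 1L ||
      length(barcodes) != shape[2] || length(fid) != shape[1])
    stop("HDF5 matrix shape is inconsistent with its datasets", call. = FALSE)
  m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = as.numeric(data),
                            dims = shape, index1 = TRUE)
  meta <- NULL
  if ("metadata" %in% groups) {
    md <- lapply(rhdf5::h5read(path, "/metadata"), as.vector)
    ord <- md[[".column_order"]]
    md[[".column_order"]] <- NULL
    if (!is.null(ord)) md <- md[as.character(ord)]
    meta <- tibble::as_tibble(md)
  }
  well_matrix(m, tibble::tibble(id = fid, name = fname, feature_type = ftype),
              barcodes, meta)
}

#' Write a well matrix in the 10x HDF5 schema
#'
#' Writes the standard Cell Ranger v3 layout under group `matrix` so that
#' third-party 10x readers can open the file, and stores `cell_metadata`
#' columns in a sibling `metadata` group aligned to barcode order.
#' `read_10x_h5(write_10x_h5(x))` is the identity on matrix, barcodes,
#' features and metadata; writing is bit-deterministic.
#'
#' @param well A [well_matrix()].
#' @param path Output path (overwritten if present).
#' @return Invisibly, `path`.
#' @export
write_10x_h5 <- function(well, path) {
  stopifnot(inherits(well, "well_matrix"))
  if (file.exists(path)) file.remove(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "matrix")
  m <- well$matrix
  # rhdf5 warns (harmlessly) when creating zero-length datasets
  h5w <- function(obj, name) {
    if (length(obj)) rhdf5::h5write(obj, path, name)
    else suppressWarnings(rhdf5::h5write(obj, path, name))
  }
  h5w(as.integer(m@x), "matrix/data")
  h5w(as.integer(m@i), "matrix/indices")
  h5w(as.integer(m@p), "matrix/indptr")
  h5w(as.integer(dim(m)), "matrix/shape")
  h5w(well$cell_barcodes, "matrix/barcodes")
  rhdf5::h5createGroup(path, "matrix/features")
  h5w(well$features$id, "matrix/features/id")
  h5w(well$features$name, "matrix/features/name")
  h5w(well$features$feature_type, "matrix/features/feature_type")
  md <- well$cell_metadata
  if (ncol(md)) {
    rhdf5::h5createGroup(path, "metadata")
    for (nm in names(md)) {
      v <- md[[nm]]
      if (length(v) != length(well$cell_barcodes))
        stop("metadata column '", nm, "' length mismatch", call. = FALSE)
      if (is.factor(v)) v <- as.character(v)
      if (is.logical(v)) v <- as.integer(v)
      if (is.character(v)) v[is.na(v)] <- ""   # missing labels stored as ""
      rhdf5::h5write(v, path, paste0("metadata/", nm))
    }
    rhdf5::h5write(names(md), path, "metadata/.column_order")
  }
  invisible(path)
}
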