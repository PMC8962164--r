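# Machine-readable metric reports (JSON with deterministically sorted keys).

sort_keys_recursive <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    x <- x[order(names(x), method = "radix")]
    lapply(x, sort_keys_recursive)
  } else if (is.list(x)) {
    lapply(x, sort_keys_recursive)
  } else x
}

#' Write a metrics report
#'
#' Serializes a nested key-value structure as pretty-printed JSON with keys
#' sorted at every level, so identical metrics always produce identical
#' bytes.
#'
#' @param metrics Named list (possibly nested) of scalars, vectors and lists.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(metrics, path) {
  if (!is.list(metrics))
    stop("metrics must be a (possibly nested) named list", call. = FALSE)
  check_leaf <- function(x) {
    if (is.list(x)) {
      lapply(x, check_leaf)
    } else if (!(is.atomic(x) || is.null(x))) {
      stop("metrics contain a non-serializable value of class ",
           paste(class(x), collapse = "/"), call. = FALSE)
    }
    invisible(NULL)
  }
  check_leaf(metrics)
  if (!length(metrics)) metrics <- setNames(list(), character(0))
  json <- tryCatch(
    jsonlite::toJSON(sort_keys_recursive(metrics), auto_unbox = TRUE,
                     pretty = TRUE, digits = NA, null = "null",
                     force = FALSE),
    error = function(e) stop("metrics contain a non-serializable value: ",
                             conditionMessage(e), call. = FALSE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a metrics report written by [write_metrics_report()]
#'
#' @param path JSON path.
#' @return The metrics list.
#' @export
read_metrics_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
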