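# Hash classification: per-tag count cutoffs via dip test + exact 1-D
# 2-means, then binarization into singlet/doublet/multiplet/no-hash.

#' Cutoff estimation parameters
#'
#' @param min_count Counts below this are discarded before estimating a
#'   cutoff (default 10); low counts are ambient background.
#' @param sd_multiplier For unimodal tags the cutoff is
#'   `exp(mean + sd_multiplier * sd)` of log counts (default 2).
#' @param fold_threshold A bimodal split is accepted only when the upper
#'   k-means center exceeds the lower by more than this fold change on the
#'   count scale (default 4).
#' @param dip_replicates Uniform-null replicates for the dip test p-value
#'   (default 20).
#' @param dip_alpha Significance level for rejecting unimodality
#'   (default 0.05).
#' @param min_values Minimum retained counts required to attempt estimation
#'   (default 10).
#' @return A `cutoff_params` list.
#' @export
cutoff_params <- function(min_count = 10L, sd_multiplier = 2,
                          fold_threshold = 4, dip_replicates = 20L,
                          dip_alpha = 0.05, min_values = 10L) {
  stopifnot(min_count > 0, sd_multiplier > 0, fold_threshold > 0,
            dip_replicates > 0, dip_alpha > 0, dip_alpha < 1, min_values > 0)
  structure(list(min_count = as.integer(min_count),
                 sd_multiplier = sd_multiplier,
                 fold_threshold = fold_threshold,
                 dip_replicates = as.integer(dip_replicates),
                 dip_alpha = dip_alpha,
                 min_values = as.integer(min_values)),
            class = "cutoff_params")
}

#' Hartigan & Hartigan dip statistic
#'
#' The dip of the empirical distribution: the smallest sup-norm distance
#' between the empirical cdf and any unimodal cdf. Computed exactly by
#' bisection on the band half-width with a convex/concave feasibility test
#' (compiled); ties are handled exactly. The value lies in
#' `[0, 0.25]`, with `1/(2n)` the floor for n distinct values.
#'
#' @param x Numeric values (at least 2 for a nonzero result).
#' @return The dip statistic.
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("dip_stat: missing values", call. = FALSE)
  if (length(x) < 2L) return(0)
  .dip_stat_cpp(x)
}

#' Dip test of unimodality
#'
#' Bootstrap-calibrated dip test: the observed dip is compared against the
#' dips of `replicates` uniform samples of the same size (the standard
#' conservative null for the dip), giving
#' `p = (1 + #{null >= observed}) / (replicates + 1)`. Deterministic given
#' `rng_seed`.
#'
#' @param values Numeric sample (>= 3 values).
#' @param replicates Number of null replicates (default 20).
#' @param rng_seed Integer seed for the null resampling.
#' @return A list with `statistic`, `p_value`, `replicates`.
#' @export
dip_unimodality_test <- function(values, replicates = 20L, rng_seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("dip test requires at least 3 values", call. = FALSE)
  obs <- dip_stat(values)
  n <- length(values)
  n_above <- withr::with_seed(rng_seed, {
    sum(vapply(seq_len(replicates), function(i)
      .dip_above_cpp(runif(n), obs - 1e-12), logical(1)))
  })
  p <- (1 + n_above) / (replicates + 1)
  list(statistic = obs, p_value = p, replicates = as.integer(replicates))
}

#' Globally optimal 1-D 2-means
#'
#' Exact two-cluster k-means in one dimension: the optimal partition is
#' always a split of the sorted values, so every split point is scanned with
#' prefix sums and the minimum within-cluster sum of squares chosen. No
#' random initialization; deterministic. Ties in cost are broken toward the
#' smallest upper cluster (largest split index).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return List with `lower_center`, `upper_center` (cluster means,
#'   `lower_center < upper_center`), `labels` (1 = lower, 2 = upper, in input
#'   order) and `withinss` (total within-cluster sum of squares).
#' @export
two_means_1d <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("two_means_1d requires at least 2 distinct values", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ssl <- cs2[k] - cs[k]^2 / k
  ssr <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  cost <- ssl + ssr
  best <- which(cost <= min(cost) + 1e-12)
  split <- best[length(best)]
  labels_sorted <- rep(1L, n)
  labels_sorted[(split + 1L):n] <- 2L
  labels <- integer(n)
  labels[ord] <- labels_sorted
  list(lower_center = cs[split] / split,
       upper_center = (cs[n] - cs[split]) / (n - split),
       labels = labels,
       withinss = cost[split])
}

#' Cutoff for one hashtag's count distribution
#'
#' The multi-step cutoff procedure: (1) discard counts below
#' `params$min_count`; with fewer than `params$min_values` retained the tag
#' is `insufficient_data` and nothing passes. (2) Log-transform. (3) Dip
#' test: a unimodal distribution gets the cutoff
#' `exp(mean + sd_multiplier * sd)` of the log counts
#' (`unimodal_mean2sd`). (4) Otherwise exact 1-D 2-means on the log counts;
#' if the upper center exceeds `fold_threshold` times the lower center on
#' the count scale, the cutoff is the smallest original count in the upper
#' cluster (`bimodal_kmeans`). (5) Otherwise no barcode passes and the
#' cutoff is the maximum observed count plus one (`none_passing`).
#'
#' @param tag_counts Non-negative integer counts for one tag across cell
#'   barcodes.
#' @param params [cutoff_params()].
#' @param rng_seed Seed for the dip test's null resampling.
#' @param tag_name Optional tag name recorded in the result.
#' @return A one-row tibble: `tag_name`, `cutoff`, `method`, `n_retained`,
#'   `dip_p`, `center_lo_log`, `center_hi_log`.
#' @export
compute_cutoff <- function(tag_counts, params = cutoff_params(),
                           rng_seed = 1L, tag_name = NA_character_) {
  counts <- as.numeric(tag_counts)
  if (any(counts < 0) || any(counts != round(counts), na.rm = TRUE))
    stop("tag counts must be non-negative integers", call. = FALSE)
  retained <- counts[counts >= params$min_count]
  row <- function(cutoff, method, dip_p = NA_real_,
                  lo = NA_real_, hi = NA_real_) {
    tibble::tibble(tag_name = tag_name, cutoff = cutoff, method = method,
                   n_retained = length(retained), dip_p = dip_p,
                   center_lo_log = lo, center_hi_log = hi)
  }
  if (length(retained) < params$min_values)
    return(row(Inf, "insufficient_data"))
  lg <- log(retained)
  dip <- dip_unimodality_test(lg, params$dip_replicates, rng_seed)
  if (dip$p_value > params$dip_alpha) {
    cutoff <- exp(mean(lg) + params$sd_multiplier * sd(lg))
    return(row(cutoff, "unimodal_mean2sd", dip$p_value))
  }
  km <- two_means_1d(lg)
  lo <- km$lower_center; hi <- km$upper_center
  if (hi - lo > log(params$fold_threshold)) {
    cutoff <- min(retained[km$labels == 2L])
    return(row(cutoff, "bimodal_kmeans", dip$p_value, lo, hi))
  }
  row(max(counts) + 1, "none_passing", dip$p_value, lo, hi)
}

#' Cutoffs for every tag of an HTO count matrix
#'
#' @param counts An [hto_counts()] object.
#' @param params [cutoff_params()].
#' @param rng_seed Base seed; each tag uses `rng_seed + <tag index>` for its
#'   dip-test resampling.
#' @return A `tag_cutoffs` tibble, one row per tag.
#' @export
compute_cutoffs <- function(counts, params = cutoff_params(), rng_seed = 1L) {
  stopifnot(inherits(counts, "hto_counts"))
  rows <- lapply(seq_along(counts$tag_names), function(j) {
    compute_cutoff(counts$umi[, j], params, rng_seed = rng_seed + j,
                   tag_name = counts$tag_names[j])
  })
  out <- dplyr::bind_rows(rows)
  structure(out, params = params, class = c("tag_cutoffs", class(out)))
}

#' @export
print.tag_cutoffs <- function(x, ...) {
  cat("<tag_cutoffs>\n")
  NextMethod()
}

#' @export
tidy.tag_cutoffs <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a cutoff table
#'
#' @param x A `tag_cutoffs` tibble.
#' @param ... Unused.
#' @return A one-row tibble with tag counts per cutoff method.
#' @export
glance.tag_cutoffs <- function(x, ...) {
  tibble::tibble(n_tags = nrow(x),
                 n_bimodal = sum(x$method == "bimodal_kmeans"),
                 n_unimodal = sum(x$method == "unimodal_mean2sd"),
                 n_none_passing = sum(x$method == "none_passing"),
                 n_insufficient = sum(x$method == "insufficient_data"))
}

#' Count histograms with cutoff lines
#'
#' @param object A `tag_cutoffs` tibble.
#' @param counts The [hto_counts()] the cutoffs were derived from.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object: per-tag histograms with the cutoff marked.
#' @export
autoplot.tag_cutoffs <- function(object, counts, bins = 50, ...) {
  p <- autoplot(counts, bins = bins)
  cut_df <- tibble::tibble(tag_name = object$tag_name,
                           cutoff = ifelse(is.finite(object$cutoff),
                                           object$cutoff, NA_real_))
  p + ggplot2::geom_vline(data = cut_df,
                          ggplot2::aes(xintercept = .data$cutoff),
                          colour = "steelblue", linewidth = 0.8, na.rm = TRUE)
}

#' Binarize counts against cutoffs and assign hash categories
#'
#' A barcode passes a tag when its count is greater than or equal to the
#' tag's cutoff. Barcodes passing exactly one tag are singlets, two are
#' doublets, more than two multiplets, and none no-hash.
#'
#' @param counts An [hto_counts()] object.
#' @param cutoffs A `tag_cutoffs` tibble aligned to the same tags.
#' @return A `hash_categories` tibble: `cell_barcode`, `category`,
#'   `assigned_tags` (passing tag names in taglist order, `;`-joined),
#'   `n_passing`, `top_tag_count`, `second_tag_count`.
#' @export
binarize_and_categorize <- function(counts, cutoffs) {
  stopifnot(inherits(counts, "hto_counts"))
  if (!identical(as.character(cutoffs$tag_name), counts$tag_names))
    stop("cutoff table tags do not align with the count matrix", call. = FALSE)
  umi <- counts$umi
  pass <- sweep(umi, 2L, cutoffs$cutoff, `>=`)
  n_pass <- rowSums(pass)
  category <- cut(n_pass, breaks = c(-1, 0, 1, 2, Inf),
                  labels = c("no_hash", "singlet", "doublet", "multiplet"))
  assigned <- unname(apply(pass, 1L, function(r)
    paste(counts$tag_names[r], collapse = ";")))
  sorted2 <- apply(umi, 1L, function(r)
    sort(r, decreasing = TRUE)[seq_len(min(2L, length(r)))])
  if (!is.matrix(sorted2)) sorted2 <- rbind(sorted2, NA_integer_)
  out <- tibble::tibble(
    cell_barcode = counts$cell_barcodes,
    category = factor(as.character(category),
                      levels = c("singlet", "doublet", "multiplet", "no_hash")),
    assigned_tags = assigned,
    n_passing = as.integer(n_pass),
    top_tag_count = as.integer(sorted2[1, ]),
    second_tag_count = as.integer(sorted2[2, ]))
  structure(out, tag_names = counts$tag_names,
            class = c("hash_categories", class(out)))
}

#' Category counts and fractions for a classification
#'
#' The per-well hashing summary: barcode counts per category (keys always
#' present, zero when empty), fractions, and per-tag passing counts.
#'
#' @param table A `hash_categories` tibble.
#' @return A nested list suitable for [write_metrics_report()].
#' @export
classification_metrics <- function(table) {
  stopifnot(inherits(table, "hash_categories"))
  if (!nrow(table)) stop("empty classification table", call. = FALSE)
  lev <- c("singlet", "doublet", "multiplet", "no_hash")
  n <- as.list(table(factor(table$category, levels = lev)))
  total <- nrow(table)
  tags <- attr(table, "tag_names")
  per_tag <- setNames(rep(0L, length(tags)), tags)
  assigned <- unlist(strsplit(table$assigned_tags[table$assigned_tags != ""], ";",
                              fixed = TRUE))
  if (length(assigned)) {
    tb <- table(factor(assigned, levels = tags))
    per_tag[names(tb)] <- as.integer(tb)
  }
  c(list(total_barcodes = total),
    lapply(n, as.integer),
    list(fractions = lapply(n, function(k) as.integer(k) / total),
         tag_passing = as.list(per_tag)))
}

#' Category composition plot
#'
#' @param object A `hash_categories` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of barcode counts per category.
#' @export
autoplot.hash_categories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "cell barcodes")
}
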