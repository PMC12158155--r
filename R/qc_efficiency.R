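#' Pseudobulk count conversion efficiency
#'
#' Treats each matrix as one bulk sample (all observations summed) and
#' returns the percentage of the input counts that survive conversion:
#' `100 * total(converted) / total(input)`. Can exceed 100 when a
#' one-to-many expansion policy replicates counts into several targets.
#'
#' @param x Input [expression_matrix()] (pre-conversion).
#' @param y Converted [expression_matrix()]; must carry the same
#'   observation ids in the same order.
#' @return A percentage (scalar).
#' @export
pseudobulk_efficiency <- function(x, y) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(y, "expression_matrix"))
  if (!identical(obs_ids(x), obs_ids(y))) {
    abort("observation ids of the two matrices differ")
  }
  tot <- sum(x$counts)
  if (tot == 0) abort("empty source matrix")
  100 * sum(y$counts) / tot
}

#' Per-observation (cell / spot / pixel) conversion efficiency
#'
#' For every observation `j`, the percentage of its counts surviving
#' conversion: `100 * colsum(y, j) / colsum(x, j)`. Observations with zero
#' input counts get `NA` (reported as missing, not as 0 or 100, to avoid
#' skewing summaries) plus a warning listing them.
#'
#' @inheritParams pseudobulk_efficiency
#' @return A tibble with columns `obs_id` and `efficiency` (percent,
#'   `NA` where undefined).
#' @export
per_observation_efficiency <- function(x, y) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(y, "expression_matrix"))
  if (!identical(obs_ids(x), obs_ids(y))) {
    abort("observation ids of the two matrices differ")
  }
  cx <- Matrix::colSums(x$counts)
  cy <- Matrix::colSums(y$counts)
  eff <- ifelse(cx > 0, 100 * cy / cx, NA_real_)
  if (any(cx == 0)) {
    warn(sprintf("efficiency undefined for zero-count observation(s): %s",
                 paste(obs_ids(x)[cx == 0], collapse = ", ")))
  }
  tibble(obs_id = obs_ids(x), efficiency = unname(eff))
}

#' Gene-level mapping rate
#'
#' The percentage of the given features that have at least one human
#' target in the table.
#'
#' @param table An [ortholog_table()].
#' @param features Character vector of feature ids, or an
#'   [expression_matrix()].
#' @param case_insensitive Uppercase both sides before matching.
#' @return A percentage (scalar).
#' @export
gene_mapping_rate <- function(table, features, case_insensitive = FALSE) {
  ids <- if (inherits(features, "expression_matrix")) feature_ids(features)
         else as.character(features)
  if (length(ids) == 0L) abort("empty feature list")
  tgt <- .match_targets(table, ids, case_insensitive)
  100 * sum(lengths(tgt) > 0L) / length(ids)
}

#' Biotype retention after conversion
#'
#' Tallies, per source-gene biotype, how many input features were retained
#' by the conversion (fate `kept`). Features lacking a biotype annotation
#' are pooled as `"unknown"`. The headline use is checking that
#' protein-coding genes survive ortholog mapping at a high rate.
#'
#' @param x The input [expression_matrix()].
#' @param result A `conversion_result` from [convert_matrix()].
#' @param biotypes Optional named character vector (names = feature ids) or
#'   a data frame with `feature_id` and `biotype` columns; defaults to the
#'   `biotype` column of `x$feature_meta` if present.
#' @return A tibble with columns `biotype`, `n_in`, `n_retained`,
#'   `percent`.
#' @export
biotype_retention <- function(x, result, biotypes = NULL) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(result, "conversion_result"))
  ids <- feature_ids(x)
  bt <- rep(NA_character_, length(ids))
  if (is.null(biotypes) && !is.null(x$feature_meta) &&
      "biotype" %in% names(x$feature_meta)) {
    bt <- x$feature_meta$biotype
  } else if (is.data.frame(biotypes)) {
    bt <- biotypes$biotype[match(ids, biotypes$feature_id)]
  } else if (!is.null(biotypes)) {
    bt <- unname(biotypes[ids])
  }
  bt[is.na(bt) | bt == ""] <- "unknown"
  kept <- result$plan$fate[match(ids, result$plan$feature_id)] == "kept"
  tibble(feature_id = ids, biotype = bt, kept = kept) |>
    dplyr::group_by(.data$biotype) |>
    dplyr::summarise(n_in = dplyr::n(), n_retained = sum(.data$kept),
                     .groups = "drop") |>
    dplyr::mutate(percent = 100 * .data$n_retained / .data$n_in) |>
    dplyr::arrange(.data$biotype)
}
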