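#' Cluster labelings
#'
#' A `cluster_labeling` is a tibble with one row per observation:
#' `obs_id` and a categorical `label`.
#'
#' @param obs_ids Character vector of observation ids (unique).
#' @param labels One label per observation (coerced to character).
#' @return A `cluster_labeling` tibble.
#' @export
cluster_labeling <- function(obs_ids, labels) {
  obs_ids <- as.character(obs_ids)
  if (anyDuplicated(obs_ids)) abort("duplicate obs_ids in labeling")
  if (length(labels) != length(obs_ids)) {
    abort("one label per obs_id required")
  }
  tibble::new_tibble(
    tibble(obs_id = obs_ids, label = as.character(labels)),
    nrow = length(obs_ids),
    class = "cluster_labeling"
  )
}

# align two labelings on their shared obs_id order; errors name differences
.align_labelings <- function(l1, l2) {
  l1 <- if (inherits(l1, "cluster_labeling")) l1 else
    cluster_labeling(l1$obs_id, l1$label)
  l2 <- if (inherits(l2, "cluster_labeling")) l2 else
    cluster_labeling(l2$obs_id, l2$label)
  if (!setequal(l1$obs_id, l2$obs_id)) {
    only1 <- setdiff(l1$obs_id, l2$obs_id)
    only2 <- setdiff(l2$obs_id, l1$obs_id)
    abort(sprintf(
      "labelings cover different observations (only in first: %s; only in second: %s)",
      paste(head(only1, 5), collapse = ","),
      paste(head(only2, 5), collapse = ",")))
  }
  if (nrow(l1) < 2L) abort("at least 2 observations required")
  list(a = l1$label, b = l2$label[match(l1$obs_id, l2$obs_id)])
}

#' Rand index between two clusterings
#'
#' Pair-counting agreement `RI = (a + b) / C(n, 2)`, where `a` is the
#' number of observation pairs placed in the same cluster by both
#' labelings and `b` the number separated by both. Computed from the
#' contingency table; symmetric and invariant to label renaming; lies in
#' `[0, 1]` with 1 for identical partitions.
#'
#' @param l1,l2 [cluster_labeling()] objects (or data frames with
#'   `obs_id` / `label` columns) over the same observations; order may
#'   differ — they are aligned on `obs_id` internally.
#' @return The Rand index, a scalar in `[0, 1]`.
#' @export
rand_index <- function(l1, l2) {
  al <- .align_labelings(l1, l2)
  n <- length(al$a)
  ct <- table(al$a, al$b)
  sum_nij2 <- sum(choose(ct, 2))
  sum_ai2 <- sum(choose(rowSums(ct), 2))
  sum_bj2 <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  a <- sum_nij2
  b <- total - sum_ai2 - sum_bj2 + sum_nij2
  (a + b) / total
}

#' Adjusted Rand index between two clusterings
#'
#' The Rand index corrected for chance agreement under the permutation
#' model (fixed cluster sizes): `ARI = (index - E[index]) /
#' (max_index - E[index])`, all computed from the contingency table.
#' Equals 1 for identical partitions, has expectation 0 for independent
#' labelings, and can be negative. When both partitions are trivial in the
#' same degenerate way (the chance-expected index equals the maximum) the
#' index is defined as 1 if the partitions agree and 0 otherwise.
#'
#' @inheritParams rand_index
#' @return The adjusted Rand index, a scalar `<= 1`.
#' @export
adjusted_rand_index <- function(l1, l2) {
  al <- .align_labelings(l1, l2)
  n <- length(al$a)
  ct <- table(al$a, al$b)
  sum_nij2 <- sum(choose(ct, 2))
  sum_ai2 <- sum(choose(rowSums(ct), 2))
  sum_bj2 <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  expected <- sum_ai2 * sum_bj2 / total
  max_index <- (sum_ai2 + sum_bj2) / 2
  if (max_index == expected) {
    # both partitions all-singletons or both one block: agreement is exact
    canon <- function(v) match(v, unique(v))
    return(if (identical(canon(al$a), canon(al$b))) 1 else 0)
  }
  (sum_nij2 - expected) / (max_index - expected)
}
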