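#' Conversion policy
#'
#' Explicit, fully disclosed rules for the three decision points of an
#' ortholog namespace conversion:
#'
#' * `many_to_one` — several source genes share one human target:
#'   `"sum"` adds their rows (pseudo-gene-level aggregation of counts,
#'   the default), `"max_total"` keeps only the row of the source with the
#'   largest total count across observations (ties broken by
#'   lexicographically smallest source id), `"drop_group"` removes the
#'   target entirely whenever two or more sources share it.
#' * `one_to_many` — a source gene has several human targets: `"expand"`
#'   (default) replicates its counts into every target (total counts can
#'   exceed the input; the report flags this), `"drop"` discards the
#'   source as ambiguous.
#' * `unmapped` — source genes with no human target: `"drop"` (default)
#'   or `"retain_tagged"`, which keeps their rows under an `unmapped:`
#'   prefix.
#'
#' @param many_to_one One of `"sum"`, `"max_total"`, `"drop_group"`.
#' @param one_to_many One of `"expand"`, `"drop"`.
#' @param unmapped One of `"drop"`, `"retain_tagged"`.
#' @param case_insensitive Uppercase both matrix features and table source
#'   genes before matching (off by default: silent case-folding can create
#'   false merges between paralogs).
#' @return A `conversion_policy` object.
#' @export
conversion_policy <- function(many_to_one = c("sum", "max_total", "drop_group"),
                              one_to_many = c("expand", "drop"),
                              unmapped = c("drop", "retain_tagged"),
                              case_insensitive = FALSE) {
  .assert_scalar_flag(case_insensitive, "case_insensitive")
  structure(
    list(many_to_one = match.arg(many_to_one),
         one_to_many = match.arg(one_to_many),
         unmapped = match.arg(unmapped),
         case_insensitive = case_insensitive),
    class = "conversion_policy"
  )
}

#' @export
print.conversion_policy <- function(x, ...) {
  cat(sprintf(
    "<conversion_policy> many_to_one=%s, one_to_many=%s, unmapped=%s, case_insensitive=%s\n",
    x$many_to_one, x$one_to_many, x$unmapped, x$case_insensitive))
  invisible(x)
}

# Shared fate/edge resolution used by both conversion_plan() and
# convert_matrix(). Returns:
#   edges: tibble(row, feature_id, target) of retained source->target edges
#   fate: tibble(feature_id, fate, targets) one row per input feature
# `totals` (per-feature total counts) is needed only for max_total; when
# NULL all totals are treated as equal so the lexicographic tie-break
# decides.
.plan_edges <- function(table, ids, policy, totals = NULL) {
  stopifnot(inherits(table, "ortholog_table"),
            inherits(policy, "conversion_policy"))
  if (anyDuplicated(ids)) abort("duplicate feature ids in input")
  tgt <- .match_targets(table, ids, policy$case_insensitive)
  n_tgt <- lengths(tgt)

  fate <- rep("kept", length(ids))
  fate[n_tgt == 0L] <- "dropped_unmapped"
  if (policy$one_to_many == "drop") fate[n_tgt > 1L] <- "dropped_ambiguous"

  live <- which(fate == "kept")
  edges <- tibble(
    row = rep(live, n_tgt[live]),
    feature_id = rep(ids[live], n_tgt[live]),
    target = as.character(unlist(tgt[live], use.names = FALSE))
  )

  if (nrow(edges) > 0L && policy$many_to_one != "sum") {
    if (is.null(totals)) totals <- rep(0, length(ids))
    grp <- split(seq_len(nrow(edges)), edges$target)
    drop_edge <- logical(nrow(edges))
    for (g in grp) {
      if (length(g) < 2L) next
      if (policy$many_to_one == "drop_group") {
        drop_edge[g] <- TRUE
      } else { # max_total
        tot <- totals[edges$row[g]]
        best <- g[order(-tot, edges$feature_id[g])][1L]
        drop_edge[setdiff(g, best)] <- TRUE
      }
    }
    edges <- edges[!drop_edge, , drop = FALSE]
    # sources that lost every edge were ambiguous casualties of the policy
    lost <- setdiff(live, unique(edges$row))
    fate[lost] <- "dropped_ambiguous"
  }

  kept_targets <- split(edges$target, edges$feature_id)
  fate_tbl <- tibble(
    feature_id = ids,
    fate = fate,
    targets = lapply(ids, function(f) {
      v <- kept_targets[[f]]
      if (is.null(v)) character(0) else sort(unique(v))
    })
  )
  list(edges = edges, fate = fate_tbl)
}

#' Preview the fate of each feature under a policy
#'
#' A dry run of [convert_matrix()]: reports, per input feature, whether it
#' is kept (and into which human targets), dropped as unmapped, or dropped
#' as ambiguous — without touching any counts.
#'
#' With `many_to_one = "max_total"` the surviving source in each collision
#' group depends on row totals; pass the `expression_matrix` itself (rather
#' than bare feature ids) to resolve those fates exactly as
#' [convert_matrix()] will.
#'
#' @param table An [ortholog_table()].
#' @param features Either a character vector of feature ids or an
#'   [expression_matrix()].
#' @param policy A [conversion_policy()].
#' @return A tibble with columns `feature_id`, `fate`
#'   (`kept` / `dropped_unmapped` / `dropped_ambiguous`) and `targets`
#'   (list column of retained human targets).
#' @export
conversion_plan <- function(table, features, policy = conversion_policy()) {
  if (inherits(features, "expression_matrix")) {
    ids <- feature_ids(features)
    totals <- Matrix::rowSums(features$counts)
  } else {
    ids <- as.character(features)
    totals <- NULL
  }
  .plan_edges(table, ids, policy, totals = totals)$fate
}

#' Convert a count matrix to the human ortholog namespace
#'
#' Applies an [ortholog_table()] to an [expression_matrix()] under an
#' explicit [conversion_policy()]. Output features are the human targets
#' reachable from the input features after policy application, sorted
#' lexicographically; entry `(h, j)` aggregates the counts of every
#' retained source of `h` in observation `j` according to the policy.
#' Observations, per-observation metadata and embeddings pass through
#' unchanged, so the dimensional architecture of the input is preserved.
#'
#' Aggregation is performed by sparse incidence-matrix multiplication and
#' is exactly equal to the dense definition for integer inputs.
#'
#' @param x An [expression_matrix()].
#' @param table An [ortholog_table()].
#' @param policy A [conversion_policy()].
#' @return A `conversion_result` with elements `converted`
#'   (an [expression_matrix()] in the human namespace), `report`
#'   (a `conversion_report`), `plan` (the realized per-feature fates),
#'   `unmapped_features` and `dropped_ambiguous`.
#' @export
convert_matrix <- function(x, table, policy = conversion_policy()) {
  stopifnot(inherits(x, "expression_matrix"))
  ids <- feature_ids(x)
  if (length(ids) == 0L) abort("empty input matrix")
  totals <- Matrix::rowSums(x$counts)
  pe <- .plan_edges(table, ids, policy, totals = totals)
  edges <- pe$edges
  fate <- pe$fate

  n_mappable <- sum(fate$fate != "dropped_unmapped")
  if (n_mappable == 0L) {
    cnd <- rlang::error_cnd(class = "orthograft_no_features_mapped",
                            message = "no features mapped",
                            mapping_rate = 0)
    rlang::cnd_signal(cnd)
  }

  out_feats <- sort(unique(edges$target))
  tagged <- character(0)
  if (policy$unmapped == "retain_tagged") {
    unm <- fate$feature_id[fate$fate == "dropped_unmapped"]
    # NB: paste0 recycles zero-length input to "", hence the guard
    if (length(unm) > 0L) tagged <- paste0("unmapped:", unm)
  }
  all_out <- sort(c(out_feats, tagged))
  if (length(all_out) == 0L) {
    warn("policy removed every feature; converted matrix is empty")
  }

  inc_i <- match(edges$target, all_out)
  inc_j <- edges$row
  if (length(tagged) > 0L) {
    unm_rows <- which(fate$fate == "dropped_unmapped")
    inc_i <- c(inc_i, match(paste0("unmapped:", ids[unm_rows]), all_out))
    inc_j <- c(inc_j, unm_rows)
  }
  inc <- Matrix::sparseMatrix(i = inc_i, j = inc_j, x = 1,
                              dims = c(length(all_out), length(ids)),
                              dimnames = list(all_out, ids))
  conv <- inc %*% x$counts
  conv <- as(as(conv, "generalMatrix"), "CsparseMatrix")
  dimnames(conv) <- list(all_out, colnames(x$counts))

  feature_meta <- tibble(feature_id = all_out)
  converted <- expression_matrix(conv, feature_meta = feature_meta,
                                 obs_meta = x$obs_meta,
                                 embeddings = x$embeddings)

  unmapped_features <- fate$feature_id[fate$fate == "dropped_unmapped"]
  dropped_ambiguous <- fate$feature_id[fate$fate == "dropped_ambiguous"]

  result <- structure(
    list(converted = converted, report = NULL, plan = fate,
         unmapped_features = unmapped_features,
         dropped_ambiguous = dropped_ambiguous,
         policy = policy),
    class = "conversion_result"
  )
  result$report <- build_conversion_report(x, result, table)
  result
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("<conversion_result> %d -> %d features, %d observations\n",
              nrow(x$plan), nrow(x$converted$counts),
              ncol(x$converted$counts)))
  print(x$report)
  invisible(x)
}

#' @export
tidy.conversion_result <- function(x, ...) {
  x$plan |>
    dplyr::mutate(targets = vapply(.data$targets, paste, character(1),
                                   collapse = ";"))
}

#' @export
glance.conversion_result <- function(x, ...) {
  r <- x$report
  tibble(
    n_source_features = r$n_source_features,
    n_mapped_features = r$n_mapped_features,
    n_output_features = r$n_output_features,
    gene_mapping_rate = r$gene_mapping_rate,
    pseudobulk_count_efficiency = r$pseudobulk_count_efficiency,
    n_warnings = length(r$warnings)
  )
}
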