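#' Sparse expression matrix container
#'
#' Canonical in-memory representation of a count matrix: sparse non-negative
#' values oriented features x observations, with optional per-feature
#' metadata (e.g. biotype, species tag), per-observation metadata (cluster
#' labels, spatial coordinates) and named embeddings (observation x
#' dimension coordinate matrices). Values may be real (normalized assays
#' are allowed); only non-negativity is enforced.
#'
#' @param counts A matrix or Matrix coercible to `dgCMatrix`, with unique
#'   rownames (feature ids) and unique colnames (observation ids).
#' @param feature_meta Optional data frame with a `feature_id` column
#'   matching the rownames.
#' @param obs_meta Optional data frame with an `obs_id` column matching the
#'   colnames.
#' @param embeddings Optional named list of numeric matrices, each with one
#'   row per observation.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, feature_meta = NULL, obs_meta = NULL,
                              embeddings = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  # zero-extent margins carry no dimnames (Matrix normalizes them to NULL)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    abort("`counts` must have rownames (features) and colnames (observations)")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) abort("duplicate observation ids")
  if (length(counts@x) > 0L && min(counts@x) < 0) {
    abort("negative values are not allowed in an expression matrix")
  }
  if (!is.null(feature_meta)) {
    feature_meta <- as_tibble(feature_meta)
    if (!"feature_id" %in% names(feature_meta)) {
      abort("`feature_meta` must have a `feature_id` column")
    }
    if (!setequal(feature_meta$feature_id, rownames(counts))) {
      abort("`feature_meta$feature_id` must match the matrix rownames")
    }
    feature_meta <- feature_meta[match(rownames(counts),
                                       feature_meta$feature_id), ]
  }
  if (!is.null(obs_meta)) {
    obs_meta <- as_tibble(obs_meta)
    if (!"obs_id" %in% names(obs_meta)) {
      abort("`obs_meta` must have an `obs_id` column")
    }
    if (!setequal(obs_meta$obs_id, colnames(counts))) {
      abort("`obs_meta$obs_id` must match the matrix colnames")
    }
    obs_meta <- obs_meta[match(colnames(counts), obs_meta$obs_id), ]
  }
  if (!is.null(embeddings)) {
    stopifnot(is.list(embeddings), !is.null(names(embeddings)))
    for (nm in names(embeddings)) {
      emb <- as.matrix(embeddings[[nm]])
      if (nrow(emb) != ncol(counts)) {
        abort(sprintf("embedding '%s' must have one row per observation", nm))
      }
      rownames(emb) <- colnames(counts)
      embeddings[[nm]] <- emb
    }
  }
  structure(
    list(counts = counts, feature_meta = feature_meta, obs_meta = obs_meta,
         embeddings = embeddings),
    class = "expression_matrix"
  )
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname expression_matrix
#' @export
obs_ids <- function(x) colnames(x$counts)

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d observations (%d stored values)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$obs_meta)) {
    cat("  obs_meta:", paste(setdiff(names(x$obs_meta), "obs_id"),
                             collapse = ", "), "\n")
  }
  if (!is.null(x$embeddings)) {
    cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an expression matrix into long format
#'
#' Returns one row per stored (non-zero) entry: `feature_id`, `obs_id`,
#' `value`. Mainly useful for small matrices and plotting.
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @export
tidy.expression_matrix <- function(x, ...) {
  m <- methods::as(x$counts, "TsparseMatrix")
  tibble(
    feature_id = rownames(x$counts)[m@i + 1L],
    obs_id = colnames(x$counts)[m@j + 1L],
    value = m@x
  ) |>
    dplyr::arrange(.data$feature_id, .data$obs_id)
}

#' @export
glance.expression_matrix <- function(x, ...) {
  tibble(
    n_features = nrow(x$counts),
    n_obs = ncol(x$counts),
    total_counts = sum(x$counts),
    sparsity = 1 - length(x$counts@x) / prod(dim(x$counts)),
    integer_counts = .is_wholenumber(x$counts@x)
  )
}

# deduplicate feature ids by suffixing -1, -2, ... (10x-style), with warning
.dedup_ids <- function(ids, what = "feature") {
  if (!anyDuplicated(ids)) return(ids)
  warn(sprintf("duplicate %s ids made unique by suffixing", what))
  new <- ids
  dup_groups <- unique(ids[duplicated(ids)])
  for (g in dup_groups) {
    hit <- which(ids == g)
    new[hit] <- paste0(g, "-", seq_along(hit))
  }
  new
}
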