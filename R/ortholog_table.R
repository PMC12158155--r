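#' Ortholog mapping tables
#'
#' An `ortholog_table` is a tibble of deduplicated (source gene, human
#' target gene) pairs carrying a cardinality classification
#' (`one2one`, `one2many`, `many2many`, `unmapped`), an optional orthology
#' confidence flag and an optional source-gene biotype. Unmapped source
#' genes are retained as rows with `target_gene = NA` so that mapping-rate
#' denominators stay computable.
#'
#' Columns: `source_gene`, `target_gene`, `homology_type`, `confidence`,
#' `source_biotype`. Attributes record the source and target species and a
#' load report (`rows_read`, `rows_skipped`, `rows_deduplicated`).
#'
#' @param pairs A data frame with at least `source_gene` and `target_gene`
#'   columns (`target_gene` may be `NA` or `""` for unmapped sources) and
#'   optional `confidence` and `source_biotype` columns.
#' @param source_species Label for the non-human species (e.g. `"mouse"`).
#' @param target_species Label for the target namespace; fixed to
#'   `"human"` by convention.
#' @return An `ortholog_table` tibble, cardinality-classified.
#' @examples
#' tab <- ortholog_table(
#'   data.frame(source_gene = c("Trp53", "Myc"), target_gene = c("TP53", "MYC"))
#' )
#' dplyr::count(tab, homology_type)
#' @export
ortholog_table <- function(pairs, source_species = "unknown",
                           target_species = "human") {
  pairs <- as_tibble(pairs)
  if (!all(c("source_gene", "target_gene") %in% names(pairs))) {
    abort("`pairs` must have columns `source_gene` and `target_gene`")
  }
  if (!"confidence" %in% names(pairs)) pairs$confidence <- NA_integer_
  if (!"source_biotype" %in% names(pairs)) pairs$source_biotype <- NA_character_

  pairs$source_gene <- .trim(pairs$source_gene)
  pairs$target_gene <- .trim(pairs$target_gene)
  pairs$target_gene[!is.na(pairs$target_gene) & pairs$target_gene == ""] <-
    NA_character_
  pairs$confidence <- suppressWarnings(as.integer(pairs$confidence))
  pairs$source_biotype <- .trim(pairs$source_biotype)

  n_read <- nrow(pairs)
  bad <- is.na(pairs$source_gene) | pairs$source_gene == ""
  if (any(bad)) {
    warn(sprintf("skipped %d row(s) with empty source gene", sum(bad)))
    pairs <- pairs[!bad, , drop = FALSE]
  }

  n_before <- nrow(pairs)
  pairs <- dplyr::distinct(pairs, .data$source_gene, .data$target_gene,
                           .keep_all = TRUE)
  n_dedup <- n_before - nrow(pairs)

  # an unmapped row is redundant when the same source also has a mapped row
  mapped_sources <- unique(pairs$source_gene[!is.na(pairs$target_gene)])
  redundant <- is.na(pairs$target_gene) & pairs$source_gene %in% mapped_sources
  pairs <- pairs[!redundant, , drop = FALSE]

  pairs <- pairs[, c("source_gene", "target_gene", "confidence",
                     "source_biotype")]
  out <- tibble::new_tibble(
    pairs,
    nrow = nrow(pairs),
    class = "ortholog_table",
    source_species = source_species,
    target_species = target_species,
    load_report = list(rows_read = n_read,
                       rows_skipped = sum(bad),
                       rows_deduplicated = n_dedup)
  )
  classify_cardinality(out)
}

# columns accepted for each BioMart-export field (any order)
.biomart_cols <- list(
  source  = c("external_gene_name", "ensembl_gene_id"),
  target  = c("hsapiens_homolog_associated_gene_name",
              "hsapiens_homolog_ensembl_gene"),
  type    = "hsapiens_homolog_orthology_type",
  conf    = "hsapiens_homolog_orthology_confidence",
  biotype = "gene_biotype"
)

#' Read an ortholog mapping table from TSV
#'
#' Supports two dialects. `"biomart_tsv"` is the tab-separated export
#' produced by an Ensembl BioMart homolog query: a source column named
#' `external_gene_name` or `ensembl_gene_id`, a human homolog column named
#' `hsapiens_homolog_associated_gene_name` or
#' `hsapiens_homolog_ensembl_gene`, and optional
#' `hsapiens_homolog_orthology_type`, `hsapiens_homolog_orthology_confidence`
#' and `gene_biotype` columns. `"generic_two_column"` expects `source`,
#' `target` and an optional `biotype` column.
#'
#' Rows with an empty human homolog become unmapped pairs; exact duplicate
#' pairs collapse to one; rows with an empty source gene are skipped with a
#' warning and counted in the load report. Homology-type strings found in
#' the file are advisory only: the cardinality stored in the result is
#' always recomputed from the table itself (subsetted exports break
#' file-level labels).
#'
#' Identifiers may be gene symbols or Ensembl IDs; no translation between
#' the two spaces is attempted, so a count matrix must use the same
#' identifier space as its table.
#'
#' @param path Path to a tab-delimited UTF-8 file with a header row
#'   (gzip-compressed files are read transparently).
#' @param dialect `"biomart_tsv"` or `"generic_two_column"`.
#' @param source_species Species label stored on the result.
#' @return An [ortholog_table()].
#' @export
read_ortholog_table <- function(path,
                                dialect = c("biomart_tsv",
                                            "generic_two_column"),
                                source_species = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("mapping file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (ncol(raw) == 0L) abort(sprintf("empty mapping file: %s", path))

  if (dialect == "biomart_tsv") {
    pick <- function(cands, what, required = TRUE) {
      hit <- intersect(cands, names(raw))
      if (length(hit) == 0L) {
        if (required) {
          abort(sprintf(
            "biomart_tsv dialect: missing required column (one of: %s)",
            paste(cands, collapse = ", ")))
        }
        return(NULL)
      }
      hit[[1L]]
    }
    src_col <- pick(.biomart_cols$source, "source")
    tgt_col <- pick(.biomart_cols$target, "target")
    conf_col <- pick(.biomart_cols$conf, "confidence", required = FALSE)
    bio_col <- pick(.biomart_cols$biotype, "biotype", required = FALSE)
    pairs <- tibble(
      source_gene = raw[[src_col]],
      target_gene = raw[[tgt_col]],
      confidence = if (is.null(conf_col)) NA_integer_ else
        suppressWarnings(as.integer(raw[[conf_col]])),
      source_biotype = if (is.null(bio_col)) NA_character_ else raw[[bio_col]]
    )
  } else {
    missing_cols <- setdiff(c("source", "target"), names(raw))
    if (length(missing_cols) > 0L) {
      abort(sprintf("generic_two_column dialect: missing required column %s",
                    paste(missing_cols, collapse = ", ")))
    }
    pairs <- tibble(
      source_gene = raw[["source"]],
      target_gene = raw[["target"]],
      confidence = NA_integer_,
      source_biotype = if ("biotype" %in% names(raw)) raw[["biotype"]] else
        NA_character_
    )
  }
  if (nrow(pairs) == 0L) abort("no mapping rows")
  ortholog_table(pairs, source_species = source_species)
}

#' Recompute cardinality classes from table degrees
#'
#' For each mapped pair let `o` be the number of distinct human targets of
#' its source gene and `i` the number of distinct source genes of its
#' target. The pair is `one2one` iff `o = 1` and `i = 1`, `many2many` iff
#' `o > 1` and `i > 1`, and `one2many` otherwise. Unmapped rows are left
#' unchanged. The operation is idempotent, and its result is authoritative
#' over any homology-type strings present in an input file.
#'
#' @param table An [ortholog_table()].
#' @return The table with `homology_type` recomputed.
#' @export
classify_cardinality <- function(table) {
  stopifnot(inherits(table, "ortholog_table"))
  mapped <- !is.na(table$target_gene)
  o <- ave(rep(1L, nrow(table)), table$source_gene, FUN = sum)
  i <- rep(NA_integer_, nrow(table))
  if (any(mapped)) {
    i[mapped] <- ave(rep(1L, sum(mapped)), table$target_gene[mapped],
                     FUN = sum)
  }
  # unmapped rows never share a source with mapped rows (see constructor),
  # so `o` for mapped rows counts mapped pairs only
  type <- rep("unmapped", nrow(table))
  type[mapped] <- dplyr::case_when(
    o[mapped] == 1L & i[mapped] == 1L ~ "one2one",
    o[mapped] > 1L & i[mapped] > 1L ~ "many2many",
    .default = "one2many"
  )
  table$homology_type <- type
  cols <- c("source_gene", "target_gene", "homology_type", "confidence",
            "source_biotype")
  out <- table
  for (nm in setdiff(names(out), cols)) out[[nm]] <- NULL
  # reorder columns without dropping the table's attributes
  attrs <- attributes(out)
  out <- out[, cols]
  for (nm in c("source_species", "target_species", "load_report")) {
    attr(out, nm) <- attrs[[nm]]
  }
  class(out) <- attrs$class
  out
}

#' Filter an ortholog table
#'
#' Keeps mapped pairs satisfying every supplied predicate, re-classifies
#' cardinality on the filtered table, and converts sources that lose all
#' their targets into unmapped rows (they are retained, not dropped, so the
#' mapping-rate denominator is unchanged).
#'
#' @param table An [ortholog_table()].
#' @param min_confidence Optional minimum orthology confidence (0 or 1);
#'   pairs with missing confidence fail the predicate.
#' @param allowed_types Homology types to keep (evaluated against the
#'   classification of the input table).
#' @param allowed_biotypes Optional character vector of source biotypes to
#'   keep; pairs with missing biotype fail the predicate.
#' @return A filtered, re-classified [ortholog_table()]. If no mapped pair
#'   survives, a warning (not an error) is emitted.
#' @export
filter_ortholog_table <- function(table, min_confidence = NULL,
                                  allowed_types = c("one2one", "one2many",
                                                    "many2many"),
                                  allowed_biotypes = NULL) {
  stopifnot(inherits(table, "ortholog_table"))
  mapped <- !is.na(table$target_gene)
  keep <- mapped
  if (!is.null(min_confidence)) {
    keep <- keep & !is.na(table$confidence) &
      table$confidence >= min_confidence
  }
  keep <- keep & table$homology_type %in% allowed_types
  if (!is.null(allowed_biotypes)) {
    keep <- keep & !is.na(table$source_biotype) &
      table$source_biotype %in% allowed_biotypes
  }

  kept <- table[keep, , drop = FALSE]
  lost_sources <- setdiff(table$source_gene, kept$source_gene)
  if (length(lost_sources) > 0L) {
    meta <- table[match(lost_sources, table$source_gene), , drop = FALSE]
    unmapped_rows <- tibble(
      source_gene = lost_sources,
      target_gene = NA_character_,
      homology_type = "unmapped",
      confidence = meta$confidence,
      source_biotype = meta$source_biotype
    )
    kept <- dplyr::bind_rows(as_tibble(kept), unmapped_rows)
  }
  if (!any(!is.na(kept$target_gene))) {
    warn("filter removed every mapped pair")
  }
  out <- ortholog_table(kept,
                        source_species = attr(table, "source_species"),
                        target_species = attr(table, "target_species"))
  attr(out, "load_report") <- attr(table, "load_report")
  out
}

#' Forward and reverse indexes of an ortholog table
#'
#' @param table An [ortholog_table()].
#' @return `forward_index()`: a named list mapping each source gene to the
#'   character vector of its human targets (`character(0)` for unmapped
#'   sources). `reverse_index()`: the analogous map from targets back to
#'   sources.
#' @export
forward_index <- function(table) {
  stopifnot(inherits(table, "ortholog_table"))
  mapped <- table[!is.na(table$target_gene), ]
  idx <- split(mapped$target_gene, mapped$source_gene)
  empty <- setdiff(unique(table$source_gene), names(idx))
  c(idx, stats::setNames(rep(list(character(0)), length(empty)), empty))
}

#' @rdname forward_index
#' @export
reverse_index <- function(table) {
  stopifnot(inherits(table, "ortholog_table"))
  mapped <- table[!is.na(table$target_gene), ]
  split(mapped$source_gene, mapped$target_gene)
}

# targets for a vector of feature ids, honouring case-insensitive matching;
# returns a list parallel to `ids` (character(0) where unmatched)
.match_targets <- function(table, ids, case_insensitive = FALSE) {
  mapped <- table[!is.na(table$target_gene), ]
  key <- .fold_case(mapped$source_gene, case_insensitive)
  idx <- split(mapped$target_gene, key)
  res <- idx[.fold_case(ids, case_insensitive)]
  res[vapply(res, is.null, logical(1))] <- list(character(0))
  names(res) <- ids
  lapply(res, unique)
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("<ortholog_table> %s -> %s\n",
              attr(x, "source_species"), attr(x, "target_species")))
  counts <- table(x$homology_type)
  cat("  ", paste(sprintf("%s: %d", names(counts), as.integer(counts)),
                  collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' @export
glance.ortholog_table <- function(x, ...) {
  tibble(
    n_pairs = sum(!is.na(x$target_gene)),
    n_sources = dplyr::n_distinct(x$source_gene),
    n_targets = dplyr::n_distinct(x$target_gene[!is.na(x$target_gene)]),
    n_one2one = sum(x$homology_type == "one2one"),
    n_one2many = sum(x$homology_type == "one2many"),
    n_many2many = sum(x$homology_type == "many2many"),
    n_unmapped = sum(x$homology_type == "unmapped"),
    source_species = attr(x, "source_species")
  )
}

#' @export
tidy.ortholog_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
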