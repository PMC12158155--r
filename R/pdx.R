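# Dual-species (xenograft) handling: species detection, selective
# conversion of the non-human block, and merge into a harmonized matrix.

# strip a configured literal prefix; both "_" and "-" separators accepted
.strip_prefix <- function(ids, prefix) {
  if (is.null(prefix) || prefix == "") return(ids)
  stem <- sub("[-_]$", "", prefix)
  for (p in paste0(stem, c("_", "-"))) {
    hit <- startsWith(ids, p)
    ids[hit] <- substring(ids[hit], nchar(p) + 1L)
  }
  ids
}

.has_prefix <- function(ids, prefix) {
  if (is.null(prefix) || prefix == "") return(rep(FALSE, length(ids)))
  stem <- sub("[-_]$", "", prefix)
  startsWith(ids, paste0(stem, "_")) | startsWith(ids, paste0(stem, "-"))
}

# case heuristic for unprefixed symbols shared between genomes:
# all-uppercase alphabetic -> human; Title-case -> nonhuman; else ambiguous
.case_heuristic <- function(ids) {
  out <- rep("ambiguous", length(ids))
  has_lower <- grepl("[a-z]", ids)
  has_upper <- grepl("[A-Z]", ids)
  out[!has_lower & has_upper] <- "human"
  title <- grepl("^[A-Z][a-z0-9.-]*$", ids)
  out[title & has_lower] <- "nonhuman"
  out
}

#' Partition the features of a mixed matrix by species
#'
#' Assigns every feature of a dual-species (e.g. PDX) matrix to human,
#' non-human, or ambiguous. If both genome prefixes are configured (as in
#' multi-genome CellRanger output, e.g. `"GRCh38_"` / `"mm10_"`),
#' assignment is purely by prefix and unprefixed features are ambiguous.
#' Otherwise membership in the ortholog table decides: features among the
#' table's source genes are non-human, among its human targets human; a
#' feature in both or neither namespaces falls back to a case heuristic
#' (all-uppercase symbol is human, Title-case is non-human, anything else
#' ambiguous). The heuristic's use is recorded so downstream reports can
#' flag it.
#'
#' @param x An [expression_matrix()].
#' @param table An [ortholog_table()] (used for membership when prefixes
#'   are not supplied).
#' @param human_prefix,nonhuman_prefix Optional literal genome prefixes
#'   (separator `_` or `-`).
#' @return A `species_partition`: list with `human_features`,
#'   `nonhuman_features`, `ambiguous_features`, and `method`
#'   (`"prefix"`, `"table_membership"` or `"case_heuristic"`).
#' @export
detect_species <- function(x, table = NULL, human_prefix = NULL,
                           nonhuman_prefix = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  ids <- feature_ids(x)
  if (length(ids) == 0L) abort("empty matrix")

  if (!is.null(human_prefix) && !is.null(nonhuman_prefix)) {
    is_h <- .has_prefix(ids, human_prefix)
    is_m <- .has_prefix(ids, nonhuman_prefix)
    species <- ifelse(is_h, "human", ifelse(is_m, "nonhuman", "ambiguous"))
    method <- "prefix"
    if (!any(is_h)) warn(sprintf("prefix '%s' matches zero features",
                                 human_prefix))
    if (!any(is_m)) warn(sprintf("prefix '%s' matches zero features",
                                 nonhuman_prefix))
  } else {
    if (is.null(table)) {
      abort("either both prefixes or an ortholog table must be supplied")
    }
    src <- unique(table$source_gene)
    tgt <- unique(table$target_gene[!is.na(table$target_gene)])
    in_src <- ids %in% src
    in_tgt <- ids %in% tgt
    species <- rep(NA_character_, length(ids))
    species[in_src & !in_tgt] <- "nonhuman"
    species[in_tgt & !in_src] <- "human"
    undecided <- is.na(species)
    species[undecided] <- .case_heuristic(ids[undecided])
    method <- if (mean(undecided) > 0.5) "case_heuristic" else
      "table_membership"
  }

  if (all(species == "ambiguous")) abort("species undecidable")
  structure(
    list(human_features = ids[species == "human"],
         nonhuman_features = ids[species == "nonhuman"],
         ambiguous_features = ids[species == "ambiguous"],
         method = method),
    class = "species_partition"
  )
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf(
    "<species_partition> %d human, %d non-human, %d ambiguous (method: %s)\n",
    length(x$human_features), length(x$nonhuman_features),
    length(x$ambiguous_features), x$method))
  invisible(x)
}

#' @export
tidy.species_partition <- function(x, ...) {
  tibble(
    feature_id = c(x$human_features, x$nonhuman_features,
                   x$ambiguous_features),
    species = c(rep("human", length(x$human_features)),
                rep("nonhuman", length(x$nonhuman_features)),
                rep("ambiguous", length(x$ambiguous_features)))
  )
}

# sum rows of a sparse matrix that share an id; output sorted by id
.sum_by_id <- function(m, ids) {
  uniq <- sort(unique(ids))
  inc <- Matrix::sparseMatrix(i = match(ids, uniq), j = seq_along(ids),
                              x = 1, dims = c(length(uniq), length(ids)),
                              dimnames = list(uniq, NULL))
  out <- inc %*% m
  as(as(out, "generalMatrix"), "CsparseMatrix")
}

#' Convert and harmonize a dual-species (PDX) matrix
#'
#' Splits a mixed human/non-human matrix by species
#' (see [detect_species()]), converts only the non-human block to the
#' human ortholog namespace via [convert_matrix()], and merges the result
#' with the native human counts: the harmonized feature set is the union
#' of (prefix-stripped) human features and converted targets, and rows
#' sharing one human symbol are summed. The harmonized matrix is returned
#' as a second, distinct matrix alongside the untouched original — the
#' original is never overwritten.
#'
#' Ambiguous features are treated as human with a warning by default
#' (for a xenograft the human graft is the analyte); set
#' `ambiguous = "drop"` to discard them instead.
#'
#' @param x The mixed [expression_matrix()].
#' @param table An [ortholog_table()] for the non-human species.
#' @param policy A [conversion_policy()].
#' @param human_prefix,nonhuman_prefix Optional genome prefixes, passed to
#'   [detect_species()] and stripped from the output feature ids.
#' @param ambiguous `"human"` (default) or `"drop"`.
#' @return A `pdx_result`: list with `original` (input, untouched),
#'   `humanized` (harmonized [expression_matrix()]), `partition`,
#'   `conversion` (the `conversion_result` of the non-human block, or NULL
#'   when there was nothing to convert) and `report` (tibble of
#'   per-species totals and merged totals).
#' @export
convert_pdx <- function(x, table, policy = conversion_policy(),
                        human_prefix = NULL, nonhuman_prefix = NULL,
                        ambiguous = c("human", "drop")) {
  ambiguous <- match.arg(ambiguous)
  part <- detect_species(x, table, human_prefix = human_prefix,
                         nonhuman_prefix = nonhuman_prefix)

  h_feats <- part$human_features
  if (length(part$ambiguous_features) > 0L) {
    if (ambiguous == "human") {
      warn(sprintf("%d ambiguous feature(s) treated as human",
                   length(part$ambiguous_features)))
      h_feats <- c(h_feats, part$ambiguous_features)
    } else {
      warn(sprintf("%d ambiguous feature(s) dropped",
                   length(part$ambiguous_features)))
    }
  }

  strip_all <- function(ids) {
    .strip_prefix(.strip_prefix(ids, human_prefix), nonhuman_prefix)
  }

  hm <- x$counts[h_feats, , drop = FALSE]
  rownames(hm) <- strip_all(rownames(hm))
  h_total <- sum(hm)

  conversion <- NULL
  if (length(part$nonhuman_features) > 0L) {
    mm <- x$counts[part$nonhuman_features, , drop = FALSE]
    rownames(mm) <- strip_all(rownames(mm))
    msub <- expression_matrix(mm, obs_meta = x$obs_meta,
                              embeddings = x$embeddings)
    conversion <- convert_matrix(msub, table, policy)
    conv_counts <- conversion$converted$counts
  } else {
    conv_counts <- x$counts[integer(0), , drop = FALSE]
  }
  m_total_in <- sum(x$counts[part$nonhuman_features, , drop = FALSE])
  conv_total <- sum(conv_counts)

  if (length(part$nonhuman_features) == 0L && !anyDuplicated(rownames(hm))) {
    # fixed point: nothing to convert, keep the human block as-is
    merged <- hm
  } else {
    stacked <- rbind(hm, conv_counts)
    merged <- .sum_by_id(stacked, rownames(stacked))
  }
  humanized <- expression_matrix(merged, obs_meta = x$obs_meta,
                                 embeddings = x$embeddings)

  report <- tibble(
    metric = c("n_human_features", "n_nonhuman_features",
               "n_ambiguous_features", "species_method",
               "human_total", "nonhuman_total_input",
               "nonhuman_total_converted", "merged_total"),
    value = as.character(c(length(part$human_features),
                           length(part$nonhuman_features),
                           length(part$ambiguous_features), part$method,
                           h_total, m_total_in, conv_total, sum(merged)))
  )

  structure(
    list(original = x, humanized = humanized, partition = part,
         conversion = conversion, report = report, policy = policy),
    class = "pdx_result"
  )
}

#' @export
print.pdx_result <- function(x, ...) {
  cat(sprintf(
    "<pdx_result> %d features harmonized from %d (human %d + nonhuman %d + ambiguous %d)\n",
    nrow(x$humanized$counts), nrow(x$original$counts),
    length(x$partition$human_features),
    length(x$partition$nonhuman_features),
    length(x$partition$ambiguous_features)))
  invisible(x)
}

#' @export
glance.pdx_result <- function(x, ...) {
  v <- stats::setNames(x$report$value, x$report$metric)
  tibble(
    n_features_in = nrow(x$original$counts),
    n_features_harmonized = nrow(x$humanized$counts),
    human_total = as.numeric(v[["human_total"]]),
    nonhuman_total_input = as.numeric(v[["nonhuman_total_input"]]),
    nonhuman_total_converted = as.numeric(v[["nonhuman_total_converted"]]),
    merged_total = as.numeric(v[["merged_total"]]),
    species_method = v[["species_method"]]
  )
}
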