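# ConversionReport: assembled by convert_matrix(); summarizes mapping and
# count-level quality of one conversion.

#' Build the conversion report for a finished conversion
#'
#' Usually called internally by [convert_matrix()]; exposed so that PDX
#' harmonization and the CLI can rebuild reports.
#'
#' @param x Input [expression_matrix()].
#' @param result A `conversion_result` (report slot may still be NULL).
#' @param table The [ortholog_table()] used.
#' @return A `conversion_report` object.
#' @keywords internal
#' @export
build_conversion_report <- function(x, result, table) {
  policy <- result$policy
  warnings <- character(0)

  fate <- result$plan
  n_source <- nrow(fate)
  n_mapped <- sum(fate$fate != "dropped_unmapped")
  n_out <- nrow(result$converted$counts)
  rate <- 100 * n_mapped / n_source

  tot_x <- sum(x$counts)
  pb <- if (tot_x > 0) 100 * sum(result$converted$counts) / tot_x else NA_real_
  if (!is.na(pb) && pb > 100 && policy$one_to_many == "expand") {
    warnings <- c(warnings, sprintf(
      "pseudobulk efficiency %.2f%% exceeds 100%%: one_to_many=expand replicates counts into multiple targets",
      pb))
  }

  cx <- Matrix::colSums(x$counts)
  cy <- Matrix::colSums(result$converted$counts)
  per_obs <- tibble(obs_id = obs_ids(x),
                    efficiency = unname(ifelse(cx > 0, 100 * cy / cx,
                                               NA_real_)))
  if (any(cx == 0)) {
    warnings <- c(warnings, sprintf(
      "efficiency undefined for zero-count observation(s): %s",
      paste(obs_ids(x)[cx == 0], collapse = ", ")))
  }

  non_integer <- !.is_wholenumber(x$counts@x)
  if (non_integer) {
    warnings <- c(warnings,
                  "input matrix is non-integer (normalized assay?): interpret count efficiencies accordingly")
  }

  bt <- biotype_retention(x, result)

  structure(
    list(
      n_source_features = n_source,
      n_mapped_features = n_mapped,
      n_output_features = n_out,
      gene_mapping_rate = rate,
      pseudobulk_count_efficiency = pb,
      per_obs_efficiency = per_obs,
      biotype_retention = bt,
      policy_echo = unclass(policy)[c("many_to_one", "one_to_many",
                                      "unmapped", "case_insensitive")],
      non_integer_input = non_integer,
      warnings = warnings
    ),
    class = "conversion_report"
  )
}

# report invariant checks, used by tests and print
.validate_report <- function(r) {
  stopifnot(r$gene_mapping_rate >= 0, r$gene_mapping_rate <= 100,
            is.na(r$pseudobulk_count_efficiency) ||
              r$pseudobulk_count_efficiency >= 0,
            all(r$biotype_retention$percent >= 0 &
                  r$biotype_retention$percent <= 100))
  if (!is.na(r$pseudobulk_count_efficiency) &&
      r$pseudobulk_count_efficiency > 100 + 1e-9) {
    stopifnot(identical(r$policy_echo$one_to_many, "expand"))
  }
  invisible(TRUE)
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("<conversion_report>\n")
  cat(sprintf("  features: %d source, %d mapped (%.2f%%), %d output\n",
              x$n_source_features, x$n_mapped_features, x$gene_mapping_rate,
              x$n_output_features))
  cat(sprintf("  pseudobulk count efficiency: %.2f%%\n",
              x$pseudobulk_count_efficiency))
  med <- stats::median(x$per_obs_efficiency$efficiency, na.rm = TRUE)
  cat(sprintf("  per-observation efficiency (median): %.2f%%\n", med))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy a conversion report into a (metric, value) tibble
#'
#' One row per scalar metric; per-observation efficiencies and the biotype
#' table are summarized (mean/median) here and available in full on the
#' report object. Values are full precision; [write_report_tsv()] rounds
#' percentages to 2 decimals for display.
#'
#' @param x A `conversion_report`.
#' @param ... Unused.
#' @export
tidy.conversion_report <- function(x, ...) {
  eff <- x$per_obs_efficiency$efficiency
  tibble(
    metric = c("n_source_features", "n_mapped_features", "n_output_features",
               "gene_mapping_rate", "pseudobulk_count_efficiency",
               "per_obs_efficiency_mean", "per_obs_efficiency_median",
               "n_obs_undefined_efficiency", "non_integer_input",
               "policy_many_to_one", "policy_one_to_many", "policy_unmapped",
               "policy_case_insensitive", "n_warnings"),
    value = c(x$n_source_features, x$n_mapped_features, x$n_output_features,
              x$gene_mapping_rate, x$pseudobulk_count_efficiency,
              mean(eff, na.rm = TRUE), stats::median(eff, na.rm = TRUE),
              sum(is.na(eff)), as.numeric(x$non_integer_input),
              x$policy_echo$many_to_one, x$policy_echo$one_to_many,
              x$policy_echo$unmapped,
              as.character(x$policy_echo$case_insensitive),
              length(x$warnings))
  )
}

#' Write a conversion report as TSV
#'
#' Emits the (metric, value) summary; numeric percentages are printed to 2
#' decimal places. With `per_obs_path`, also writes the per-observation
#' efficiency table; with `biotype_path`, the biotype retention table.
#' All writes are atomic.
#'
#' @param report A `conversion_report`.
#' @param path Output TSV path for the summary.
#' @param per_obs_path Optional path for the per-observation table.
#' @param biotype_path Optional path for the biotype retention table.
#' @export
write_report_tsv <- function(report, path, per_obs_path = NULL,
                             biotype_path = NULL) {
  stopifnot(inherits(report, "conversion_report"))
  df <- tidy(report)
  pct <- grepl("rate|efficiency", df$metric)
  suppressWarnings({
    num <- as.numeric(df$value)
    df$value[pct & !is.na(num)] <- sprintf("%.2f", num[pct & !is.na(num)])
  })
  .atomic_write(path, function(p) {
    readr::write_tsv(df, p, progress = FALSE)
  })
  if (!is.null(per_obs_path)) {
    po <- report$per_obs_efficiency
    po$efficiency <- ifelse(is.na(po$efficiency), NA,
                            sprintf("%.2f", po$efficiency))
    .atomic_write(per_obs_path, function(p) {
      readr::write_tsv(po, p, progress = FALSE)
    })
  }
  if (!is.null(biotype_path)) {
    bt <- report$biotype_retention
    bt$percent <- sprintf("%.2f", bt$percent)
    .atomic_write(biotype_path, function(p) {
      readr::write_tsv(bt, p, progress = FALSE)
    })
  }
  invisible(path)
}

#' Plot a conversion report
#'
#' Histogram of per-observation conversion efficiencies with the
#' pseudobulk efficiency marked.
#'
#' @param object A `conversion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conversion_report <- function(object, ...) {
  df <- object$per_obs_efficiency[!is.na(object$per_obs_efficiency$efficiency), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$efficiency)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$pseudobulk_count_efficiency,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "per-observation conversion efficiency (%)",
                  y = "observations",
                  title = "Conversion efficiency",
                  subtitle = sprintf("pseudobulk = %.2f%% (dashed)",
                                     object$pseudobulk_count_efficiency)) +
    ggplot2::theme_minimal()
}
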