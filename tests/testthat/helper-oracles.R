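# Independent brute-force references used to check the sparse
# implementation. These deliberately use dense matrices and explicit
# loops over the definitions, sharing no code with the package internals.

# Dense reference conversion: materializes the full source->target
# incidence and aggregates row by row.
oracle_convert <- function(m, pairs, many_to_one, one_to_many, unmapped,
                           case_insensitive = FALSE) {
  ids <- rownames(m)
  key <- if (case_insensitive) toupper(ids) else ids
  pairs <- pairs[!is.na(pairs$target_gene) & pairs$target_gene != "", ,
                 drop = FALSE]
  pairs <- unique(pairs[, c("source_gene", "target_gene")])
  pkey <- if (case_insensitive) toupper(pairs$source_gene) else
    pairs$source_gene

  targets_of <- lapply(key, function(k) {
    unique(pairs$target_gene[pkey == k])
  })
  fate <- ifelse(lengths(targets_of) == 0L, "dropped_unmapped", "kept")
  if (one_to_many == "drop") {
    fate[lengths(targets_of) > 1L] <- "dropped_ambiguous"
  }

  e_row <- integer(0); e_tgt <- character(0)
  for (i in which(fate == "kept")) {
    for (t in targets_of[[i]]) {
      e_row <- c(e_row, i); e_tgt <- c(e_tgt, t)
    }
  }

  if (length(e_row) > 0L && many_to_one != "sum") {
    totals <- rowSums(m)
    keep <- rep(TRUE, length(e_row))
    for (t in unique(e_tgt)) {
      g <- which(e_tgt == t)
      if (length(g) >= 2L) {
        if (many_to_one == "drop_group") {
          keep[g] <- FALSE
        } else { # max_total, ties to lexicographically smallest source id
          best <- g[order(-totals[e_row[g]], ids[e_row[g]])][1L]
          keep[setdiff(g, best)] <- FALSE
        }
      }
    }
    e_row <- e_row[keep]; e_tgt <- e_tgt[keep]
    lost <- setdiff(which(fate == "kept"), unique(e_row))
    fate[lost] <- "dropped_ambiguous"
  }

  out_feats <- sort(unique(e_tgt))
  unm_ids <- ids[fate == "dropped_unmapped"]
  if (unmapped == "retain_tagged" && length(unm_ids) > 0L) {
    out_feats <- sort(c(out_feats, paste0("unmapped:", unm_ids)))
  }
  res <- matrix(0, nrow = length(out_feats), ncol = ncol(m),
                dimnames = list(out_feats, colnames(m)))
  if (length(out_feats) == 0L) rownames(res) <- NULL
  for (r in seq_along(e_row)) {
    res[e_tgt[r], ] <- res[e_tgt[r], ] + m[e_row[r], ]
  }
  if (unmapped == "retain_tagged") {
    for (i in which(fate == "dropped_unmapped")) {
      res[paste0("unmapped:", ids[i]), ] <- m[i, ]
    }
  }
  list(matrix = res, fate = fate)
}

# Exhaustive pair enumeration of the Rand index.
oracle_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      total <- total + 1L
      same1 <- a[i] == a[j]
      same2 <- b[i] == b[j]
      if (same1 == same2) agree <- agree + 1L
    }
  }
  agree / total
}

# Brute-force degree scan of cardinality classes over a pair data frame.
oracle_cardinality <- function(pairs) {
  pairs <- pairs[!is.na(pairs$target_gene), , drop = FALSE]
  pairs <- unique(pairs[, c("source_gene", "target_gene")])
  vapply(seq_len(nrow(pairs)), function(r) {
    o <- length(unique(pairs$target_gene[pairs$source_gene ==
                                           pairs$source_gene[r]]))
    i <- length(unique(pairs$source_gene[pairs$target_gene ==
                                           pairs$target_gene[r]]))
    if (o == 1 && i == 1) "one2one"
    else if (o > 1 && i > 1) "many2many"
    else "one2many"
  }, character(1))
}

# Random fixtures -----------------------------------------------------------

# Random non-negative integer matrix with unique ids.
rand_count_matrix <- function(n_genes, n_obs, max_count = 20,
                              density = 0.5) {
  vals <- stats::rbinom(n_genes * n_obs, 1, density) *
    sample.int(max_count, n_genes * n_obs, replace = TRUE)
  m <- matrix(as.double(vals), nrow = n_genes,
              dimnames = list(sprintf("Gene%03d", seq_len(n_genes)),
                              sprintf("obs%02d", seq_len(n_obs))))
  m
}

# Random mapping table mixing all cardinalities plus unmapped sources and
# occasional duplicate rows; target pool is small so many-to-one
# collisions arise naturally.
rand_pair_table <- function(ids, p_unmapped = 0.2, max_targets = 3,
                            target_pool_frac = 0.6) {
  pool <- sprintf("HUM%03d", seq_len(max(2L, ceiling(length(ids) *
                                                       target_pool_frac))))
  rows <- lapply(ids, function(g) {
    if (stats::runif(1) < p_unmapped) {
      return(data.frame(source_gene = g, target_gene = NA_character_))
    }
    k <- sample.int(max_targets, 1)
    data.frame(source_gene = g,
               target_gene = sample(pool, k, replace = FALSE))
  })
  df <- do.call(rbind, rows)
  # occasionally duplicate a row to exercise deduplication
  if (nrow(df) > 2 && stats::runif(1) < 0.5) {
    df <- rbind(df, df[sample.int(nrow(df), 1), ])
  }
  df
}

all_policies <- function() {
  expand.grid(many_to_one = c("sum", "max_total", "drop_group"),
              one_to_many = c("expand", "drop"),
              unmapped = c("drop", "retain_tagged"),
              stringsAsFactors = FALSE)
}

# convert an expression_matrix result to a plain dense matrix for
# comparison against the oracle
dense_of <- function(x) as.matrix(x$counts)
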