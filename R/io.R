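#' Read a 10x-style MTX triplet directory
#'
#' Loads `matrix.mtx`, `features.tsv` (1-3 columns: id, optional name,
#' optional type) and `barcodes.tsv` from `directory`; `.gz`-compressed
#' variants are picked up transparently. Feature row order follows
#' `features.tsv`. Duplicate feature ids are made unique by suffixing
#' `-1`, `-2`, ... with a warning.
#'
#' @param directory Directory containing the triplet.
#' @return An [expression_matrix()].
#' @export
read_10x_mtx <- function(directory) {
  find1 <- function(base) {
    for (cand in c(base, paste0(base, ".gz"))) {
      p <- file.path(directory, cand)
      if (file.exists(p)) return(p)
    }
    abort(sprintf("missing %s(.gz) in %s", base, directory))
  }
  mtx_path <- find1("matrix.mtx")
  feat_path <- find1("features.tsv")
  bc_path <- find1("barcodes.tsv")

  m <- Matrix::readMM(mtx_path)
  # pattern MTX (a binary matrix) reads as an nMatrix without values
  if (methods::is(m, "nsparseMatrix")) m <- as(m, "dMatrix")
  feats <- readr::read_tsv(feat_path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  bcs <- readr::read_tsv(bc_path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(feats) != nrow(m)) {
    abort(sprintf(
      "dimension mismatch: matrix.mtx declares %d rows but features.tsv has %d lines",
      nrow(m), nrow(feats)))
  }
  if (nrow(bcs) != ncol(m)) {
    abort(sprintf(
      "dimension mismatch: matrix.mtx declares %d columns but barcodes.tsv has %d lines",
      ncol(m), nrow(bcs)))
  }
  if (length(m@x) > 0L && min(m@x) < 0) {
    abort("negative entry in matrix.mtx")
  }
  rownames(m) <- .dedup_ids(feats[[1L]], "feature")
  colnames(m) <- .dedup_ids(bcs[[1L]], "barcode")
  fm <- tibble(feature_id = rownames(m))
  if (ncol(feats) >= 2L) fm$feature_name <- feats[[2L]]
  if (ncol(feats) >= 3L) fm$feature_type <- feats[[3L]]
  expression_matrix(m, feature_meta = fm)
}

#' Write an expression matrix as a 10x-style MTX triplet
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `directory`
#' (created if needed), exactly in the form [read_10x_mtx()] accepts, so a
#' write/read cycle reproduces ids, ordering and values bit-exactly. Files
#' are written atomically (temp file + rename).
#'
#' @param x An [expression_matrix()].
#' @param directory Output directory.
#' @param gzip Compress the three files with gzip.
#' @export
write_10x_mtx <- function(x, directory, gzip = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  .atomic_write(file.path(directory, paste0("matrix.mtx", ext)), function(p) {
    if (gzip) {
      tmp <- tempfile(fileext = ".mtx")
      on.exit(unlink(tmp), add = TRUE)
      Matrix::writeMM(x$counts, tmp)
      con_in <- file(tmp, "rb"); con_out <- gzfile(p, "wb")
      writeBin(readBin(con_in, "raw", file.size(tmp)), con_out)
      close(con_in); close(con_out)
    } else {
      Matrix::writeMM(x$counts, p)
    }
  })
  fm <- x$feature_meta
  feat_out <- tibble(id = feature_ids(x))
  if (!is.null(fm) && "feature_name" %in% names(fm)) {
    feat_out$name <- fm$feature_name
  }
  if (!is.null(fm) && "feature_type" %in% names(fm)) {
    if (!"name" %in% names(feat_out)) feat_out$name <- feat_out$id
    feat_out$type <- fm$feature_type
  }
  .atomic_write(file.path(directory, paste0("features.tsv", ext)), function(p) {
    readr::write_tsv(feat_out, p, col_names = FALSE, progress = FALSE)
  })
  .atomic_write(file.path(directory, paste0("barcodes.tsv", ext)), function(p) {
    readr::write_tsv(tibble(bc = obs_ids(x)), p, col_names = FALSE,
                     progress = FALSE)
  })
  invisible(directory)
}

#' Read and write dense CSV count matrices
#'
#' The first CSV column holds feature ids and the header row holds
#' observation ids. `transpose = TRUE` reads matrices stored observations x
#' features. Non-numeric cells raise an error naming the offending row and
#' column; duplicate feature ids are suffixed with a warning.
#'
#' @param path CSV file path (gzip transparent).
#' @param transpose Input is oriented observations x features.
#' @return An [expression_matrix()].
#' @export
read_dense_csv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("dense CSV needs an id column plus data columns")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-numeric cell at row %d (feature '%s'), column '%s'",
                  bad[1L, 1L], ids[bad[1L, 1L]],
                  colnames(vals)[bad[1L, 2L]]))
  }
  num[is.na(num)] <- 0
  rownames(num) <- ids
  if (transpose) num <- base::t(num)
  rownames(num) <- .dedup_ids(rownames(num), "feature")
  colnames(num) <- .dedup_ids(colnames(num), "observation")
  expression_matrix(num)
}

#' @rdname read_dense_csv
#' @param x An [expression_matrix()].
#' @export
write_dense_csv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  dense <- as.matrix(x$counts)
  df <- tibble::as_tibble(dense, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(feature_id = rownames(dense)), df)
  .atomic_write(path, function(p) {
    readr::write_csv(df, p, progress = FALSE)
  })
  invisible(path)
}

#' Read per-observation metadata
#'
#' A TSV with an `obs_id` column (or whose first column is taken as obs_id)
#' plus arbitrary annotation columns such as cluster labels or spatial
#' coordinates.
#'
#' @param path TSV path.
#' @return A tibble with an `obs_id` first column.
#' @export
read_obs_meta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"obs_id" %in% names(df)) names(df)[1L] <- "obs_id"
  df$obs_id <- as.character(df$obs_id)
  dplyr::relocate(df, "obs_id")
}
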