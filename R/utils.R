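# Internal helpers shared across modules.

# strtrim-like whitespace trim that tolerates NA
.trim <- function(x) {
  x <- as.character(x)
  out <- trimws(x)
  out[is.na(x)] <- NA_character_
  out
}

# fold identifiers to upper case when case-insensitive matching is requested
.fold_case <- function(x, case_insensitive) {
  if (isTRUE(case_insensitive)) toupper(x) else x
}

.assert_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# atomic file write: write to a temp file in the same directory, then rename
.atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".tmp-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # rename across filesystems can fail; fall back to copy + remove
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# deterministic total of a sparse or dense matrix
.total <- function(m) sum(m)

.is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
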