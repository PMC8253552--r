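# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; if seed is NULL the current RNG stream is used (and advanced).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Coerce a counts input (tibble/data.frame with an id column + numeric sample
# columns, or an already-numeric matrix) into a numeric matrix with feature
# ids as rownames. Coordinate columns (chrom/start/end/strand/width) are
# dropped; the id column is `peak_id`/`feature_id` when present, otherwise
# the first non-numeric column.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) rownames(m) <- paste0("feature_", seq_len(nrow(m)))
  } else if (is.data.frame(counts)) {
    coord_cols <- intersect(c("chrom", "start", "end", "strand", "width"),
                            names(counts))
    id_col <- intersect(c("peak_id", "feature_id"), names(counts))[1]
    body <- counts[, setdiff(names(counts), coord_cols), drop = FALSE]
    is_num <- vapply(body, is.numeric, logical(1))
    if (is.na(id_col) && any(!is_num)) id_col <- names(body)[which(!is_num)[1]]
    ids <- if (!is.na(id_col)) as.character(body[[id_col]]) else
      paste0("feature_", seq_len(nrow(body)))
    sample_cols <- setdiff(names(body)[is_num], id_col)
    if (length(sample_cols) == 0) abort("No numeric sample columns found in `counts`.")
    m <- as.matrix(body[, sample_cols, drop = FALSE])
    rownames(m) <- ids
  } else {
    abort("`counts` must be a data frame or a numeric matrix.")
  }
  if (anyNA(m)) abort("Count matrix contains missing values.")
  if (any(m < 0)) abort("Count matrix contains negative values.")
  ids <- rownames(m)
  if (anyDuplicated(ids)) abort("Feature ids must be unique.")
  storage.mode(m) <- "double"
  m
}

# Validate a two-condition design against the columns of a count matrix.
# Returns a list(cols1, cols2, labels = c(cond_i, cond_j), condition) where
# cols1/cols2 index into colnames(m).
check_design <- function(m, design) {
  if (!is.data.frame(design) || !all(c("sample_id", "condition") %in% names(design))) {
    abort("`design` must be a data frame with columns `sample_id` and `condition`.")
  }
  design <- as_tibble(design)
  if (anyDuplicated(design$sample_id)) abort("Duplicated sample_id in design.")
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from design: ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(design$sample_id, colnames(m))
  if (length(extra) > 0) {
    abort(paste0("Design references samples absent from counts: ",
                 paste(extra, collapse = ", ")))
  }
  cond <- setNames(as.character(design$condition), design$sample_id)[colnames(m)]
  labels <- sort(unique(cond))
  if (length(labels) != 2) {
    abort(paste0("Design must have exactly two conditions, found ",
                 length(labels), "."))
  }
  cols1 <- which(cond == labels[1])
  cols2 <- which(cond == labels[2])
  if (length(cols1) < 2 || length(cols2) < 2) {
    abort("Each condition needs at least 2 samples.")
  }
  list(cols1 = cols1, cols2 = cols2, labels = labels, condition = cond)
}

# Atomic write: render to a temp file in the same directory, then rename.
write_atomic <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(x, path) {
  write_atomic(function(tmp) readr::write_tsv(x, tmp, progress = FALSE), path)
}

cli_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
}
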