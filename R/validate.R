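#' Validate a set of input files before a run
#'
#' Checks existence, parseability, coordinate sanity and sample-id
#' consistency across peak, count and design files without raising errors;
#' every problem becomes a row of the returned report.
#'
#' @param peak_files Character vector of BED/narrowPeak paths (optional).
#' @param counts_file Count-matrix TSV path (optional).
#' @param design_file Design TSV path (optional).
#' @return A tibble with columns `file`, `issue`; zero rows when everything
#'   checks out.
#' @export
validate_inputs <- function(peak_files = character(), counts_file = NULL,
                            design_file = NULL) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1]] <<- tibble(file = file, issue = issue)
  }
  for (pf in peak_files) {
    if (!file.exists(pf)) {
      note(pf, "file not found")
      next
    }
    tryCatch(read_peaks(pf), error = function(e) note(pf, conditionMessage(e)))
  }
  counts <- NULL
  if (!is.null(counts_file)) {
    if (!file.exists(counts_file)) {
      note(counts_file, "file not found")
    } else {
      counts <- tryCatch(read_count_matrix(counts_file), error = function(e) {
        note(counts_file, conditionMessage(e))
        NULL
      })
    }
  }
  if (!is.null(design_file)) {
    if (!file.exists(design_file)) {
      note(design_file, "file not found")
    } else {
      design <- tryCatch(read_design(design_file), error = function(e) {
        note(design_file, conditionMessage(e))
        NULL
      })
      if (!is.null(design)) {
        if (length(unique(design$condition)) != 2) {
          note(design_file, "design must define exactly two conditions")
        }
        if (!is.null(counts)) {
          sample_cols <- colnames(as_count_matrix(counts))
          extra <- setdiff(design$sample_id, sample_cols)
          for (s in extra) {
            note(design_file, paste0("sample ", s, " absent from count matrix"))
          }
        }
      }
    }
  }
  if (length(issues) == 0) {
    tibble(file = character(), issue = character())
  } else {
    bind_rows(issues)
  }
}
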