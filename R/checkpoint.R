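#' Expected partial-result file names of an M x N grid
#'
#' Each task writes `results.<i1>_<i2>`; a complete run has exactly
#' `m * n` such files.
#'
#' @param m,n Query- and database-chunk counts.
#' @return Character vector of `m * n` names, task-ID order.
#' @export
expected_result_names <- function(m, n) {
  check_count(m, "m"); check_count(n, "n")
  grid <- expand.grid(i1 = seq_len(m), i2 = seq_len(n))
  result_name(grid$i1, grid$i2)
}

parse_result_name <- function(name) {
  m <- regmatches(name, regexec("^results\\.([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m) != 3)
    dseg_stop(sprintf("unparseable result name: '%s'", name),
              "dualseg_error_bad_result_name")
  c(i1 = as.integer(m[2]), i2 = as.integer(m[3]))
}

#' Identify missing partial results
#'
#' Compares the expected result names against the names actually present
#' and maps the difference back to (i1, i2) chunk pairs. Present names
#' not in the expected set are ignored with a warning (shared scratch
#' directories accumulate strays).
#'
#' @param expected Character vector from [expected_result_names()].
#' @param present Character vector of names found on disk.
#' @return Data.frame with columns `i1`, `i2`, sorted by (i2, i1), i.e.
#'   task-ID order.
#' @export
find_missing <- function(expected, present) {
  extras <- setdiff(present, expected)
  if (length(extras) > 0)
    dseg_warn(paste("ignoring unexpected result file(s):",
                    paste(utils::head(extras, 5), collapse = ", ")),
              "dualseg_warning_extra_results")
  miss <- setdiff(expected, present)
  if (length(miss) == 0)
    return(data.frame(i1 = integer(), i2 = integer()))
  pairs <- t(vapply(miss, parse_result_name, integer(2)))
  out <- data.frame(i1 = pairs[, "i1"], i2 = pairs[, "i2"])
  out <- out[order(out$i2, out$i1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Task IDs to rerun for a set of missing chunk pairs
#'
#' Converts missing (i1, i2) pairs to task IDs (ascending, deduplicated)
#' — the content of a `failed.lst` file, one task ID per line, which the
#' run and script-emission commands accept as a task filter.
#'
#' @param missing Data.frame with columns `i1`, `i2` ([find_missing()]).
#' @param m Query-chunk count.
#' @param path Optional path: when given, the IDs are written there, one
#'   per line.
#' @return Integer vector of task IDs.
#' @export
rerun_manifest <- function(missing, m, path = NULL) {
  ids <- if (nrow(missing) == 0) integer() else
    sort(unique(as.integer(task_id_from_pair(missing$i1, missing$i2, m))))
  if (!is.null(path)) writeLines(as.character(ids), path)
  ids
}

#' Verify a run's partial results and build a rerun manifest
#'
#' Checks that every task of the plan produced its result file. Zero-byte
#' files count as failed by default (a killed task can leave an empty
#' file); `require_nonempty = FALSE` restores existence-only semantics.
#' When failures exist and `failed_lst` is given, the failed task IDs are
#' written there one per line.
#'
#' @param plan A [build_plan()] job plan.
#' @param results_dir Directory holding the `results.<i1>_<i2>` files.
#' @param failed_lst Optional path for the rerun manifest.
#' @param require_nonempty Treat zero-byte result files as failures.
#' @return A `run_report` list: `complete` (logical), `expected_count`,
#'   `present_count`, `missing` (pairs data.frame), `failed_task_ids`.
#' @export
verify_run <- function(plan, results_dir, failed_lst = NULL,
                       require_nonempty = TRUE) {
  if (!dir.exists(results_dir))
    dseg_stop(sprintf("results directory not found: %s", results_dir),
              "dualseg_error_missing_dir")
  expected <- expected_result_names(plan$m, plan$n)
  files <- list.files(results_dir, pattern = "^results\\.")
  if (require_nonempty) {
    sizes <- file.size(file.path(results_dir, files))
    files <- files[sizes > 0]
  }
  missing <- find_missing(expected, files)
  ids <- rerun_manifest(missing, plan$m,
                        path = if (nrow(missing) > 0) failed_lst else NULL)
  structure(list(complete = nrow(missing) == 0,
                 expected_count = length(expected),
                 present_count = length(expected) - nrow(missing),
                 missing = missing, failed_task_ids = ids),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  if (x$complete) {
    cat(sprintf("Run complete: all %d partial result file(s) present.\n",
                x$expected_count))
  } else {
    cat(sprintf("Run incomplete: %d of %d partial result file(s) missing.\n",
                nrow(x$missing), x$expected_count))
    cat("Failed task ID(s):", paste(x$failed_task_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a failed.lst task filter
#'
#' @param path Text file, one task ID per line.
#' @return Sorted integer vector of task IDs.
#' @export
read_task_filter <- function(path) {
  if (!file.exists(path))
    dseg_stop(sprintf("task filter file not found: %s", path),
              "dualseg_error_missing_file")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  ids <- suppressWarnings(as.integer(lines))
  if (any(is.na(ids)))
    dseg_stop(sprintf("non-integer line in task filter %s", path),
              "dualseg_error_bad_task_filter")
  sort(unique(ids))
}
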