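#' Number of array-job tasks for an M x N dual segmentation
#'
#' With the query set split into `m` chunks and the database into `n`
#' chunks, every (query-chunk, db-chunk) pair is one independent task, so
#' the array job has `m * n` tasks.
#'
#' @param m Number of query chunks (>= 1).
#' @param n Number of database chunks (>= 1).
#' @return `m * n`.
#' @export
num_tasks <- function(m, n) {
  check_count(m, "m"); check_count(n, "n")
  as.numeric(m) * as.numeric(n)
}

check_count <- function(x, what) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    dseg_stop(sprintf("%s must be a positive integer (got %s)", what,
                      paste(x, collapse = ",")),
              "dualseg_error_bad_index")
  invisible(x)
}

#' Task ID of a (query-chunk, db-chunk) pair
#'
#' Implements the array-job indexing convention
#' `task_id = (i2 - 1) * m + i1`: the query-chunk index `i1` varies
#' fastest, so tasks `1..m` all use db chunk 1, tasks `m+1..2m` use db
#' chunk 2, and so on. This is the scheme a scheduler task-ID variable
#' (e.g. `SGE_TASK_ID`) is decoded with inside an emitted array script.
#'
#' @param i1 Query-chunk index, `1 <= i1 <= m`.
#' @param i2 Database-chunk index, `>= 1`.
#' @param m Number of query chunks.
#' @return The task ID (vectorized over `i1`, `i2`).
#' @seealso [pair_from_task_id()]
#' @export
task_id_from_pair <- function(i1, i2, m) {
  check_count(m, "m")
  if (any(i1 < 1 | i1 > m | i1 != floor(i1)))
    dseg_stop(sprintf("i1 out of range 1..%d", m), "dualseg_error_bad_index")
  if (any(i2 < 1 | i2 != floor(i2)))
    dseg_stop("i2 must be >= 1", "dualseg_error_bad_index")
  (i2 - 1) * m + i1
}

#' Decode a task ID back into its (i1, i2) chunk pair
#'
#' Inverse of [task_id_from_pair()]: `i1 = ((task_id - 1) mod m) + 1`,
#' `i2 = ((task_id - 1) div m) + 1`.
#'
#' @param task_id Task ID in `1..m*n` (vectorized).
#' @param m Number of query chunks.
#' @param n Number of database chunks.
#' @return A list with integer vectors `i1` and `i2`.
#' @export
pair_from_task_id <- function(task_id, m, n) {
  check_count(m, "m"); check_count(n, "n")
  if (any(task_id < 1 | task_id > m * n | task_id != floor(task_id)))
    dseg_stop(sprintf("task_id out of range 1..%d", m * n),
              "dualseg_error_bad_index")
  list(i1 = as.integer((task_id - 1) %% m + 1),
       i2 = as.integer((task_id - 1) %/% m + 1))
}

result_name <- function(i1, i2) sprintf("results.%d_%d", i1, i2)

#' Build an executable job plan from query and database split manifests
#'
#' Enumerates all `m * n` tasks in task-ID order (query-chunk index
#' fastest), records the chunk paths and result file name of each task,
#' and computes per-chunk database statistics alongside the global ones.
#' The global statistics ride with every task so fragment searches can
#' compute E-values against the full database.
#'
#' @param query_manifest [split_fasta()] manifest of the query set.
#' @param db_manifest [split_fasta()] manifest of the database.
#' @param threads_per_task CPUs a scheduler should allot each task
#'   (metadata for script emission and slot accounting; the built-in
#'   backend is single-threaded per task).
#' @param global_db_stats [compute_db_stats()] of the original, unsplit
#'   database. Defaults to the field-wise sum over the database chunks.
#' @return A `job_plan` object: list with `m`, `n`, `task_count`,
#'   `threads_per_task`, `total_slots`, `tasks` (data.frame with columns
#'   `task_id`, `i1`, `i2`, `query_chunk_path`, `db_chunk_path`,
#'   `result_name`), `global_db_stats`, `per_chunk_db_stats`,
#'   `query_chunk_paths`.
#' @export
build_plan <- function(query_manifest, db_manifest, threads_per_task = 1L,
                       global_db_stats = NULL) {
  if (!inherits(query_manifest, "split_manifest") ||
      !inherits(db_manifest, "split_manifest"))
    dseg_stop("query_manifest and db_manifest must be split manifests",
              "dualseg_error_bad_manifest")
  check_count(threads_per_task, "threads_per_task")
  missing_files <- c(query_manifest$chunk_paths, db_manifest$chunk_paths)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files) > 0)
    dseg_stop(paste("chunk files missing:",
                    paste(missing_files, collapse = ", ")),
              "dualseg_error_bad_manifest")
  m <- query_manifest$chunk_count
  n <- db_manifest$chunk_count
  per_chunk <- lapply(db_manifest$chunk_paths, compute_db_stats)
  if (is.null(global_db_stats))
    global_db_stats <- db_stats(
      sum(vapply(per_chunk, `[[`, numeric(1), "num_sequences")),
      sum(vapply(per_chunk, `[[`, numeric(1), "total_length")))
  grid <- expand.grid(i1 = seq_len(m), i2 = seq_len(n))  # i1 fastest
  tasks <- data.frame(
    task_id = task_id_from_pair(grid$i1, grid$i2, m),
    i1 = grid$i1, i2 = grid$i2,
    query_chunk_path = query_manifest$chunk_paths[grid$i1],
    db_chunk_path = db_manifest$chunk_paths[grid$i2],
    result_name = result_name(grid$i1, grid$i2),
    stringsAsFactors = FALSE)
  tasks <- tasks[order(tasks$task_id), , drop = FALSE]
  rownames(tasks) <- NULL
  structure(list(
    m = m, n = n, task_count = m * n,
    threads_per_task = as.integer(threads_per_task),
    total_slots = m * n * as.integer(threads_per_task),
    tasks = tasks,
    global_db_stats = global_db_stats,
    per_chunk_db_stats = per_chunk,
    query_chunk_paths = query_manifest$chunk_paths),
    class = "job_plan")
}

#' @export
print.job_plan <- function(x, ...) {
  cat(sprintf(
    "Dual-segmentation job plan: %d x %d = %d task(s), %d thread(s)/task, %d total slot(s)\n",
    x$m, x$n, x$task_count, x$threads_per_task, x$total_slots))
  print(x$global_db_stats)
  invisible(x)
}

#' Persist a job plan as JSON
#'
#' @param plan A `job_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_plan <- function(plan, path) {
  x <- unclass(plan)
  x$global_db_stats <- unclass(x$global_db_stats)
  x$per_chunk_db_stats <- lapply(x$per_chunk_db_stats, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a job plan saved by [save_plan()]
#'
#' @param path JSON plan path.
#' @return A `job_plan`.
#' @export
load_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tasks <- as.data.frame(x$tasks, stringsAsFactors = FALSE)
  x$global_db_stats <- db_stats(x$global_db_stats$num_sequences,
                                x$global_db_stats$total_length)
  x$per_chunk_db_stats <- lapply(seq_len(nrow(x$per_chunk_db_stats)),
    function(i) db_stats(x$per_chunk_db_stats$num_sequences[i],
                         x$per_chunk_db_stats$total_length[i]))
  structure(x, class = "job_plan")
}
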