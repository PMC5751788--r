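#' Execute one task of a job plan
#'
#' Reads the task's query and database chunks, searches them with the
#' built-in backend, assigns bit scores and E-values against the
#' *global* database statistics (so the fragment search reports E-values
#' as if it had searched the whole database), and writes the task's
#' `results.<i1>_<i2>` file atomically (temp name + rename) — an
#' interrupted task never leaves a complete-looking partial file.
#'
#' @param task One row of `plan$tasks`.
#' @param plan The job plan.
#' @param results_dir Output directory.
#' @param scoring A [scoring_scheme()].
#' @param base_freqs Background base frequencies.
#' @param both_strands Also search reverse complements.
#' @param length_adjust Apply the edge-effect correction.
#' @return Invisibly, the number of hits written.
#' @export
run_one_task <- function(task, plan, results_dir,
                         scoring = scoring_scheme(),
                         base_freqs = rep(0.25, 4), both_strands = FALSE,
                         length_adjust = TRUE) {
  queries <- read_fasta(task$query_chunk_path)
  subjects <- read_fasta(task$db_chunk_path)
  hits <- search_chunk(queries, subjects, scoring,
                       both_strands = both_strands)
  params <- karlin_params(scoring, base_freqs)
  fragment_stats <- plan$per_chunk_db_stats[[task$i2]]
  query_lengths <- stats::setNames(nchar(queries$seq), queries$id)
  if (nrow(hits) > 0)
    hits <- globalize_hits(hits, fragment_stats, plan$global_db_stats,
                           query_lengths, params,
                           length_adjust = length_adjust)
  hits <- hits[order(match(hits$query_id, queries$id), hits$evalue,
                     -hits$bit_score, hits$subject_id, hits$q_start,
                     hits$s_start), , drop = FALSE]
  final <- file.path(results_dir, task$result_name)
  tmp <- paste0(final, ".tmp.", Sys.getpid())
  write_tabular(hits, tmp)
  if (!suppressWarnings(file.rename(tmp, final)))
    dseg_stop(sprintf("cannot move %s into place", tmp),
              "dualseg_error_unwritable")
  invisible(nrow(hits))
}

#' Run a job plan locally with a worker pool
#'
#' Executes the plan's tasks with `workers` independent processes; the
#' only coordination is the filesystem, mirroring the array-job model,
#' so tasks may complete in any order and outputs are identical for any
#' worker count. With `resume = TRUE`, tasks whose non-empty result file
#' already exists are skipped. `task_filter` restricts execution to the
#' given task IDs (e.g. a `failed.lst` read with [read_task_filter()]).
#' A backend failure is recorded per task and the run continues.
#'
#' @param plan The [build_plan()] job plan.
#' @param results_dir Output directory (created if needed).
#' @param scoring A [scoring_scheme()].
#' @param workers Number of worker processes.
#' @param resume Skip tasks with an existing non-empty result file.
#' @param task_filter Optional integer vector of task IDs to run.
#' @param base_freqs,both_strands,length_adjust Passed to
#'   [run_one_task()].
#' @return A `run_report`-like list: `executed`, `skipped`, `failed`
#'   (task-ID vectors) and `elapsed` seconds.
#' @export
run_local <- function(plan, results_dir, scoring = scoring_scheme(),
                      workers = 1L, resume = FALSE, task_filter = NULL,
                      base_freqs = rep(0.25, 4), both_strands = FALSE,
                      length_adjust = TRUE) {
  check_count(workers, "workers")
  if (!dir.exists(results_dir) && !dir.create(results_dir, recursive = TRUE))
    dseg_stop(sprintf("cannot create %s", results_dir),
              "dualseg_error_unwritable")
  tasks <- plan$tasks
  if (!is.null(task_filter)) {
    unknown <- setdiff(task_filter, tasks$task_id)
    if (length(unknown) > 0)
      dseg_stop(paste("task filter IDs outside the plan:",
                      paste(unknown, collapse = ", ")),
                "dualseg_error_bad_task_filter")
    tasks <- tasks[tasks$task_id %in% task_filter, , drop = FALSE]
  }
  skipped <- integer()
  if (resume) {
    existing <- file.path(results_dir, tasks$result_name)
    done <- file.exists(existing) & file.size(existing) > 0
    skipped <- tasks$task_id[done]
    tasks <- tasks[!done, , drop = FALSE]
  }
  t0 <- Sys.time()
  one <- function(i) {
    task <- tasks[i, , drop = FALSE]
    tryCatch({
      run_one_task(task, plan, results_dir, scoring,
                   base_freqs = base_freqs, both_strands = both_strands,
                   length_adjust = length_adjust)
      NA_integer_
    }, error = function(e) task$task_id)
  }
  failed <- if (nrow(tasks) == 0) integer()
  else if (workers == 1L) vapply(seq_len(nrow(tasks)), one, integer(1))
  else unlist(parallel::mclapply(seq_len(nrow(tasks)), one,
                                 mc.cores = workers))
  failed <- failed[!is.na(failed)]
  list(executed = setdiff(tasks$task_id, failed), skipped = skipped,
       failed = failed,
       elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Emit an SGE or Slurm array-job script for a plan
#'
#' The script declares a task range `1..M*N` (or, with a task filter,
#' the explicit ID list), decodes the scheduler's task-ID variable into
#' the (i1, i2) chunk pair with the inverse of
#' `task_id = (i2 - 1) * M + i1`, renders the backend command template
#' for that pair, and writes `results.<i1>_<i2>` atomically. The
#' template uses the same placeholders as [render_external_command()];
#' inside the script they are substituted with shell variables.
#'
#' @param plan The job plan.
#' @param dialect `"sge"` or `"slurm"`.
#' @param backend_template Command template with `{query}`, `{db}`,
#'   `{out}` and optionally `{dbseqnum}`, `{dblen}`, `{threads}`.
#' @param task_filter Optional integer vector of task IDs.
#' @param job_name Scheduler job name.
#' @return The script text (also usable via `writeLines`).
#' @export
emit_array_script <- function(plan, dialect = c("sge", "slurm"),
                              backend_template =
                                "dualseg-task {query} {db} {out} {dbseqnum}",
                              task_filter = NULL, job_name = "dualseg") {
  dialect <- match.arg(dialect)
  spec <- if (is.null(task_filter)) sprintf("1-%d", plan$task_count)
          else paste(sort(unique(task_filter)), collapse = ",")
  header <- switch(dialect,
    sge = c("#!/bin/sh", "#$ -cwd", "#$ -S /bin/sh",
            sprintf("#$ -N %s", job_name),
            sprintf("#$ -pe thread %d", plan$threads_per_task),
            sprintf("#$ -t %s", spec),
            "TASK_ID=$SGE_TASK_ID"),
    slurm = c("#!/bin/sh",
              sprintf("#SBATCH --job-name=%s", job_name),
              sprintf("#SBATCH --cpus-per-task=%d", plan$threads_per_task),
              sprintf("#SBATCH --array=%s", spec),
              "TASK_ID=$SLURM_ARRAY_TASK_ID"))
  qpaths <- plan$tasks$query_chunk_path
  dpaths <- plan$tasks$db_chunk_path
  qprefix <- sub("_[0-9]+$", "", qpaths[1])
  dprefix <- sub("_[0-9]+$", "", dpaths[1])
  shell_task <- list(query_chunk_path = '"$IN"', db_chunk_path = '"$IN_DB"',
                     result_name = '"$OUT.tmp.$$"')
  cmd <- render_external_command(backend_template, shell_task,
                                 plan$global_db_stats,
                                 threads = plan$threads_per_task)
  body <- c(
    sprintf("M=%d", plan$m),
    "I1=$(( (TASK_ID - 1) % M + 1 ))",
    "I2=$(( (TASK_ID - 1) / M + 1 ))",
    sprintf('IN="%s_${I1}"', qprefix),
    sprintf('IN_DB="%s_${I2}"', dprefix),
    'OUT="results.${I1}_${I2}"',
    cmd,
    'mv "$OUT.tmp.$$" "$OUT"')
  paste(c(header, body, ""), collapse = "\n")
}

#' Run the whole dual-segmentation pipeline in one call
#'
#' Split both inputs, build the plan, run all tasks locally, verify, and
#' merge — the library-level equivalent of the CLI sequence
#' `split / plan / run / verify / merge`.
#'
#' @param query_path,db_path Input FASTA files.
#' @param work_dir Working directory for chunks and partial results.
#' @param query_chunk_bytes,db_chunk_bytes Chunk byte budgets.
#' @param scoring A [scoring_scheme()].
#' @param workers Local worker processes.
#' @param top_k,evalue_cutoff Merge parameters.
#' @param threads_per_task Slot metadata for the plan.
#' @param base_freqs,both_strands,length_adjust Backend parameters.
#' @return List with `plan`, `run`, `hits`, `merged_path`.
#' @export
run_pipeline <- function(query_path, db_path, work_dir,
                         query_chunk_bytes = 50000, db_chunk_bytes = 50000,
                         scoring = scoring_scheme(), workers = 1L,
                         top_k = 500, evalue_cutoff = 10,
                         threads_per_task = 1L,
                         base_freqs = rep(0.25, 4), both_strands = FALSE,
                         length_adjust = TRUE) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  qman <- split_fasta(query_path, query_chunk_bytes,
                      file.path(work_dir, "query_split"), "query")
  dman <- split_fasta(db_path, db_chunk_bytes,
                      file.path(work_dir, "db_split"), "db")
  plan <- build_plan(qman, dman, threads_per_task = threads_per_task,
                     global_db_stats = compute_db_stats(db_path))
  results_dir <- file.path(work_dir, "results")
  run <- run_local(plan, results_dir, scoring, workers = workers,
                   base_freqs = base_freqs, both_strands = both_strands,
                   length_adjust = length_adjust)
  hits <- merge_results(plan, results_dir, scoring, top_k = top_k,
                        evalue_cutoff = evalue_cutoff,
                        base_freqs = base_freqs,
                        length_adjust = length_adjust)
  merged_path <- file.path(work_dir, "merged.tsv")
  write_tabular(hits, merged_path)
  list(plan = plan, run = run, hits = hits, merged_path = merged_path)
}
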