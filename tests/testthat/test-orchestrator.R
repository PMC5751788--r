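plan_setup <- function(seed = 11, q_bytes = 2000, db_bytes = 4000) {
  fix <- small_fixture_dir(seed = seed)
  work <- tempfile("work")
  qman <- split_fasta(fix$query, q_bytes, file.path(work, "qs"), "query")
  dman <- split_fasta(fix$db, db_bytes, file.path(work, "ds"), "db")
  plan <- build_plan(qman, dman,
                     global_db_stats = compute_db_stats(fix$db))
  c(fix, list(work = work, plan = plan,
              results = file.path(work, "results")))
}

test_that("run_local completes the grid and resume skips finished tasks", {
  s <- plan_setup()
  plan <- s$plan
  rep <- run_local(plan, s$results)
  expect_equal(sort(rep$executed), plan$tasks$task_id)
  expect_length(rep$failed, 0)
  expect_true(all(file.exists(file.path(s$results,
                                        plan$tasks$result_name))))
  expect_true(verify_run(plan, s$results)$complete)

  # delete two results, resume executes exactly those
  gone <- plan$tasks$task_id[c(1, nrow(plan$tasks))]
  unlink(file.path(s$results,
                   plan$tasks$result_name[plan$tasks$task_id %in% gone]))
  rep2 <- run_local(plan, s$results, resume = TRUE)
  expect_equal(sort(rep2$executed), sort(gone))
  expect_equal(sort(rep2$skipped), setdiff(plan$tasks$task_id, gone))
})

test_that("a task filter restricts execution to the listed task IDs", {
  s <- plan_setup(seed = 17, q_bytes = 600, db_bytes = 3000)
  plan <- s$plan
  expect_gte(plan$task_count, 4)
  pick <- plan$tasks$task_id[c(2, 4)]
  rep <- run_local(plan, s$results, task_filter = pick)
  expect_equal(sort(rep$executed), sort(pick))
  made <- list.files(s$results)
  expect_setequal(made,
                  plan$tasks$result_name[plan$tasks$task_id %in% pick])
  expect_error(run_local(plan, s$results, task_filter = 10000L),
               class = "dualseg_error_bad_task_filter")
})

test_that("worker count never changes the merged output", {
  s <- plan_setup(seed = 23)
  plan <- s$plan
  run_local(plan, s$results, workers = 1)
  h1 <- merge_results(plan, s$results)
  res4 <- file.path(s$work, "results4")
  run_local(plan, res4, workers = 4)
  h4 <- merge_results(plan, res4)
  expect_identical(h1, h4)
  f1 <- file.path(s$work, "m1.tsv"); f4 <- file.path(s$work, "m4.tsv")
  write_tabular(h1, f1); write_tabular(h4, f4)
  expect_identical(readLines(f1), readLines(f4))
})

test_that("array scripts declare the grid range and decode task IDs correctly", {
  s <- plan_setup(seed = 11)
  plan <- s$plan
  sge <- emit_array_script(plan, "sge")
  expect_match(sge, sprintf("#\\$ -t 1-%d\n", plan$task_count))
  expect_match(sge, "SGE_TASK_ID", fixed = TRUE)
  slurm <- emit_array_script(plan, "slurm")
  expect_match(slurm, sprintf("--array=1-%d", plan$task_count), fixed = TRUE)
  filt <- emit_array_script(plan, "slurm", task_filter = c(3L, 1L, 3L))
  expect_match(filt, "--array=1,3", fixed = TRUE)
  expect_error(emit_array_script(plan, "pbs"))

  # evaluate the emitted shell arithmetic for every task ID and compare
  # with the reference decoder
  lines <- strsplit(sge, "\n")[[1]]
  arith <- grep("^I[12]=", lines, value = TRUE)
  expect_length(arith, 2)
  for (tid in seq_len(plan$task_count)) {
    out <- system2("bash", c("-c", shQuote(sprintf(
      "TASK_ID=%d; M=%d; %s; %s; echo $I1 $I2", tid, plan$m,
      arith[1], arith[2]))), stdout = TRUE)
    got <- as.integer(strsplit(out, " ")[[1]])
    want <- pair_from_task_id(tid, plan$m, plan$n)
    expect_equal(got, c(want$i1, want$i2))
  }
})

test_that("a 1 x 1 plan emits the degenerate range", {
  fix <- small_fixture_dir(seed = 5, n_db = 3, n_query = 2)
  qman <- split_fasta(fix$query, 1e9, tempfile(), "query")
  dman <- split_fasta(fix$db, 1e9, tempfile(), "db")
  plan <- build_plan(qman, dman)
  expect_equal(plan$task_count, 1)
  expect_match(emit_array_script(plan, "sge"), "#\\$ -t 1-1\n")
})

test_that("interrupted tasks never leave a complete-looking result file", {
  # atomicity contract: the result appears only via rename of a temp file,
  # so a task killed mid-write leaves *.tmp.* debris, not a partial result
  s <- plan_setup(seed = 31)
  plan <- s$plan
  task <- plan$tasks[1, ]
  dir.create(s$results, showWarnings = FALSE)
  # simulate the kill by running the same write path against an
  # unwritable rename target
  ro <- file.path(s$results, task$result_name)
  dir.create(ro)  # rename onto a directory fails after the temp write
  expect_error(run_one_task(task, plan, s$results))
  unlink(ro, recursive = TRUE)
  leftovers <- list.files(s$results, pattern = "^results\\.[0-9]+_[0-9]+$")
  expect_length(leftovers, 0)
})

test_that("the CLI pipeline reproduces the library pipeline exactly", {
  fix <- small_fixture_dir(seed = 11)
  work <- tempfile("cliwork"); dir.create(work)
  owd <- setwd(work); on.exit(setwd(owd))
  plan_json <- file.path(work, "plan.json")
  expect_equal(cli_main(c("plan", "--query", fix$query, "--db", fix$db,
                          "--block-bytes", "2000",
                          "--db-block-bytes", "4000",
                          "--work-dir", work, "--plan", plan_json)), 0L)
  expect_equal(cli_main(c("run", "--plan", plan_json, "--results-dir",
                          file.path(work, "results"))), 0L)
  expect_equal(cli_main(c("verify", "--plan", plan_json, "--results-dir",
                          file.path(work, "results"))), 0L)
  merged <- file.path(work, "merged.tsv")
  expect_equal(cli_main(c("merge", "--plan", plan_json, "--results-dir",
                          file.path(work, "results"), "--out", merged)), 0L)

  lib <- run_pipeline(fix$query, fix$db, file.path(work, "lib"),
                      query_chunk_bytes = 2000, db_chunk_bytes = 4000)
  expect_identical(readLines(merged), readLines(lib$merged_path))
})

test_that("CLI guards merging behind verification with a distinct exit code", {
  fix <- small_fixture_dir(seed = 13)
  work <- tempfile("cliwork2"); dir.create(work)
  plan_json <- file.path(work, "plan.json")
  rdir <- file.path(work, "results")
  cli_main(c("plan", "--query", fix$query, "--db", fix$db,
             "--block-bytes", "2000", "--db-block-bytes", "4000",
             "--work-dir", work, "--plan", plan_json))
  cli_main(c("run", "--plan", plan_json, "--results-dir", rdir))
  plan <- load_plan(plan_json)
  unlink(file.path(rdir, plan$tasks$result_name[2]))
  failed_lst <- file.path(work, "failed.lst")
  expect_equal(cli_main(c("verify", "--plan", plan_json, "--results-dir",
                          rdir, "--failed-lst", failed_lst)), 2L)
  expect_equal(cli_main(c("merge", "--plan", plan_json, "--results-dir",
                          rdir)), 2L)
  expect_equal(read_task_filter(failed_lst), plan$tasks$task_id[2])
  # rerun just the failed task, then everything goes green
  expect_equal(cli_main(c("rerun", "--plan", plan_json, "--results-dir",
                          rdir, "--task-filter", failed_lst)), 0L)
  expect_equal(cli_main(c("verify", "--plan", plan_json, "--results-dir",
                          rdir)), 0L)
  expect_equal(cli_main(c("badcommand")), 1L)
})
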