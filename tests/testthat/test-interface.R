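# The CLI is exercised two ways: in-process through nitrotyr_cli() (status
# codes, logging) and through the installed exec/nitrotyr script in a child
# Rscript process (byte-level determinism of its file outputs).

cli_script <- function() {
  system.file("exec", "nitrotyr", package = "nitrotyr")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- suppressWarnings(system2(
    rscript, c(shQuote(cli_script()), vapply(args, shQuote, "")),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", shQuote(libs))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

test_that("nitrotyr_cli pipeline: simulate, train, predict, evaluate", {
  dir <- withr::local_tempdir()
  bench_tsv <- file.path(dir, "bench.tsv")
  model_file <- file.path(dir, "model.txt")

  expect_equal(suppressMessages(nitrotyr_cli(c(
    "simulate", "--out", bench_tsv, "--n-pos", "30", "--n-neg", "60",
    "--half-width", "3", "--seed", "5"
  ))), 0L)
  bench <- read_benchmark(bench_tsv)
  expect_equal(nrow(bench), 90L)
  expect_identical(bench, generate_benchmark(30, 60, half_width = 3, seed = 5))

  expect_equal(suppressMessages(nitrotyr_cli(c(
    "train", "--data", bench_tsv, "--out", model_file
  ))), 0L)
  model <- read_model(model_file)
  expect_equal(model$encoder, "dipeptide")
  # the saved model round-trips bit-exactly
  f2 <- file.path(dir, "model2.txt")
  write_model(model, f2)
  expect_identical(readLines(model_file), readLines(f2))

  # fixed xi bypasses tuning; single-residue encoder trains the baseline
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "train", "--data", bench_tsv, "--out", f2, "--xi", "0.0", "--encoder", "single"
  ))), 0L)
  baseline <- read_model(f2)
  expect_equal(baseline$encoder, "single")
  expect_equal(baseline$xi, 0)
  expect_equal(baseline$xi_policy, "fixed")

  fasta <- file.path(dir, "query.fasta")
  writeLines(c(">q1", "MYAYAAAA"), fasta)
  pred_tsv <- file.path(dir, "pred.tsv")
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "predict", "--model", model_file, "--fasta", fasta, "--out", pred_tsv
  ))), 0L)
  pred <- readr::read_tsv(pred_tsv, show_col_types = FALSE)
  expect_equal(nrow(pred), 2L) # two tyrosines in MYAYAAAA
  expect_equal(pred$position, c(2, 4))

  eval_tsv <- file.path(dir, "eval.tsv")
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "evaluate", "--data", bench_tsv, "--mode", "jackknife", "--out", eval_tsv
  ))), 0L)
  tab <- readr::read_tsv(eval_tsv, show_col_types = FALSE)
  expect_equal(tab$acc, jackknife_eval(bench, xi = "shared")$metrics$acc)
})

test_that("the installed script is deterministic at the byte level", {
  dir <- withr::local_tempdir()
  bench_tsv <- file.path(dir, "bench.tsv")
  r <- run_cli(c("simulate", "--out", bench_tsv, "--n-pos", "15", "--n-neg", "25",
                 "--half-width", "2", "--seed", "11"))
  expect_equal(r$status, 0L)

  model_file <- file.path(dir, "model.txt")
  expect_equal(run_cli(c("train", "--data", bench_tsv, "--out", model_file))$status, 0L)

  fasta <- file.path(dir, "q.fasta")
  writeLines(c(">q1", "AAYAAYAA"), fasta)
  p1 <- file.path(dir, "p1.tsv")
  p2 <- file.path(dir, "p2.tsv")
  expect_equal(run_cli(c("predict", "--model", model_file, "--fasta", fasta,
                         "--out", p1))$status, 0L)
  expect_equal(run_cli(c("predict", "--model", model_file, "--fasta", fasta,
                         "--out", p2))$status, 0L)
  expect_identical(readLines(p1), readLines(p2))
  # delta column is printed to 6 decimal places
  expect_match(readLines(p1)[2], "\\t-?[0-9]+\\.[0-9]{6}\\t")

  e1 <- file.path(dir, "e1.tsv")
  e2 <- file.path(dir, "e2.tsv")
  expect_equal(run_cli(c("evaluate", "--data", bench_tsv, "--mode", "kfold",
                         "--k", "5", "--seed", "7", "--out", e1))$status, 0L)
  expect_equal(run_cli(c("evaluate", "--data", bench_tsv, "--mode", "kfold",
                         "--k", "5", "--seed", "7", "--out", e2))$status, 0L)
  expect_identical(readLines(e1), readLines(e2))
})

test_that("build-dataset and sweep work from FASTA plus site annotations", {
  dir <- withr::local_tempdir()
  gen <- generate_annotated_proteins(n_proteins = 40, protein_length = 60,
                                     sites_per_protein = 2, half_width = 2,
                                     motif = motif_spec(1, "D", "E", 0.9),
                                     seed = 13)
  fasta <- file.path(dir, "prot.fasta")
  writeLines(paste0(">", gen$proteins$id, "\n", gen$proteins$sequence), fasta)
  sites_tsv <- file.path(dir, "sites.tsv")
  readr::write_tsv(gen$sites, sites_tsv)

  bench_tsv <- file.path(dir, "bench.tsv")
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "build-dataset", "--fasta", fasta, "--sites", sites_tsv,
    "--half-width", "2", "--out", bench_tsv
  ))), 0L)
  b <- read_benchmark(bench_tsv)
  expect_identical(b, build_benchmark(gen$proteins, gen$sites, half_width = 2))

  sweep_tsv <- file.path(dir, "sweep.tsv")
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "evaluate", "--fasta", fasta, "--sites", sites_tsv,
    "--sweep", "1,2", "--k", "5", "--seed", "3", "--out", sweep_tsv
  ))), 0L)
  sw <- readr::read_tsv(sweep_tsv, show_col_types = FALSE)
  expect_equal(sw$half_width, c(1, 2))
})

test_that("the CLI reports usage and data errors with distinct exit codes", {
  expect_equal(suppressMessages(nitrotyr_cli(character())), 2L)
  expect_equal(suppressMessages(nitrotyr_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(nitrotyr_cli(c("train", "--data"))), 2L)
  expect_equal(suppressMessages(nitrotyr_cli(c("train", "--out", "x"))), 2L)
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "train", "--data", "/nonexistent/bench.tsv", "--out", tempfile()
  ))), 3L)

  dir <- withr::local_tempdir()
  bad_tsv <- file.path(dir, "bad.tsv")
  writeLines("P1\t1\tAYCA\t1", bad_tsv) # even-length peptide
  expect_equal(suppressMessages(nitrotyr_cli(c(
    "train", "--data", bad_tsv, "--out", file.path(dir, "m.txt")
  ))), 3L)
})

test_that("predicting proteins without tyrosine warns and emits a header-only report", {
  dir <- withr::local_tempdir()
  bench <- generate_benchmark(10, 20, half_width = 2, seed = 31)
  model_file <- file.path(dir, "m.txt")
  write_model(nitro_train(bench, xi = 0), model_file)
  fasta <- file.path(dir, "noy.fasta")
  writeLines(c(">q", "AAAA"), fasta)
  out <- file.path(dir, "p.tsv")
  expect_warning(
    status <- suppressMessages(nitrotyr_cli(c(
      "predict", "--model", model_file, "--fasta", fasta, "--out", out
    ))),
    "no tyrosine"
  )
  expect_equal(status, 0L)
  expect_equal(length(readLines(out)), 1L) # header only
})
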