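# Aligner adapter: command rendering, builtin dispatch, failure capture,
# and a live run of the packaged MAFFT template.

mafft_like_spec <- function() {
  aligner_spec(
    "mafft-linsi",
    command_template = "mafft --localpair --maxiterate 1000 --op {gop} --ep {gep} {matrix_flag} --quiet {input} > {output}",
    matrix_flag_map = c(BLOSUM30 = "--bl 30", BLOSUM45 = "--bl 45",
                        BLOSUM62 = "--bl 62", BLOSUM80 = "--bl 80",
                        PAM100 = "--jtt 100", PAM200 = "--jtt 200"))
}

test_that("command templates render to argument vectors without a shell", {
  spec <- mafft_like_spec()
  cmd <- render_command(spec, list(matrix = "BLOSUM62", gop = 1.53, gep = 0.123),
                        "in.fa", "out.fa")
  expect_equal(cmd$command, "mafft")
  expect_true(all(c("--op", "1.53", "--ep", "0.123", "--bl", "62") %in% cmd$args))
  expect_equal(cmd$stdout, "out.fa")       # '>' token becomes stdout capture
  expect_false(">" %in% cmd$args)
  expect_true("in.fa" %in% cmd$args)
  # unmapped matrix is a configuration error
  spec2 <- spec; spec2$matrix_flag_map <- spec2$matrix_flag_map[-5]
  expect_error(render_command(spec2, list(matrix = "PAM100", gop = 1, gep = 0.1),
                              "i", "o"), "PAM100")
})

test_that("template validation requires input and output placeholders", {
  expect_error(aligner_spec("bad", command_template = "prog {input}"),
               "\\{output\\}")
  expect_error(aligner_spec("bad", command_template = "prog {output}"),
               "\\{input\\}")
})

test_that("rendering is injective over a parameter grid", {
  spec <- mafft_like_spec()
  grid <- build_grid(grid_spec(0.1, 0.5, 0.1, 0.03, 0.15, 0.03,
                               c("BLOSUM62", "PAM100")))
  rendered <- vapply(seq_len(nrow(grid)), function(i) {
    paste(render_command(spec, grid[i, ], "in.fa", "out.fa")$args, collapse = " ")
  }, character(1))
  expect_equal(anyDuplicated(rendered), 0L)
  expect_equal(length(rendered), 50L)
})

test_that("the builtin spec dispatches to the progressive aligner", {
  fam <- generate_family(family_spec(n_seqs = 4L, ancestor_len = 60L,
                                     divergence = 0.3, seed = 5L))
  aln <- run_aligner(builtin_aligner(), list(matrix = "BLOSUM62", gop = 1.53,
                                             gep = 0.123), fam)
  expect_s3_class(aln, "alignment")
  expect_setequal(aln$ids, names(fam$inputs))
  expect_equal(ungap(aln), fam$inputs)
})

test_that("failing external commands become FAILED records, not exceptions", {
  fam <- generate_family(family_spec(n_seqs = 3L, ancestor_len = 30L, seed = 6L))
  wd <- withr::local_tempdir()
  # exits 1
  fail_spec <- aligner_spec("fails", command_template = "false {input} {output}")
  r <- run_aligner(fail_spec, list(matrix = "BLOSUM62", gop = 1, gep = 0.1),
                   fam, workdir = wd)
  expect_s3_class(r, "aligner_failure")
  # exits 0 but writes no output
  silent_spec <- aligner_spec("silent", command_template = "true {input} {output}")
  r2 <- run_aligner(silent_spec, list(matrix = "BLOSUM62", gop = 1, gep = 0.1),
                    fam, workdir = wd)
  expect_s3_class(r2, "aligner_failure")
  # and the sweep records the cell instead of aborting
  tab <- run_sweep(list(fam), data.frame(matrix = "BLOSUM62", gop = 1, gep = 0.1,
                                         stringsAsFactors = FALSE),
                   fail_spec, workdir = wd)
  expect_equal(tab$status, "FAILED")
  expect_true(is.na(tab$sps))
})

test_that("output that loses a sequence is an integrity error", {
  # indel-free family: inputs share one length, so dropping a record still
  # parses as a rectangular alignment and fails only the integrity check
  fam <- generate_family(family_spec(n_seqs = 3L, ancestor_len = 30L,
                                     divergence = 0.2, indel_rate = 0, seed = 8L))
  wd <- withr::local_tempdir()
  # fake aligner: copies the input FASTA but drops the last record
  script <- file.path(wd, "drop_one.R")
  writeLines(c(
    "args <- commandArgs(TRUE)",
    "x <- readLines(args[1])",
    "last <- max(grep('^>', x))",
    "writeLines(x[seq_len(last - 1L)], args[2])"), script)
  spec <- aligner_spec("droppy",
                       command_template = paste("Rscript", script, "{input} {output}"))
  expect_error(run_aligner(spec, list(matrix = "BLOSUM62", gop = 1, gep = 0.1),
                           fam, workdir = wd),
               "conserve")
})

test_that("successful external runs leave no case files in the workdir", {
  fam <- generate_family(family_spec(n_seqs = 3L, ancestor_len = 40L,
                                     divergence = 0.2, seed = 9L))
  wd <- withr::local_tempdir()
  script <- file.path(wd, "copy_ref.R")
  # fake aligner that emits the true alignment of its input sequences
  ref_fa <- file.path(wd, "truth.fasta")
  write_fasta_alignment(fam$reference$alignment, ref_fa)
  writeLines(c("args <- commandArgs(TRUE)",
               sprintf("file.copy('%s', args[2])", ref_fa)), script)
  spec <- aligner_spec("copier",
                       command_template = paste("Rscript", script, "{input} {output}"))
  aln <- run_aligner(spec, list(matrix = "BLOSUM62", gop = 1, gep = 0.1),
                     fam, workdir = wd)
  expect_equal(sps(aln, fam$reference)$sps, 1.0)
  left <- setdiff(list.files(wd), c("drop_one.R", "copy_ref.R", "truth.fasta"))
  expect_length(grep(fam$case_id, left, value = TRUE), 0L)
})

test_that("the packaged MAFFT template drives a real MAFFT run", {
  cfg <- read_aligner_config(system.file("extdata", "aligners", "aligners.yaml",
                                         package = "alnsweep"))
  expect_true(cfg$builtin$is_builtin)
  fam <- generate_family(family_spec(n_seqs = 4L, ancestor_len = 60L,
                                     divergence = 0.3, indel_rate = 0.02,
                                     seed = 12L))
  wd <- withr::local_tempdir()
  aln <- run_aligner(cfg$`mafft-linsi`,
                     list(matrix = "BLOSUM62", gop = 1.53, gep = 0.123),
                     fam, workdir = wd)
  expect_s3_class(aln, "alignment")
  expect_equal(ungap(aln), fam$inputs)
  expect_gt(sps(aln, fam$reference)$sps, 0.5)
})
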