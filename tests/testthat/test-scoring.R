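# Sum-of-pairs and column scores against brute-force oracles.

make_ref <- function(rows, ids = sprintf("s%d", seq_along(rows)), core = NULL) {
  reference_alignment(alignment(ids, rows), core)
}

test_that("pair index enumerates column co-occupancy", {
  ref <- make_ref(c("AACD", "A-CD"))
  pi <- build_pair_index(ref)
  expect_setequal(pi$keys, c("s1|1//s2|1", "s1|3//s2|2", "s1|4//s2|3"))
  expect_equal(pi$denominator_total, 3L)

  # two identical gap-free rows: one pair per column
  ref2 <- make_ref(c("ACDEF", "ACDEF"))
  expect_equal(build_pair_index(ref2)$denominator_total, 5L)

  # mask restricted to column 1
  ref3 <- make_ref(c("AACD", "A-CD"), core = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(build_pair_index(ref3)$denominator_total, 1L)
  expect_equal(build_pair_index(ref3, use_core_mask = FALSE)$denominator_total, 3L)

  # reference with no co-occupied column
  expect_error(build_pair_index(make_ref(c("A-", "-C"))), "no aligned pairs")
})

test_that("the four-column worked example scores 2/3", {
  ref <- make_ref(c("AACD", "A-CD"))
  tst <- alignment(c("s1", "s2"), c("AACD", "-ACD"))
  r <- sps(tst, ref)
  expect_identical(r$numerator, 2L)
  expect_identical(r$denominator, 3L)
  expect_equal(round(r$sps, 4), 0.6667)
  o <- oracle_sps(tst, ref)
  expect_equal(o$numerator / o$denominator, r$sps)
  # column score: reference columns 3 and 4 are reproduced intact
  expect_equal(cs(tst, ref), 2 / 4)
  expect_equal(cs(tst, ref, skip_single_residue_columns = TRUE), 2 / 3)
  expect_equal(oracle_cs(tst, ref), 2 / 4)
})

test_that("scoring is exact against the double-sum oracle on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    inst <- random_scoring_instance()
    r <- sps(inst$test, inst$ref)
    o <- oracle_sps(inst$test, inst$ref)
    # oracle counts ordered pairs; implementation reports unordered by default
    expect_identical(2L * r$numerator, o$numerator)
    expect_identical(2L * r$denominator, o$denominator)
    ro <- sps(inst$test, inst$ref, ordered = TRUE)
    expect_identical(ro$numerator, o$numerator)
    expect_identical(ro$denominator, o$denominator)
    expect_equal(ro$sps, r$sps)
    expect_true(r$sps >= 0 && r$sps <= 1)
    cv <- cs(inst$test, inst$ref)
    expect_equal(cv, oracle_cs(inst$test, inst$ref))
    expect_true(cv >= 0 && cv <= 1)
  }
})

test_that("a reference recovers itself perfectly and a shredded test scores 0", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_scoring_instance()
    expect_equal(sps(inst$ref$alignment, inst$ref)$sps, 1.0)
    expect_equal(cs(inst$ref$alignment, inst$ref), 1.0)
  }
  # every residue in its own column: no pair survives
  ref <- make_ref(c("ACD", "ACD"))
  shred <- alignment(c("s1", "s2"), c("ACD---", "---ACD"))
  expect_equal(sps(shred, ref)$sps, 0)
  expect_equal(cs(shred, ref), 0)
})

test_that("residue identity, not letter identity, decides matches", {
  # the test aligns s1's *second* A against s2's A: a letter-based scorer
  # would credit column 1, a position-based one must not
  ref <- make_ref(c("AA", "A-"))          # reference pairs s1 pos 1 with s2's A
  tst <- alignment(c("s1", "s2"), c("AA", "-A"))  # s1 pos 2 vs s2's A
  expect_identical(sps(tst, ref)$numerator, 0L)
})

test_that("scoring is case-insensitive", {
  ref <- make_ref(c("aAcD", "A-CD"))
  tst <- alignment(c("s1", "s2"), c("AACD", "-acd"))
  expect_identical(sps(tst, ref)$numerator, 2L)
})

test_that("core masks restrict both numerator and denominator", {
  ref <- make_ref(c("AACD", "A-CD"), core = c(TRUE, FALSE, TRUE, FALSE))
  tst <- alignment(c("s1", "s2"), c("AACD", "-ACD"))
  r <- sps(tst, ref)
  expect_identical(r$denominator, 2L)   # columns 1 and 3 only
  expect_identical(r$numerator, 1L)     # only column 3's pair survives
  o <- oracle_sps(tst, ref)
  expect_identical(2L * r$numerator, o$numerator)
  full <- sps(tst, ref, use_core_mask = FALSE)
  expect_identical(full$denominator, 3L)
})

test_that("mismatched rows raise input errors naming the row", {
  ref <- make_ref(c("AACD", "A-CD"))
  expect_error(sps(alignment(c("s1", "sX"), c("AACD", "-ACD")), ref), "sX")
  expect_error(sps(alignment(c("s1", "s2"), c("AACD", "-AED")), ref), "s2")
})

test_that("splitting a test column never increases the numerator", {
  set.seed(202)
  for (rep in 1:15) {
    inst <- random_scoring_instance(max_rows = 4L, max_cols = 15L)
    base <- sps(inst$test, inst$ref)$numerator
    # split a random occupied column of the test alignment in two
    m <- as.matrix(inst$test)
    occ <- which(colSums(m != "-") >= 2L)
    if (length(occ) == 0L) next
    j <- occ[sample.int(length(occ), 1L)]
    rows_in <- which(m[, j] != "-")
    mover <- rows_in[sample.int(length(rows_in), 1L)]
    left <- m[, j]; left[mover] <- "-"
    right <- rep("-", nrow(m)); right[mover] <- m[mover, j]
    m2 <- cbind(m[, seq_len(j - 1L), drop = FALSE], left, right,
                if (j < ncol(m)) m[, (j + 1L):ncol(m), drop = FALSE])
    split_aln <- alignment(inst$test$ids, apply(m2, 1L, paste, collapse = ""))
    expect_lte(sps(split_aln, inst$ref)$numerator, base)
  }
})

test_that("file-level scoring composes readers and scorers", {
  dir <- withr::local_tempdir()
  ref <- alignment(c("s1", "s2"), c("AACD", "A-CD"))
  tst <- alignment(c("s1", "s2"), c("AACD", "-ACD"))
  write_fasta_alignment(ref, file.path(dir, "ref.fasta"))
  write_fasta_alignment(tst, file.path(dir, "test.fasta"))
  r <- suppressMessages(score_case(file.path(dir, "test.fasta"),
                                   file.path(dir, "ref.fasta")))
  expect_equal(round(r$sps, 4), 0.6667)
  expect_equal(r$cs, 0.5)
  same <- suppressMessages(score_case(file.path(dir, "ref.fasta"),
                                      file.path(dir, "ref.fasta")))
  expect_equal(same$sps, 1.0)
  expect_equal(same$cs, 1.0)
  # MSF reference against FASTA test, via extension dispatch
  write_msf_alignment(ref, file.path(dir, "ref.msf"))
  r2 <- suppressMessages(score_case(file.path(dir, "test.fasta"),
                                    file.path(dir, "ref.msf")))
  expect_equal(r2$sps, r$sps)
  # mismatched content is an input error
  write_fasta_alignment(alignment(c("s1", "s2"), c("AACD", "ACED")),
                        file.path(dir, "bad.fasta"))
  expect_error(suppressMessages(score_case(file.path(dir, "bad.fasta"),
                                           file.path(dir, "ref.fasta"))))
})
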