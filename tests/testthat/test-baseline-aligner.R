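# Built-in pairwise / progressive aligner.

test_that("identical sequences align gap-free at the diagonal score", {
  m <- get_matrix("BLOSUM62")
  s <- "MKVLATW"
  a <- pairwise_align(c(x = s), c(y = s), m, 1.53, 0.123)
  expect_equal(a$seqs, c(s, s))
  diag_sum <- sum(vapply(strsplit(s, "")[[1]], function(r) m$scores[r, r], integer(1)))
  expect_equal(attr(a, "score"), diag_sum)
  one <- pairwise_align(c(x = "A"), c(y = "A"), m, 10, 1)
  expect_equal(one$n_cols, 1L)
})

test_that("pairwise scores equal the exhaustive-enumeration oracle", {
  set.seed(31)
  m <- get_matrix("BLOSUM62")
  for (rep in 1:25) {
    a <- random_protein(sample(1:6, 1L))
    b <- random_protein(sample(1:6, 1L))
    gop <- sample(c(0.5, 1.53, 5, 11), 1L)
    gep <- sample(c(0.1, 0.123, 1), 1L)
    aln <- pairwise_align(c(x = a), c(y = b), m, gop, gep)
    expect_equal(attr(aln, "score"), oracle_affine_best(a, b, m, gop, gep),
                 info = sprintf("%s vs %s (gop %s gep %s)", a, b, gop, gep))
    # and the emitted alignment realizes the reported score
    expect_equal(affine_alignment_score(aln, m, gop, gep), attr(aln, "score"))
    expect_equal(unname(ungap(aln)), c(a, b))
  }
})

test_that("guide trees join identical sequences first and match a hand-run UPGMA", {
  seqs <- c(a = "MKVLATWQDE", b = "MKVLATWQDE", c = "PPPGGGHHHI")
  tr <- build_guide_tree(seqs)
  expect_equal(tree_shape_string(tr), "((a,b),c)")

  # 4-sequence toy set: UPGMA run by hand on the 3-mer distance matrix
  toy <- c(w = "MKVLATWQDE", x = "MKVLATWQDA", y = "MKVPPTWQDE", z = "WWWGGGHHHI")
  d <- kmer_distance(toy)
  expect_true(isSymmetric(d))
  # hand/brute-force UPGMA with the same average-linkage update
  pool <- list(w = "w", x = "x", y = "y", z = "z")
  dd <- d
  while (length(pool) > 1L) {
    nms <- names(pool)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(nms)[-length(nms)]) for (j in (i + 1L):length(nms)) {
      if (dd[nms[i], nms[j]] < bestd) { bestd <- dd[nms[i], nms[j]]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merged <- paste0("(", paste(sort(c(pool[[i]], pool[[j]])), collapse = ","), ")")
    sz <- function(s) lengths(regmatches(s, gregexpr("[a-z]", s)))
    keep <- nms[-c(i, j)]
    newd <- vapply(keep, function(k) {
      (sz(pool[[i]]) * dd[nms[i], k] + sz(pool[[j]]) * dd[nms[j], k]) /
        (sz(pool[[i]]) + sz(pool[[j]]))
    }, numeric(1))
    dd2 <- matrix(0, length(keep) + 1L, length(keep) + 1L,
                  dimnames = list(c(keep, merged), c(keep, merged)))
    if (length(keep) > 0L) {
      dd2[keep, keep] <- dd[keep, keep, drop = FALSE]
      dd2[merged, keep] <- dd2[keep, merged] <- newd
    }
    dd <- dd2
    pool <- c(pool[-c(i, j)], stats::setNames(list(merged), merged))
  }
  expect_equal(tree_shape_string(build_guide_tree(toy)), names(pool))
})

test_that("two-sequence progressive alignment degenerates to pairwise", {
  m <- get_matrix("BLOSUM45")
  seqs <- c(p = "MKVLATWQDE", q = "MKVATWQD")
  expect_equal(progressive_align(seqs, m, 1.5, 0.3)$seqs,
               pairwise_align(seqs["p"], seqs["q"], m, 1.5, 0.3)$seqs)
})

test_that("progressive alignment conserves sequences, order, and determinism", {
  set.seed(47)
  m <- get_matrix("BLOSUM62")
  seqs <- stats::setNames(vapply(sample(20:30, 5, replace = TRUE), random_protein,
                                 character(1)), c("e", "a", "c", "b", "d"))
  a1 <- progressive_align(seqs, m, 1.53, 0.123)
  a2 <- progressive_align(seqs, m, 1.53, 0.123)
  expect_identical(a1, a2)                       # byte-identical reruns
  expect_equal(a1$ids, names(seqs))              # input row order kept
  expect_equal(ungap(a1), seqs)                  # content conserved
  expect_true(all(colSums(as.matrix(a1) != "-") > 0))  # no all-gap columns
})

test_that("identical inputs produce a gap-free multiple alignment", {
  seqs <- stats::setNames(rep("MKVLATWQDEPPR", 4), sprintf("s%d", 1:4))
  a <- progressive_align(seqs, get_matrix("BLOSUM62"), 1.53, 0.123)
  expect_equal(a$n_cols, 13L)
  expect_false(any(grepl("-", a$seqs, fixed = TRUE)))
})

test_that("a low-divergence indel-free family is recovered exactly", {
  fam <- generate_family(family_spec(n_seqs = 4L, ancestor_len = 80L,
                                     divergence = 0.05, indel_rate = 0,
                                     seed = 99L))
  aln <- progressive_align(fam$inputs, get_matrix("BLOSUM62"), 1.53, 0.123)
  expect_equal(sps(aln, fam$reference)$sps, 1.0)
})

test_that("raising the extension penalty eventually splits a long insertion", {
  # family of three: two carry a shared 12-residue insertion, one does not;
  # with a mild GEP the insertion stays contiguous, with a punitive GEP the
  # recovered accuracy cannot improve
  core <- "MKVLATWQDEMKVLATWQDE"
  ins <- "WWWWCCCCWWWW"
  seqs <- c(u = paste0(substr(core, 1, 10), ins, substr(core, 11, 20)),
            v = paste0(substr(core, 1, 10), ins, substr(core, 11, 20)),
            t = core)
  truth <- reference_alignment(alignment(
    c("u", "v", "t"),
    c(paste0(substr(core, 1, 10), ins, substr(core, 11, 20)),
      paste0(substr(core, 1, 10), ins, substr(core, 11, 20)),
      paste0(substr(core, 1, 10), strrep("-", nchar(ins)), substr(core, 11, 20)))))
  m <- get_matrix("BLOSUM62")
  sps_at <- function(gep) sps(progressive_align(seqs, m, 1.0, gep), truth)$sps
  gentle <- sps_at(0.1)
  harsh <- sps_at(8)
  expect_equal(gentle, 1.0)
  expect_lte(harsh, gentle)
})
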