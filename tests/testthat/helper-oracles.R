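# Independent oracles and random-instance generators shared across tests.
# These deliberately take different routes than the package implementation:
# the SPS oracle enumerates the double sum pair by pair from the score
# definition, and the alignment oracle enumerates every global alignment.

# --- SPS / CS brute-force oracle -------------------------------------------

# Enumerate "row|ungapped-pos" labels per cell of a character matrix.
.oracle_labels <- function(m) {
  lab <- matrix(NA_character_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    p <- 0L
    for (j in seq_len(ncol(m))) {
      if (m[i, j] != "-") {
        p <- p + 1L
        lab[i, j] <- paste0(rownames(m)[i], "|", p)
      }
    }
  }
  lab
}

# All ordered residue pairs co-occupying a column, per column subset.
.oracle_ordered_pairs <- function(m, cols) {
  lab <- .oracle_labels(m)
  keys <- character(0)
  for (j in cols) {
    present <- which(!is.na(lab[, j]))
    for (a in present) for (b in present) {
      if (a != b) keys <- c(keys, paste0(lab[a, j], "->", lab[b, j]))
    }
  }
  keys
}

# SPS straight from the definition: numerator = sum over test columns of the
# ordered pairs aligned in the reference; denominator = same sum over the
# reference itself. Returns exact integer counts (ordered-pair units).
oracle_sps <- function(test, ref, use_core_mask = TRUE) {
  tm <- as.matrix(test)
  rm_ <- as.matrix(ref$alignment)
  tm <- tm[rownames(rm_), , drop = FALSE]
  scored <- if (use_core_mask && !is.null(ref$core_mask)) {
    which(ref$core_mask)
  } else {
    seq_len(ncol(rm_))
  }
  ref_keys <- .oracle_ordered_pairs(rm_, scored)
  test_keys <- .oracle_ordered_pairs(tm, seq_len(ncol(tm)))
  list(numerator = sum(test_keys %in% ref_keys),
       denominator = length(ref_keys))
}

# CS oracle: reference column content (set of labels) reproduced verbatim by
# some test column.
oracle_cs <- function(test, ref, use_core_mask = TRUE,
                      skip_single_residue_columns = FALSE) {
  tm <- as.matrix(test)
  rm_ <- as.matrix(ref$alignment)
  tm <- tm[rownames(rm_), , drop = FALSE]
  rlab <- .oracle_labels(rm_)
  tlab <- .oracle_labels(tm)
  scored <- if (use_core_mask && !is.null(ref$core_mask)) {
    which(ref$core_mask)
  } else {
    seq_len(ncol(rm_))
  }
  test_sets <- lapply(seq_len(ncol(tm)), function(j) sort(stats::na.omit(tlab[, j])))
  hits <- 0L
  n <- 0L
  for (j in scored) {
    content <- sort(stats::na.omit(rlab[, j]))
    if (length(content) == 0L) next   # residue-less columns are never scored
    if (skip_single_residue_columns && length(content) < 2L) next
    n <- n + 1L
    if (any(vapply(test_sets, identical, logical(1), y = content))) hits <- hits + 1L
  }
  hits / n
}

# --- exhaustive affine-gap alignment oracle --------------------------------

# Best global alignment score by enumerating every alignment path (no DP
# matrices, no memoization): moves M / gap-in-b / gap-in-a, affine cost
# gop + gep*(L-1) charged move by move via the previous-move state.
oracle_affine_best <- function(a, b, m, gop, gep) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == length(A) && j == length(B)) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < length(A) && j < length(B)) {
      rec(i + 1L, j + 1L, "M", acc + pair_score(m, A[i + 1L], B[j + 1L]))
    }
    if (i < length(A)) {
      rec(i + 1L, j, "X", acc - if (identical(last, "X")) gep else gop)
    }
    if (j < length(B)) {
      rec(i, j + 1L, "Y", acc - if (identical(last, "Y")) gep else gop)
    }
  }
  rec(0L, 0L, "S", 0)
  best
}

# Score an alignment under the same affine convention (for checking that the
# aligner's reported score matches its emitted alignment).
affine_alignment_score <- function(aln, m, gop, gep) {
  stopifnot(aln$n_rows == 2L)
  r1 <- strsplit(toupper(aln$seqs[1]), "")[[1]]
  r2 <- strsplit(toupper(aln$seqs[2]), "")[[1]]
  sc <- 0
  last <- "S"
  for (k in seq_along(r1)) {
    if (r1[k] != "-" && r2[k] != "-") {
      sc <- sc + pair_score(m, r1[k], r2[k])
      last <- "M"
    } else if (r2[k] == "-") {
      sc <- sc - if (last == "X") gep else gop
      last <- "X"
    } else {
      sc <- sc - if (last == "Y") gep else gop
      last <- "Y"
    }
  }
  sc
}

# --- random-instance generators --------------------------------------------

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                 "S","T","V","W","Y"), len, replace = TRUE), collapse = "")
}

# Random gapped embedding of fixed sequences into n_cols columns.
random_gapping <- function(seqs, n_cols) {
  rows <- vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    slots <- sort(sample.int(n_cols, length(chars)))
    r <- rep("-", n_cols)
    r[slots] <- chars
    paste(r, collapse = "")
  }, character(1))
  alignment(names(seqs), unname(rows))
}

# Random (test, reference) pair over the same sequences; the reference is
# regenerated until it defines at least one aligned pair.
random_scoring_instance <- function(max_rows = 6L, max_cols = 30L) {
  n <- sample(2:max_rows, 1L)
  lens <- sample(3:12, n, replace = TRUE)
  seqs <- stats::setNames(vapply(lens, random_protein, character(1)),
                          sprintf("r%d", seq_len(n)))
  n_cols <- sample(max(lens):max_cols, 1L)
  repeat {
    ref_aln <- random_gapping(seqs, n_cols)
    cols_ok <- colSums(as.matrix(ref_aln) != "-") >= 2L
    if (any(cols_ok)) break
  }
  test_aln <- random_gapping(seqs, sample(max(lens):max_cols, 1L))
  list(test = test_aln, ref = reference_alignment(ref_aln))
}

# Random sweep table for the aggregation oracle.
random_sweep_table <- function(max_cases = 5L, max_combos = 60L,
                               fail_rate = 0.05) {
  datasets <- sample(1:2, 1L)
  mats <- sample(matrix_names(), sample(1:3, 1L))
  n_gop <- sample(1:6, 1L)
  n_gep <- max(1L, min(sample(1:10, 1L), floor(max_combos / (length(mats) * n_gop))))
  gops <- round(seq(0.1, by = 0.1, length.out = n_gop), 1)
  geps <- round(seq(0.03, by = 0.03, length.out = n_gep), 2)
  rows <- list()
  for (d in seq_len(datasets)) {
    n_cases <- sample(1:max_cases, 1L)
    for (cid in seq_len(n_cases)) {
      for (mt in mats) for (go in gops) for (ge in geps) {
        failed <- stats::runif(1) < fail_rate
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = sprintf("DS%d", d),
          case_id = sprintf("DS%d_c%d", d, cid),
          matrix = mt, gop = go, gep = ge,
          sps = if (failed) NA_real_ else stats::runif(1),
          cs = NA_real_, status = if (failed) "FAILED" else "OK",
          runtime_s = 0, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# One-pass brute-force optimum per dataset over a raw sweep table (the
# aggregation oracle): mean over OK cells per combo, argmax with ties
# resolved by matrix list order across matrices and by smallest gop, then
# smallest gep, within a matrix.
oracle_select_optimal <- function(tab, matrix_order = matrix_names()) {
  out <- list()
  for (ds in sort(unique(tab$dataset_id))) {
    sub <- tab[tab$dataset_id == ds & tab$status == "OK", , drop = FALSE]
    best <- NULL
    for (mt in unique(sub$matrix)) for (go in unique(sub$gop)) for (ge in unique(sub$gep)) {
      cell <- sub[sub$matrix == mt & sub$gop == go & sub$gep == ge, , drop = FALSE]
      if (nrow(cell) == 0L) next
      mval <- mean(cell$sps)
      cand <- list(matrix = mt, gop = go, gep = ge, mean = mval,
                   rank = match(mt, matrix_order))
      if (is.null(best) || mval > best$mean ||
          (mval == best$mean && (cand$rank < best$rank ||
            (cand$rank == best$rank && (go < best$gop ||
              (go == best$gop && ge < best$gep)))))) {
        best <- cand
      }
    }
    out[[ds]] <- data.frame(dataset_id = ds, matrix = best$matrix,
                            gop = best$gop, gep = best$gep,
                            best_max_mean_sps = best$mean,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}

# Canonical string form of a guide tree for topology comparisons (children
# ordered lexicographically by their leaf sets, heights ignored).
tree_shape_string <- function(nd) {
  if (!is.null(nd$id)) return(nd$id)
  kids <- sort(c(tree_shape_string(nd$left), tree_shape_string(nd$right)))
  paste0("(", kids[1L], ",", kids[2L], ")")
}
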