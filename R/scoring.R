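# Reference-based alignment accuracy: sum-of-pairs score (SPS) and column
# score (CS).
#
# A residue is identified by (row id, position in the row's ungapped
# sequence), never by its letter, so repeated letters cannot produce false
# matches. Two residues are "aligned" in an alignment iff they occupy the
# same column. SPS is the fraction of reference-aligned residue pairs that a
# test alignment recovers; CS is the fraction of scored reference columns
# reproduced intact.

# Map each cell of the alignment to the ungapped position of its residue
# (NA at gaps); rows x cols integer matrix.
.ungapped_pos_matrix <- function(a) {
  m <- as.matrix(a)
  nongap <- m != "-"
  pos <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    pos[i, nongap[i, ]] <- seq_len(sum(nongap[i, ]))
  }
  pos
}

.check_same_sequences <- function(test, ref_aln) {
  tu <- ungap(test)
  ru <- ungap(ref_aln)
  if (!setequal(names(tu), names(ru))) {
    stop(sprintf("row ids differ between test and reference (test-only: %s; ref-only: %s)",
                 paste(setdiff(names(tu), names(ru)), collapse = ","),
                 paste(setdiff(names(ru), names(tu)), collapse = ",")),
         call. = FALSE)
  }
  for (id in names(ru)) {
    if (toupper(tu[[id]]) != toupper(ru[[id]])) {
      stop(sprintf("ungapped sequence of row '%s' differs between test and reference",
                   id), call. = FALSE)
    }
  }
  invisible(TRUE)
}

.scored_columns <- function(ref, use_core_mask) {
  n <- ref$alignment$n_cols
  if (use_core_mask && !is.null(ref$core_mask)) ref$core_mask else rep(TRUE, n)
}

#' Enumerate the reference-aligned residue pairs
#'
#' Builds the index of all unordered residue pairs that co-occupy a scored
#' reference column — the ground truth that [sps()] counts against. The
#' number of such pairs is the SPS denominator.
#'
#' @param ref a [reference_alignment()] with at least 2 rows.
#' @param use_core_mask when `TRUE` (default) and the reference carries a
#'   core mask, only masked columns contribute.
#' @return object of class `"pair_index"`: list with `keys` (character
#'   vector, one canonical `"row|pos//row|pos"` key per unordered pair),
#'   `denominator_total` and `n_columns_scored`.
#' @export
build_pair_index <- function(ref, use_core_mask = TRUE) {
  stopifnot(inherits(ref, "reference_alignment"))
  a <- ref$alignment
  if (a$n_rows < 2L) stop("reference needs at least 2 rows", call. = FALSE)
  scored <- .scored_columns(ref, use_core_mask)
  pos <- .ungapped_pos_matrix(a)
  keys <- character(0)
  for (j in which(scored)) {
    rows <- which(!is.na(pos[, j]))
    if (length(rows) < 2L) next
    labs <- paste0(a$ids[rows], "|", pos[rows, j])
    cmb <- utils::combn(sort(labs), 2L)
    keys <- c(keys, paste0(cmb[1L, ], "//", cmb[2L, ]))
  }
  if (length(keys) == 0L) {
    stop("reference defines no aligned pairs (no scored column holds 2+ residues)",
         call. = FALSE)
  }
  structure(list(keys = keys, denominator_total = length(keys),
                 n_columns_scored = sum(scored)),
            class = "pair_index")
}

# Shared machinery: per test column, count residue pairs that are
# reference-aligned. Works on ungapped-position matrices, grouping each test
# column's residues by the reference column they came from.
.sps_counts <- function(test, ref, use_core_mask) {
  ra <- ref$alignment
  .check_same_sequences(test, ra)
  scored <- .scored_columns(ref, use_core_mask)
  rpos <- .ungapped_pos_matrix(ra)
  tpos <- .ungapped_pos_matrix(test)

  # ref_col_of[[id]][p] = reference column holding residue p of row id
  # (NA when that column is outside the core mask)
  ref_col_of <- list()
  for (i in seq_len(ra$n_rows)) {
    id <- ra$ids[i]
    cols <- which(!is.na(rpos[i, ]))
    v <- integer(length(cols))
    v[rpos[i, cols]] <- cols
    v[!scored[v]] <- NA_integer_
    ref_col_of[[id]] <- v
  }

  choose2 <- function(k) k * (k - 1L) / 2L

  denom <- 0L
  for (j in which(scored)) {
    k <- sum(!is.na(rpos[, j]))
    denom <- denom + choose2(k)
  }

  numer <- 0L
  for (j in seq_len(test$n_cols)) {
    rows <- which(!is.na(tpos[, j]))
    if (length(rows) < 2L) next
    rc <- vapply(rows, function(i) {
      ref_col_of[[test$ids[i]]][tpos[i, j]]
    }, integer(1))
    rc <- rc[!is.na(rc)]
    if (length(rc) < 2L) next
    numer <- numer + sum(choose2(table(rc)))
  }
  list(numerator = as.integer(numer), denominator = as.integer(denom),
       n_ref_columns_scored = sum(scored), scored = scored,
       rpos = rpos, tpos = tpos)
}

#' Sum-of-pairs score of a test alignment
#'
#' The SPS is the number of residue pairs co-aligned in the test alignment
#' that are also co-aligned in the reference, divided by the total number of
#' reference-aligned pairs. Counting ordered pairs (the column score summed
#' over `j != k`) scales numerator and denominator by exactly 2 and leaves
#' the ratio unchanged; `ordered = TRUE` reports those doubled counts.
#'
#' @param test an [alignment()] of the same sequences as the reference.
#' @param ref a [reference_alignment()].
#' @param use_core_mask restrict scoring to the reference core mask when one
#'   is present (default `TRUE`).
#' @param ordered count ordered instead of unordered pairs (default `FALSE`;
#'   the score is identical either way).
#' @return object of class `"score_result"`: list with `sps`, `numerator`,
#'   `denominator`, `n_ref_columns_scored` (and `cs = NA`, see [cs()]).
#' @examples
#' ref <- reference_alignment(alignment(c("s1", "s2"), c("AACD", "A-CD")))
#' tst <- alignment(c("s1", "s2"), c("AACD", "-ACD"))
#' sps(tst, ref)$sps  # 2/3
#' @export
sps <- function(test, ref, use_core_mask = TRUE, ordered = FALSE) {
  stopifnot(inherits(test, "alignment"), inherits(ref, "reference_alignment"))
  cnt <- .sps_counts(test, ref, use_core_mask)
  mult <- if (ordered) 2L else 1L
  if (cnt$denominator == 0L) {
    stop("reference defines no aligned pairs (no scored column holds 2+ residues)",
         call. = FALSE)
  }
  structure(list(sps = cnt$numerator / cnt$denominator,
                 cs = NA_real_,
                 numerator = mult * cnt$numerator,
                 denominator = mult * cnt$denominator,
                 n_ref_columns_scored = cnt$n_ref_columns_scored),
            class = "score_result")
}

#' Column score of a test alignment
#'
#' A scored reference column is recovered when its full residue content
#' (gaps excluded, residues identified by row and ungapped position) appears
#' as the exact residue content of a single test column. CS is the fraction
#' of scored reference columns recovered.
#'
#' @inheritParams sps
#' @param skip_single_residue_columns drop reference columns holding fewer
#'   than 2 residues from the CS denominator (conventions differ across the
#'   literature; default `FALSE` scores every masked column that holds at
#'   least one residue — residue-less columns define no content and are
#'   never scored).
#' @return numeric scalar in `[0, 1]`.
#' @export
cs <- function(test, ref, use_core_mask = TRUE,
               skip_single_residue_columns = FALSE) {
  stopifnot(inherits(test, "alignment"), inherits(ref, "reference_alignment"))
  ra <- ref$alignment
  .check_same_sequences(test, ra)
  scored <- .scored_columns(ref, use_core_mask)
  rpos <- .ungapped_pos_matrix(ra)
  tpos <- .ungapped_pos_matrix(test)

  # test_col_of[[id]][p] = test column holding residue p of row id
  test_col_of <- list()
  for (i in seq_len(test$n_rows)) {
    id <- test$ids[i]
    cols <- which(!is.na(tpos[i, ]))
    v <- integer(length(cols))
    v[tpos[i, cols]] <- cols
    test_col_of[[id]] <- v
  }
  test_col_count <- colSums(!is.na(tpos))

  # columns holding no residue define no content and are never scored for CS
  cols <- which(scored & colSums(!is.na(rpos)) >= 1L)
  if (skip_single_residue_columns) {
    cols <- cols[colSums(!is.na(rpos))[cols] >= 2L]
  }
  if (length(cols) == 0L) stop("no reference columns to score for CS", call. = FALSE)
  recovered <- 0L
  for (j in cols) {
    rows <- which(!is.na(rpos[, j]))
    tc <- vapply(rows, function(i) test_col_of[[ra$ids[i]]][rpos[i, j]], integer(1))
    if (length(unique(tc)) == 1L && test_col_count[tc[1L]] == length(rows)) {
      recovered <- recovered + 1L
    }
  }
  recovered / length(cols)
}

#' Score a test alignment file against a reference file
#'
#' Convenience wrapper: reads both alignments (FASTA or MSF by extension),
#' an optional core annotation, and computes [sps()] and [cs()].
#'
#' @param test_path,ref_path alignment files.
#' @param core_path optional core-annotation file (see
#'   [read_core_annotation()]).
#' @param use_core_mask as in [sps()].
#' @param case_id label for the log line; defaults to the test file name.
#' @return a `"score_result"` with both `sps` and `cs` filled in.
#' @export
score_case <- function(test_path, ref_path, core_path = NULL,
                       use_core_mask = TRUE, case_id = NULL) {
  read_aln <- function(p) {
    if (tolower(tools::file_ext(p)) == "msf") read_msf_alignment(p) else read_fasta_alignment(p)
  }
  test <- read_aln(test_path)
  ref_aln <- read_aln(ref_path)
  core <- if (!is.null(core_path)) read_core_annotation(core_path, ref_aln$n_cols) else NULL
  ref <- reference_alignment(ref_aln, core)
  res <- sps(test, ref, use_core_mask = use_core_mask)
  res$cs <- cs(test, ref, use_core_mask = use_core_mask)
  if (is.null(case_id)) case_id <- tools::file_path_sans_ext(basename(test_path))
  message(sprintf("%s\tSPS=%.4f\tCS=%.4f\t(%d/%d pairs)",
                  case_id, res$sps, res$cs, res$numerator, res$denominator))
  res
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("SPS = %.4f (%d/%d reference pairs", x$sps, x$numerator, x$denominator))
  if (!is.na(x$cs)) cat(sprintf("), CS = %.4f", x$cs)) else cat(")")
  cat(sprintf(", %d reference columns scored\n", x$n_ref_columns_scored))
  invisible(x)
}
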