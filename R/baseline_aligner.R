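# Built-in progressive aligner: pairwise and profile-profile affine-gap
# alignment (Gotoh DP in C++), a UPGMA guide tree over 3-mer distances, and
# the progressive merge. Deliberately minimal — it exists so parameter
# sweeps run end-to-end with no external binaries, not as a substitute for
# a production aligner.

.as_named_seq <- function(s, default_id) {
  if (is.null(names(s)) || !nzchar(names(s)[1L])) names(s) <- default_id
  s
}

# residue-frequency profile over the matrix alphabet; gap frequency kept in
# its own row so columns sum to 1, but gaps contribute 0 to the
# substitution term (the gap row is dropped before the score product)
.profile_freqs <- function(a, m) {
  chars <- as.matrix(a)
  rows <- c(m$alphabet, "-")
  f <- matrix(0, length(rows), a$n_cols, dimnames = list(rows, NULL))
  for (j in seq_len(a$n_cols)) {
    col <- chars[, j]
    col[col != "-"] <- normalize_residues(m, col[col != "-"])
    tab <- table(col)
    f[names(tab), j] <- as.numeric(tab) / a$n_rows
  }
  f
}

# merge two alignments along a DP path (1 = both, 2 = gap in b, 3 = gap in a)
.merge_by_path <- function(a, b, path) {
  am <- as.matrix(a)
  bm <- as.matrix(b)
  n <- length(path)
  out <- matrix("-", a$n_rows + b$n_rows, n)
  ia <- 0L; ib <- 0L
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv != 3L) { ia <- ia + 1L; out[seq_len(a$n_rows), k] <- am[, ia] }
    if (mv != 2L) { ib <- ib + 1L; out[a$n_rows + seq_len(b$n_rows), k] <- bm[, ib] }
  }
  alignment(c(a$ids, b$ids), apply(out, 1L, paste, collapse = ""))
}

.align_profiles <- function(a, b, m, gop, gep) {
  fa <- .profile_freqs(a, m)[m$alphabet, , drop = FALSE]
  fb <- .profile_freqs(b, m)[m$alphabet, , drop = FALSE]
  S <- t(fa) %*% m$scores %*% fb  # expected pair score under column frequencies
  res <- gotoh_align(S, gop, gep)
  out <- .merge_by_path(a, b, res$path)
  attr(out, "score") <- res$score
  out
}

#' Pairwise global alignment with affine gap costs
#'
#' Needleman–Wunsch/Gotoh alignment maximizing the summed substitution score
#' minus affine gap costs: a gap of length L costs `gop + gep * (L - 1)`,
#' terminal gaps included. Traceback is deterministic (ties prefer a match
#' column, then a gap in `b`, then a gap in `a`).
#'
#' @param a,b single sequences: character scalars, optionally named with
#'   their ids (defaults `"seq1"`/`"seq2"`).
#' @param m a `"substitution_matrix"` from [get_matrix()].
#' @param gop,gep non-negative gap-open and gap-extension penalties.
#' @return an [alignment()] of the two sequences, with the optimal score in
#'   `attr(, "score")`.
#' @examples
#' pairwise_align(c(s1 = "HEAGAWGHEE"), c(s2 = "PAWHEAE"), get_matrix("BLOSUM62"), 10, 1)
#' @export
pairwise_align <- function(a, b, m, gop, gep) {
  stopifnot(inherits(m, "substitution_matrix"), gop >= 0, gep >= 0)
  a <- .as_named_seq(a, "seq1"); b <- .as_named_seq(b, "seq2")
  if (!nzchar(a[[1L]]) || !nzchar(b[[1L]])) stop("empty sequence", call. = FALSE)
  ca <- normalize_residues(m, strsplit(toupper(a[[1L]]), "")[[1]])
  cb <- normalize_residues(m, strsplit(toupper(b[[1L]]), "")[[1]])
  S <- m$scores[ca, cb, drop = FALSE]
  storage.mode(S) <- "double"
  res <- gotoh_align(S, gop, gep)
  # spell out the two gapped rows directly from the path
  ia <- 0L; ib <- 0L
  ra <- character(length(res$path)); rb <- character(length(res$path))
  chars_a <- strsplit(a[[1L]], "")[[1]]; chars_b <- strsplit(b[[1L]], "")[[1]]
  for (k in seq_along(res$path)) {
    mv <- res$path[k]
    ra[k] <- if (mv != 3L) { ia <- ia + 1L; chars_a[ia] } else "-"
    rb[k] <- if (mv != 2L) { ib <- ib + 1L; chars_b[ib] } else "-"
  }
  out <- alignment(c(names(a)[1L], names(b)[1L]),
                   c(paste(ra, collapse = ""), paste(rb, collapse = "")))
  attr(out, "score") <- res$score
  out
}

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Pairwise k-mer distance matrix
#'
#' Distance `1 - |shared k-mers| / min(|K_a|, |K_b|)` over distinct k-mers
#' (k = 3, reduced when the shortest sequence is shorter than k).
#'
#' @param seqs named character vector of ungapped sequences.
#' @param k k-mer size (default 3).
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
kmer_distance <- function(seqs, k = 3L) {
  validate_sequences(seqs)
  k <- min(k, min(nchar(seqs)))
  sets <- lapply(toupper(seqs), .kmer_set, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      frac <- shared / min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - frac
    }
  }
  d
}

#' UPGMA guide tree over k-mer distances
#'
#' Strictly binary UPGMA clustering of the sequences under the 3-mer
#' distance of [kmer_distance()]. Equal-distance ties are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster's smallest leaf id), making the topology deterministic.
#'
#' @param seqs named character vector of at least 2 ungapped sequences.
#' @return object of class `"guide_tree"`: nested list of nodes. Leaves are
#'   `list(id = <id>)`; internal nodes are `list(left, right, height)` in
#'   merge order.
#' @export
build_guide_tree <- function(seqs) {
  validate_sequences(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  d <- kmer_distance(seqs)
  nodes <- lapply(names(seqs), function(id) list(id = id))
  reps <- names(seqs)          # lexicographic tie-break key per cluster
  sizes <- rep(1L, length(seqs))
  active <- seq_along(seqs)
  while (length(active) > 1L) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1L):length(active)) {
        i <- active[ai]; j <- active[aj]
        dij <- d[i, j]
        key <- sort(c(reps[i], reps[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(d = dij, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    new_node <- list(left = nodes[[i]], right = nodes[[j]], height = best$d / 2)
    # UPGMA average-linkage update into slot i
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) /
        (sizes[i] + sizes[j])
    }
    nodes[[i]] <- new_node
    sizes[i] <- sizes[i] + sizes[j]
    reps[i] <- min(best$key)
    active <- setdiff(active, j)
  }
  structure(nodes[[active]], class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  fmt <- function(nd) {
    if (!is.null(nd$id)) return(nd$id)
    sprintf("(%s,%s):%.3f", fmt(nd$left), fmt(nd$right), nd$height)
  }
  cat("guide tree: ", fmt(x), "\n", sep = "")
  invisible(x)
}

#' Progressive multiple alignment
#'
#' Aligns the sequences by merging them in [build_guide_tree()] order with
#' profile–profile affine-gap alignment: each profile column is scored by
#' the expected substitution score under the column residue frequencies
#' (gaps contribute only through the affine gap states). Output rows are
#' returned in input order; the result is deterministic for fixed inputs
#' and parameters.
#'
#' @param seqs named character vector of at least 2 ungapped sequences.
#' @param m a `"substitution_matrix"`.
#' @param gop,gep non-negative gap penalties (see [pairwise_align()]).
#' @return an [alignment()] covering all input sequences.
#' @export
progressive_align <- function(seqs, m, gop, gep) {
  validate_sequences(seqs)
  stopifnot(inherits(m, "substitution_matrix"), gop >= 0, gep >= 0)
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (length(seqs) == 2L) {
    out <- pairwise_align(seqs[1L], seqs[2L], m, gop, gep)
  } else {
    tree <- build_guide_tree(seqs)
    align_node <- function(nd) {
      if (!is.null(nd$id)) return(alignment(nd$id, unname(seqs[[nd$id]])))
      .align_profiles(align_node(nd$left), align_node(nd$right), m, gop, gep)
    }
    out <- align_node(tree)
  }
  # restore input row order
  ord <- match(names(seqs), out$ids)
  alignment(out$ids[ord], out$seqs[ord])
}
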