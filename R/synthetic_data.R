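# Synthetic benchmark generator: protein families evolved from a random
# ancestor with a known true alignment, controllable identity bands and
# indel structure, grouped into named datasets. Emulates the structure of
# curated benchmark sets (a reference alignment plus unaligned inputs per
# case) so the sweep/selection machinery is testable without external data
# or binaries. The process is deliberately non-phylogenetic in detail:
# substitutions follow a BLOSUM62-derived exchange distribution, not a rate
# matrix exponential.

# Robinson-Robinson-style background amino-acid frequencies (rounded);
# used for ancestor sampling and insertion residues.
.AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.064)

.STANDARD_AA <- names(.AA_BACKGROUND)

.exchange_cache <- new.env(parent = emptyenv())

# P(b | a), b != a: proportional to p_b * 2^(S62[a,b]/2) — a BLOSUM62-
# compatible replacement distribution (half-bit units).
.exchange_matrix <- function() {
  if (is.null(.exchange_cache$P)) {
    s62 <- get_matrix("BLOSUM62")$scores[.STANDARD_AA, .STANDARD_AA]
    P <- sweep(2^(s62 / 2), 2L, .AA_BACKGROUND, `*`)
    diag(P) <- 0
    P <- P / rowSums(P)
    .exchange_cache$P <- P
  }
  .exchange_cache$P
}

#' Specify a synthetic protein family
#'
#' Parameters of the generator: tree shape and size, expected root-to-leaf
#' substitutions per site (`divergence`, which controls the pairwise
#' identity band of the family), and the indel process (events per site per
#' branch, geometric length distribution).
#'
#' @param n_seqs number of leaf sequences (>= 2).
#' @param ancestor_len ancestral sequence length (> 0).
#' @param divergence expected substitutions per site from root to leaf.
#' @param indel_rate expected indel events per site per branch.
#' @param indel_len_mean mean indel length (geometric, >= 1).
#' @param tree_shape `"balanced"` or `"caterpillar"`.
#' @param seed integer RNG seed; the whole case is reproducible from it.
#' @return object of class `"family_spec"`.
#' @export
family_spec <- function(n_seqs = 6L, ancestor_len = 120L, divergence = 0.5,
                        indel_rate = 0.02, indel_len_mean = 3,
                        tree_shape = c("balanced", "caterpillar"), seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_seqs >= 2L, ancestor_len >= 1L, divergence >= 0,
            indel_rate >= 0, indel_len_mean >= 1, is.finite(divergence),
            is.finite(indel_rate), is.finite(indel_len_mean))
  structure(list(n_seqs = as.integer(n_seqs),
                 ancestor_len = as.integer(ancestor_len),
                 divergence = divergence, indel_rate = indel_rate,
                 indel_len_mean = indel_len_mean, tree_shape = tree_shape,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# simple rooted binary topology as nested lists of leaf indices
.family_tree <- function(n, shape) {
  make_leaf <- function(i) list(leaf = i)
  if (shape == "balanced") {
    build <- function(idx) {
      if (length(idx) == 1L) return(make_leaf(idx))
      mid <- ceiling(length(idx) / 2)
      list(left = build(idx[seq_len(mid)]), right = build(idx[-seq_len(mid)]))
    }
    build(seq_len(n))
  } else {
    node <- make_leaf(n)
    for (i in (n - 1L):1L) node <- list(left = make_leaf(i), right = node)
    node
  }
}

.tree_depths <- function(node, depth = 0L) {
  if (!is.null(node$leaf)) return(depth)
  c(.tree_depths(node$left, depth + 1L), .tree_depths(node$right, depth + 1L))
}

#' Generate one synthetic family with its true alignment
#'
#' Evolves a random ancestor down the family tree. Each edge carries an
#' equal share of the root-to-leaf divergence (per-site substitution
#' probability `1 - exp(-t)`; replacements drawn from a BLOSUM62-derived
#' exchange distribution) and an indel process (Poisson number of events,
#' geometric lengths; insertions create new true columns occupied only by
#' the inserting lineage's descendants, deletions leave gaps). The emitted
#' reference alignment is the true site homology: residues descending from
#' one ancestral or inserted site share a column.
#'
#' @param spec a [family_spec()].
#' @param case_id,dataset_id identifiers for the resulting bundle.
#' @return object of class `"synthetic_case"`: a [case_bundle()] with the
#'   generating `spec` attached as `$provenance`.
#' @export
generate_family <- function(spec, case_id = sprintf("case_%d", spec$seed),
                            dataset_id = "synthetic") {
  stopifnot(inherits(spec, "family_spec"))
  if (spec$ancestor_len < 1L) stop("ancestor_len must be positive", call. = FALSE)

  # private RNG stream, restored on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  tree <- .family_tree(spec$n_seqs, spec$tree_shape)
  depths <- .tree_depths(tree)
  t_edge <- if (spec$divergence > 0) spec$divergence / mean(depths) else 0
  p_sub <- 1 - exp(-t_edge)
  P <- .exchange_matrix()

  # global registry of true columns: site ids in alignment order
  reg <- new.env(parent = emptyenv())
  reg$order <- seq_len(spec$ancestor_len)
  reg$next_id <- spec$ancestor_len + 1L

  ancestor <- list(
    sites = seq_len(spec$ancestor_len),
    res = sample(.STANDARD_AA, spec$ancestor_len, replace = TRUE,
                 prob = .AA_BACKGROUND))

  evolve_edge <- function(state) {
    res <- state$res
    sites <- state$sites
    # substitutions
    if (p_sub > 0 && length(res) > 0L) {
      hit <- which(stats::runif(length(res)) < p_sub)
      for (i in hit) {
        res[i] <- sample(.STANDARD_AA, 1L, prob = P[res[i], ])
      }
    }
    # indels
    if (spec$indel_rate > 0 && length(sites) > 0L) {
      n_ev <- stats::rpois(1L, spec$indel_rate * length(sites))
      for (ev in seq_len(n_ev)) {
        L <- length(sites)
        len <- stats::rgeom(1L, 1 / spec$indel_len_mean) + 1L
        if (stats::runif(1L) < 0.5 && L > 10L) {
          # deletion, capped so lineages never collapse below 10 residues
          len <- min(len, L - 10L)
          if (len < 1L) next
          start <- sample.int(L - len + 1L, 1L)
          keep <- setdiff(seq_len(L), start:(start + len - 1L))
          sites <- sites[keep]
          res <- res[keep]
        } else {
          # insertion after position pos (0 = before first residue)
          pos <- sample.int(L + 1L, 1L) - 1L
          new_ids <- reg$next_id:(reg$next_id + len - 1L)
          reg$next_id <- reg$next_id + len
          anchor_at <- if (pos == 0L) {
            which(reg$order == sites[1L]) - 1L
          } else {
            which(reg$order == sites[pos])
          }
          reg$order <- append(reg$order, new_ids, after = anchor_at)
          new_res <- sample(.STANDARD_AA, len, replace = TRUE,
                            prob = .AA_BACKGROUND)
          sites <- append(sites, new_ids, after = pos)
          res <- append(res, new_res, after = pos)
        }
      }
    }
    list(sites = sites, res = res)
  }

  leaves <- vector("list", spec$n_seqs)
  descend <- function(node, state) {
    if (!is.null(node$leaf)) {
      leaves[[node$leaf]] <<- state
      return(invisible(NULL))
    }
    descend(node$left, evolve_edge(state))
    descend(node$right, evolve_edge(state))
  }
  # root edges: evolve once per child so siblings differ
  descend(tree, ancestor)

  ids <- sprintf("s%d", seq_len(spec$n_seqs))
  # true alignment: one column per site id present in >= 1 leaf
  present <- sort(unique(unlist(lapply(leaves, `[[`, "sites"))))
  cols <- reg$order[reg$order %in% present]
  rows <- vapply(leaves, function(lf) {
    r <- rep("-", length(cols))
    idx <- match(lf$sites, cols)
    r[idx] <- lf$res
    paste(r, collapse = "")
  }, character(1))

  ref <- reference_alignment(alignment(ids, rows))
  inputs <- stats::setNames(vapply(leaves, function(lf) paste(lf$res, collapse = ""),
                                   character(1)), ids)
  out <- case_bundle(case_id, dataset_id, ref, inputs)
  out$provenance <- spec
  class(out) <- c("synthetic_case", "case_bundle")
  out
}

#' Mean pairwise identity of an alignment
#'
#' Fraction of identical residues over columns where both rows hold a
#' residue, averaged over all row pairs (case-insensitive).
#'
#' @param a an [alignment()] with >= 2 rows.
#' @return numeric scalar in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(a) {
  stopifnot(inherits(a, "alignment"), a$n_rows >= 2L)
  m <- toupper(as.matrix(a))
  vals <- c()
  for (i in seq_len(a$n_rows - 1L)) {
    for (j in (i + 1L):a$n_rows) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) next
      vals <- c(vals, mean(m[i, both] == m[j, both]))
    }
  }
  mean(vals)
}

#' Degrade a reference alignment by a known amount
#'
#' Moves a random fraction of residues out of their true columns: each
#' selected residue is re-gapped into a fresh private column inserted next
#' to its original one. `shift_fraction = 0` returns the reference
#' unchanged; `shift_fraction = 1` isolates every residue, which breaks all
#' aligned pairs of a 2-row reference. Useful for producing test alignments
#' of known (decreasing) quality for the scorer.
#'
#' @param ref a [reference_alignment()].
#' @param shift_fraction fraction of residues to displace, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an [alignment()] over the same sequences.
#' @export
perturb_alignment <- function(ref, shift_fraction, seed = 1L) {
  stopifnot(inherits(ref, "reference_alignment"),
            shift_fraction >= 0, shift_fraction <= 1)
  a <- ref$alignment
  if (shift_fraction == 0) return(a)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  m <- as.matrix(a)
  res_idx <- which(m != "-")                      # column-major cell indices
  n_shift <- round(shift_fraction * length(res_idx))
  shift <- rep(FALSE, length(m))
  if (n_shift > 0L) shift[sample(res_idx, n_shift)] <- TRUE
  shift <- matrix(shift, nrow(m), ncol(m))

  out_cols <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    sel <- shift[, j] & col != "-"
    keep <- col
    keep[sel] <- "-"
    if (any(keep != "-")) out_cols[[length(out_cols) + 1L]] <- keep
    for (i in which(sel)) {
      single <- rep("-", nrow(m))
      single[i] <- col[i]
      out_cols[[length(out_cols) + 1L]] <- single
    }
  }
  om <- do.call(cbind, out_cols)
  alignment(a$ids, apply(om, 1L, paste, collapse = ""))
}

#' Packaged dataset presets
#'
#' Six [family_spec()] templates named after the strata of curated
#' benchmark collections they loosely emulate: `RV11-like` (equidistant,
#' low identity), `RV12-like` (equidistant, 20–40 % identity), `RV20-like`
#' (family plus a diverged orphan — caterpillar topology), `RV30-like`
#' (divergent subfamilies), `RV40-like` (long terminal extensions),
#' `RV50-like` (long internal insertions). They are test fixtures with
#' calibrated identity bands, not claims of equivalence to any curated
#' database. Divergences were fixed once by simulating the mean pairwise
#' identity of replicate families.
#'
#' @return named list of `"family_spec"` objects (seeds are placeholders;
#'   [generate_benchmark()] rewrites them per case).
#' @export
benchmark_presets <- function() {
  list(
    "RV11-like" = family_spec(n_seqs = 6L, ancestor_len = 120L, divergence = 1.80,
                              indel_rate = 0.02, indel_len_mean = 3,
                              tree_shape = "balanced"),
    "RV12-like" = family_spec(n_seqs = 6L, ancestor_len = 120L, divergence = 0.85,
                              indel_rate = 0.02, indel_len_mean = 3,
                              tree_shape = "balanced"),
    "RV20-like" = family_spec(n_seqs = 8L, ancestor_len = 120L, divergence = 0.70,
                              indel_rate = 0.02, indel_len_mean = 3,
                              tree_shape = "caterpillar"),
    "RV30-like" = family_spec(n_seqs = 8L, ancestor_len = 120L, divergence = 1.10,
                              indel_rate = 0.02, indel_len_mean = 3,
                              tree_shape = "balanced"),
    "RV40-like" = family_spec(n_seqs = 6L, ancestor_len = 120L, divergence = 0.70,
                              indel_rate = 0.03, indel_len_mean = 8,
                              tree_shape = "caterpillar"),
    "RV50-like" = family_spec(n_seqs = 6L, ancestor_len = 120L, divergence = 0.70,
                              indel_rate = 0.03, indel_len_mean = 10,
                              tree_shape = "balanced"))
}

#' Generate a benchmark directory
#'
#' Writes `n_per_dataset` families for each preset into
#' `out_dir/<dataset>/<case>_ref.fasta` (true alignment) and
#' `<case>_in.fasta` (unaligned inputs), plus a `manifest.tsv` that
#' [load_benchmark()] reads. Per-case seeds are derived deterministically
#' from `seed` and recorded in the manifest, so the files regenerate
#' identically.
#'
#' @param out_dir output directory; must be empty or absent unless `force`.
#' @param n_per_dataset families per dataset.
#' @param presets named list of [family_spec()] objects
#'   (default [benchmark_presets()]).
#' @param seed master seed.
#' @param force overwrite a non-empty `out_dir`.
#' @return the manifest data frame, invisibly.
#' @export
generate_benchmark <- function(out_dir, n_per_dataset = 3L,
                               presets = benchmark_presets(), seed = 1L,
                               force = FALSE) {
  stopifnot(length(presets) >= 1L, !is.null(names(presets)), n_per_dataset >= 1L)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)", out_dir),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (d in seq_along(presets)) {
    ds <- names(presets)[d]
    ds_dir <- file.path(out_dir, ds)
    dir.create(ds_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_dataset)) {
      case_seed <- (as.integer(seed) * 7919L + d * 1009L + i * 97L) %% 2147483647L
      sp <- presets[[d]]
      sp$seed <- case_seed
      case_id <- sprintf("%s_%02d", gsub("-like$", "", ds), i)
      case <- generate_family(sp, case_id = case_id, dataset_id = ds)
      ref_rel <- file.path(ds, paste0(case_id, "_ref.fasta"))
      in_rel <- file.path(ds, paste0(case_id, "_in.fasta"))
      write_fasta_alignment(case$reference$alignment, file.path(out_dir, ref_rel))
      write_sequences(case$inputs, file.path(out_dir, in_rel))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = ds, case_id = case_id, ref_path = ref_rel, in_path = in_rel,
        seed = case_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
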