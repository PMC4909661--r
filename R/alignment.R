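# Core containers: gapped alignments, reference alignments, benchmark cases.

.GAP <- "-"
# 20 standard residues plus the ambiguity/rare codes seen in curated benchmarks
.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYBZXUO", "")[[1]]

#' Normalize gap characters to '-'
#'
#' Accepts the '.', '~' and '-' gap conventions used by FASTA and GCG MSF
#' dialects and rewrites them all to '-'.
#'
#' @param x character vector of (possibly gapped) sequence strings.
#' @return character vector with all gaps written as '-'.
#' @keywords internal
normalize_gaps <- function(x) {
  chartr(".~", "--", x)
}

.validate_residues <- function(s, id, gapped = FALSE) {
  chars <- unique(strsplit(toupper(s), "")[[1]])
  allowed <- if (gapped) c(.AA_LETTERS, .GAP) else .AA_LETTERS
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue character(s) %s in sequence '%s'",
                 paste(sQuote(bad), collapse = ", "), id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a gapped multiple sequence alignment
#'
#' An alignment is a rectangular set of gapped rows: every row has the same
#' number of columns and a unique id. Gap characters '.', '~' and '-' are
#' accepted and normalized to '-'; letter case is preserved (curated
#' benchmarks use case to mark reliably aligned regions), but all scoring in
#' this package is case-insensitive.
#'
#' @param ids character vector of unique, non-empty row identifiers.
#' @param gapped character vector of gapped row strings, one per id, all of
#'   identical length.
#' @return An object of class `"alignment"` with fields `ids`, `seqs`
#'   (gap-normalized rows), `n_rows` and `n_cols`.
#' @examples
#' a <- alignment(c("s1", "s2"), c("AC-D", "ACED"))
#' a$n_cols
#' @export
alignment <- function(ids, gapped) {
  ids <- as.character(ids)
  gapped <- normalize_gaps(as.character(gapped))
  if (length(ids) != length(gapped)) {
    stop("ids and gapped rows differ in length", call. = FALSE)
  }
  if (length(ids) == 0L) stop("alignment has no rows", call. = FALSE)
  if (any(!nzchar(ids))) stop("empty row id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate row id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  lens <- nchar(gapped)
  if (length(unique(lens)) != 1L) {
    ref_len <- lens[1L]
    off <- ids[which(lens != ref_len)[1L]]
    stop(sprintf("ragged alignment: row '%s' has %d columns, expected %d",
                 off, lens[ids == off][1L], ref_len), call. = FALSE)
  }
  for (i in seq_along(ids)) .validate_residues(gapped[i], ids[i], gapped = TRUE)
  structure(list(ids = ids, seqs = unname(gapped),
                 n_rows = length(ids), n_cols = lens[1L]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d rows x %d columns\n", x$n_rows, x$n_cols))
  show_n <- min(x$n_rows, 6L)
  w <- max(nchar(x$ids[seq_len(show_n)]))
  for (i in seq_len(show_n)) {
    s <- x$seqs[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-*s %s\n", w, x$ids[i], s))
  }
  if (x$n_rows > show_n) cat(sprintf("  ... %d more rows\n", x$n_rows - show_n))
  invisible(x)
}

#' @export
as.matrix.alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

#' Remove gaps from alignment rows
#'
#' @param a an [alignment()].
#' @return named character vector of ungapped sequences, in row order.
#' @export
ungap <- function(a) {
  stopifnot(inherits(a, "alignment"))
  out <- gsub("-", "", a$seqs, fixed = TRUE)
  names(out) <- a$ids
  out
}

#' Construct a reference alignment with an optional core-column mask
#'
#' A reference alignment defines the ground-truth residue pairings used by
#' [sps()] and [cs()]. The optional core mask restricts scoring to annotated
#' reliably aligned columns (the usual practice with curated benchmark
#' references).
#'
#' @param aln an [alignment()] with at least 2 rows.
#' @param core_mask optional logical vector of length `aln$n_cols`; `TRUE`
#'   marks columns that participate in scoring. Must contain at least one
#'   `TRUE` when supplied.
#' @return object of class `"reference_alignment"`.
#' @export
reference_alignment <- function(aln, core_mask = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (!is.null(core_mask)) {
    core_mask <- as.logical(core_mask)
    if (length(core_mask) != aln$n_cols) {
      stop(sprintf("core_mask length %d does not match %d columns",
                   length(core_mask), aln$n_cols), call. = FALSE)
    }
    if (anyNA(core_mask)) stop("core_mask contains NA", call. = FALSE)
    if (!any(core_mask)) stop("core_mask selects no columns", call. = FALSE)
  }
  structure(list(alignment = aln, core_mask = core_mask),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat("reference ")
  print(x$alignment)
  if (!is.null(x$core_mask)) {
    cat(sprintf("  core mask: %d of %d columns scored\n",
                sum(x$core_mask), length(x$core_mask)))
  }
  invisible(x)
}

#' Validate a set of unaligned sequences
#'
#' @param seqs named character vector: names are unique ids, values ungapped
#'   amino-acid sequences.
#' @return the validated (invisible) vector.
#' @keywords internal
validate_sequences <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("sequences must carry non-empty ids", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence '%s'", ids[which(!nzchar(seqs))[1L]]),
         call. = FALSE)
  }
  for (i in seq_along(seqs)) .validate_residues(seqs[[i]], ids[i])
  invisible(seqs)
}

#' Bundle one benchmark case
#'
#' A case couples a reference alignment with the unaligned input sequences an
#' aligner is given, under a case id and a dataset id (e.g. "RV11"). The
#' input ids must equal the reference row ids and each input must equal the
#' ungapped content of its reference row.
#'
#' @param case_id,dataset_id character scalars.
#' @param reference a [reference_alignment()].
#' @param inputs named character vector of ungapped sequences.
#' @return object of class `"case_bundle"`.
#' @export
case_bundle <- function(case_id, dataset_id, reference, inputs) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id),
            is.character(dataset_id), length(dataset_id) == 1L,
            inherits(reference, "reference_alignment"))
  validate_sequences(inputs)
  ref_ungapped <- ungap(reference$alignment)
  if (!setequal(names(inputs), names(ref_ungapped))) {
    stop(sprintf("case '%s': input ids do not match reference row ids",
                 case_id), call. = FALSE)
  }
  for (id in names(inputs)) {
    if (toupper(inputs[[id]]) != toupper(ref_ungapped[[id]])) {
      stop(sprintf("case '%s': input '%s' differs from ungapped reference row",
                   case_id, id), call. = FALSE)
    }
  }
  structure(list(case_id = case_id, dataset_id = dataset_id,
                 reference = reference, inputs = inputs),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("case '%s' (dataset %s): %d sequences, reference %d columns\n",
              x$case_id, x$dataset_id, length(x$inputs),
              x$reference$alignment$n_cols))
  invisible(x)
}
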