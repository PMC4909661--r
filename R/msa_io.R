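# Readers and writers: aligned/unaligned FASTA, GCG MSF, core-column
# annotations, and the benchmark-directory layout.

.read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  seqs <- as.character(set)
  # FASTA headers: the id is the first whitespace-delimited token
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate id(s) in '%s': %s", path, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Read an aligned FASTA file
#'
#' All records must have identical gapped length. Gap characters '-' and '.'
#' are normalized to '-'; record order and letter case are preserved.
#'
#' @param path path to an aligned FASTA file.
#' @return an [alignment()].
#' @export
read_fasta_alignment <- function(path) {
  seqs <- .read_fasta_raw(path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- names(seqs)[which(lens != lens[1L])[1L]]
    stop(sprintf("ragged alignment in '%s': record '%s' has length %d, expected %d",
                 path, off, lens[[off]], lens[[1L]]), call. = FALSE)
  }
  alignment(names(seqs), unname(seqs))
}

#' Write an alignment as aligned FASTA
#'
#' @param a an [alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(a, path) {
  stopifnot(inherits(a, "alignment"))
  set <- Biostrings::BStringSet(stats::setNames(a$seqs, a$ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read unaligned sequences from FASTA
#'
#' Gap characters, if present, are stripped with a warning.
#'
#' @param path path to a FASTA file.
#' @return named character vector of ungapped sequences, in file order.
#' @export
read_sequences <- function(path) {
  seqs <- .read_fasta_raw(path)
  norm <- normalize_gaps(seqs)
  if (any(grepl("-", norm, fixed = TRUE))) {
    warning(sprintf("gap characters stripped from sequences in '%s'", path),
            call. = FALSE)
    norm <- gsub("-", "", norm, fixed = TRUE)
  }
  names(norm) <- names(seqs)
  validate_sequences(norm)
  norm
}

#' Write unaligned sequences as FASTA
#'
#' @param seqs named character vector of ungapped sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  validate_sequences(seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a GCG MSF alignment
#'
#' Parses the interleaved GCG MSF dialect (header terminated by "..",
#' `Name:` lines, interleaved sequence blocks). Gap characters '.' and '~'
#' are converted to '-'. A missing checksum section is tolerated.
#'
#' @param path path to an MSF file.
#' @return an [alignment()].
#' @export
read_msf_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sep <- grep("\\.\\.\\s*$", lines)
  if (length(sep) == 0L) {
    stop(sprintf("not an MSF file (missing '..' header separator): %s", path),
         call. = FALSE)
  }
  sep <- sep[1L]
  # GCG layout: '..' ends the file description; 'Name:' lines follow it,
  # then an optional '//' line, then the interleaved sequence blocks
  name_lines <- grep("^\\s*Name:", lines, value = TRUE)
  declared <- sub("^\\s*Name:\\s*(\\S+).*$", "\\1", name_lines)
  if (!any(grepl("Check:", lines))) {
    message(sprintf("MSF '%s': no checksum section (ignored)", path))
  }
  body <- lines[-seq_len(sep)]
  chunks <- list()
  for (ln in body) {
    ln <- sub("^\\s+", "", ln)
    if (!nzchar(ln)) next
    if (grepl("^Name:", ln) || grepl("^//", ln)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    # column-ruler lines contain only numbers
    if (all(grepl("^[0-9]+$", toks))) next
    id <- toks[1L]
    if (length(toks) < 2L) next
    chunks[[id]] <- c(chunks[[id]], paste(toks[-1L], collapse = ""))
  }
  if (length(chunks) == 0L) {
    stop(sprintf("MSF file has no sequence blocks: %s", path), call. = FALSE)
  }
  if (length(declared) > 0L) {
    missing <- setdiff(declared, names(chunks))
    if (length(missing) > 0L) {
      stop(sprintf("MSF '%s': sequence(s) named in header but absent from blocks: %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    }
    ids <- declared
  } else {
    ids <- names(chunks)
  }
  gapped <- vapply(chunks[ids], paste, character(1), collapse = "")
  alignment(ids, unname(gapped))
}

#' Write an alignment in GCG MSF format
#'
#' @param a an [alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msf_alignment <- function(a, path) {
  stopifnot(inherits(a, "alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!!AA_MULTIPLE_ALIGNMENT 1.0", con)
  writeLines("", con)
  writeLines(sprintf(" alignment.msf  MSF: %d  Type: P  Check: 0  ..", a$n_cols), con)
  writeLines("", con)
  w <- max(nchar(a$ids))
  for (i in seq_len(a$n_rows)) {
    writeLines(sprintf(" Name: %-*s  Len: %d  Check: 0  Weight: 1.00",
                       w, a$ids[i], a$n_cols), con)
  }
  writeLines(c("", "//"), con)
  block <- 50L
  starts <- seq(1L, a$n_cols, by = block)
  for (s in starts) {
    writeLines("", con)
    e <- min(s + block - 1L, a$n_cols)
    for (i in seq_len(a$n_rows)) {
      seg <- substr(a$seqs[i], s, e)
      # MSF convention writes gaps as '.', in groups of 10
      seg <- gsub("-", ".", seg, fixed = TRUE)
      grp <- regmatches(seg, gregexpr(".{1,10}", seg))[[1]]
      writeLines(sprintf("%-*s  %s", w, a$ids[i], paste(grp, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a core-column annotation file
#'
#' The file lists whitespace-separated 1-based inclusive column ranges, e.g.
#' `"3-10 25-40"`; single columns may be given as `"7"`. Overlapping ranges
#' are merged with a warning.
#'
#' @param path path to the annotation file.
#' @param n_cols number of columns of the alignment the mask applies to.
#' @return logical vector of length `n_cols`.
#' @export
read_core_annotation <- function(path, n_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  stopifnot(is.numeric(n_cols), n_cols >= 1L)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) == 0L) stop(sprintf("empty annotation file: %s", path), call. = FALSE)
  mask <- logical(n_cols)
  covered <- 0L
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([0-9]+)(-([0-9]+))?$", tk))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed range '%s' in %s", tk, path), call. = FALSE)
    }
    a <- as.integer(m[2L])
    b <- if (nzchar(m[4L])) as.integer(m[4L]) else a
    if (a < 1L || b > n_cols || a > b) {
      stop(sprintf("range '%s' outside columns 1-%d", tk, n_cols), call. = FALSE)
    }
    mask[a:b] <- TRUE
    covered <- covered + (b - a + 1L)
  }
  if (covered > sum(mask)) {
    warning("overlapping column ranges merged", call. = FALSE)
  }
  mask
}

#' Load a benchmark case from files
#'
#' Reads a reference alignment (FASTA or MSF, chosen by file extension), the
#' unaligned input FASTA and an optional core-column annotation, and returns
#' a validated [case_bundle()].
#'
#' @param ref_path reference alignment file (`.msf` is parsed as GCG MSF,
#'   anything else as aligned FASTA).
#' @param in_path unaligned input FASTA; when `NULL`, inputs are taken as the
#'   ungapped reference rows.
#' @param core_path optional core-annotation file.
#' @param case_id,dataset_id identifiers; `case_id` defaults to the reference
#'   file name without extension.
#' @return a [case_bundle()].
#' @export
load_case <- function(ref_path, in_path = NULL, core_path = NULL,
                      case_id = NULL, dataset_id = "default") {
  ext <- tolower(tools::file_ext(ref_path))
  ref_aln <- if (ext == "msf") read_msf_alignment(ref_path) else read_fasta_alignment(ref_path)
  core <- if (!is.null(core_path)) read_core_annotation(core_path, ref_aln$n_cols) else NULL
  ref <- reference_alignment(ref_aln, core)
  inputs <- if (is.null(in_path)) ungap(ref_aln) else read_sequences(in_path)
  if (is.null(case_id)) {
    case_id <- sub("_ref$", "", tools::file_path_sans_ext(basename(ref_path)))
  }
  case_bundle(case_id, dataset_id, ref, inputs)
}

#' Load a benchmark directory via its manifest
#'
#' Expects the layout written by [generate_benchmark()]: a `manifest.tsv`
#' with columns `dataset_id`, `case_id`, `ref_path`, `in_path` (paths
#' relative to the directory) and optionally `core_path` and `seed`.
#'
#' @param dir benchmark directory containing `manifest.tsv`.
#' @return list of [case_bundle()] objects.
#' @export
load_benchmark <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.tsv under '%s'", dir), call. = FALSE)
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  req <- c("dataset_id", "case_id", "ref_path", "in_path")
  if (!all(req %in% names(man))) {
    stop(sprintf("manifest lacks required column(s): %s",
                 paste(setdiff(req, names(man)), collapse = ", ")), call. = FALSE)
  }
  cases <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    core <- if ("core_path" %in% names(man) && nzchar(man$core_path[i]) &&
                !is.na(man$core_path[i])) file.path(dir, man$core_path[i]) else NULL
    cases[[i]] <- tryCatch(
      load_case(file.path(dir, man$ref_path[i]), file.path(dir, man$in_path[i]),
                core_path = core, case_id = man$case_id[i],
                dataset_id = man$dataset_id[i]),
      error = function(e) {
        message(sprintf("ERROR loading case '%s': %s (skipped)",
                        man$case_id[i], conditionMessage(e)))
        NULL
      })
  }
  Filter(Negate(is.null), cases)
}
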