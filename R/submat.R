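# Substitution matrices: the six NCBI tables swept by the pipeline, plus
# lookups for the built-in aligner.

.MATRIX_NAMES <- c("BLOSUM30", "BLOSUM45", "BLOSUM62", "BLOSUM80",
                   "PAM100", "PAM200")

.matrix_cache <- new.env(parent = emptyenv())

#' Names of the packaged substitution matrices
#'
#' The six matrices swept by default, in their canonical listing order
#' (BLOSUM30, BLOSUM45, BLOSUM62, BLOSUM80, PAM100, PAM200). This order also
#' breaks ties in [select_optimal()].
#'
#' @return character vector of matrix names.
#' @export
matrix_names <- function() .MATRIX_NAMES

#' Read a substitution matrix in NCBI whitespace-table format
#'
#' The format is the classic NCBI layout: '#' comment lines, a header row of
#' residue letters, then one row per residue beginning with its letter.
#'
#' @param path path to the matrix file.
#' @param name name to attach to the matrix.
#' @return object of class `"substitution_matrix"`: a list with `name`,
#'   `alphabet` and integer matrix `scores` (symmetric, residues as dimnames).
#' @export
read_matrix_file <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("malformed matrix file: %s", path), call. = FALSE)
  alphabet <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- length(alphabet)
  scores <- matrix(NA_integer_, n, n, dimnames = list(alphabet, alphabet))
  for (ln in lines[-1L]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    res <- toks[1L]
    vals <- suppressWarnings(as.integer(toks[-1L]))
    if (!(res %in% alphabet) || length(vals) != n || anyNA(vals)) {
      stop(sprintf("malformed matrix row '%s' in %s", res, path), call. = FALSE)
    }
    scores[res, ] <- vals
  }
  if (anyNA(scores)) stop(sprintf("incomplete matrix in %s", path), call. = FALSE)
  if (!isTRUE(all.equal(scores, t(scores)))) {
    stop(sprintf("matrix in %s is not symmetric", path), call. = FALSE)
  }
  structure(list(name = name, alphabet = alphabet, scores = scores),
            class = "substitution_matrix")
}

#' Get one of the packaged substitution matrices
#'
#' Returns the canonical NCBI integer score table for the requested name
#' (case-insensitive), loaded from the text tables shipped with the package.
#'
#' @param name one of `matrix_names()`.
#' @return a `"substitution_matrix"` (see [read_matrix_file()]).
#' @examples
#' m <- get_matrix("BLOSUM62")
#' m$scores["W", "W"]
#' @export
get_matrix <- function(name) {
  key <- toupper(as.character(name)[1L])
  if (!(key %in% .MATRIX_NAMES)) {
    stop(sprintf("unknown substitution matrix '%s'; valid names: %s",
                 name, paste(.MATRIX_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (is.null(.matrix_cache[[key]])) {
    path <- system.file("extdata", "matrices", paste0(key, ".mat"),
                        package = "alnsweep", mustWork = TRUE)
    .matrix_cache[[key]] <- read_matrix_file(path, name = key)
  }
  .matrix_cache[[key]]
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("substitution matrix %s: %d x %d\n",
              x$name, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

.unknown_logged <- new.env(parent = emptyenv())

#' Normalize residues to a matrix alphabet
#'
#' Uppercases and maps any residue absent from the matrix alphabet (e.g. J,
#' U, O against an NCBI table) to 'X'. The remapping is logged once per
#' matrix per session.
#'
#' @param m a `"substitution_matrix"`.
#' @param res character vector of single residues.
#' @return character vector of residues present in `m$alphabet`.
#' @keywords internal
normalize_residues <- function(m, res) {
  res <- toupper(res)
  unknown <- !(res %in% m$alphabet)
  if (any(unknown)) {
    key <- paste0(m$name, ":", paste(sort(unique(res[unknown])), collapse = ""))
    if (is.null(.unknown_logged[[key]])) {
      message(sprintf("residue(s) %s not in %s alphabet: scored as X",
                      paste(sort(unique(res[unknown])), collapse = ", "), m$name))
      .unknown_logged[[key]] <- TRUE
    }
    res[unknown] <- "X"
  }
  res
}

#' Look up a residue-pair score
#'
#' @param m a `"substitution_matrix"`.
#' @param a,b single residue characters; residues outside the matrix alphabet
#'   are scored as 'X'.
#' @return integer score.
#' @export
pair_score <- function(m, a, b) {
  stopifnot(inherits(m, "substitution_matrix"))
  a <- normalize_residues(m, a)
  b <- normalize_residues(m, b)
  unname(m$scores[cbind(a, b)])
}
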