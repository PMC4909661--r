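# Pluggable aligner execution: the built-in progressive aligner or any
# external command-line tool described by a command template.

#' Describe an aligner
#'
#' An aligner spec is either the built-in progressive aligner or an external
#' command described by a whitespace-tokenized template with placeholders
#' `{input}`, `{output}`, `{gop}`, `{gep}` and `{matrix_flag}`. Tools that
#' write the alignment to standard output use a `">"` token before
#' `{output}`; the runner captures stdout to that path instead of passing it
#' as an argument (no shell is ever involved).
#'
#' @param name aligner name.
#' @param command_template command template string; must contain `{input}`
#'   and `{output}`.
#' @param matrix_flag_map named character vector mapping matrix names to the
#'   flag fragment substituted for `{matrix_flag}` (e.g.
#'   `c(BLOSUM62 = "--bl 62")`). Required for external aligners swept over
#'   matrices.
#' @param timeout_s kill the external process after this many seconds.
#' @param is_builtin dispatch to [progressive_align()] instead of running a
#'   command.
#' @return object of class `"aligner_spec"`.
#' @export
aligner_spec <- function(name, command_template = NULL, matrix_flag_map = NULL,
                         timeout_s = 600L, is_builtin = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is_builtin) {
    if (is.null(command_template) ||
        !grepl("{input}", command_template, fixed = TRUE) ||
        !grepl("{output}", command_template, fixed = TRUE)) {
      stop("command_template must contain {input} and {output} placeholders",
           call. = FALSE)
    }
  }
  structure(list(name = name, command_template = command_template,
                 matrix_flag_map = matrix_flag_map,
                 timeout_s = as.integer(timeout_s), is_builtin = is_builtin),
            class = "aligner_spec")
}

#' The built-in aligner spec
#'
#' @return an `"aligner_spec"` dispatching to [progressive_align()].
#' @export
builtin_aligner <- function() {
  aligner_spec("builtin", is_builtin = TRUE)
}

#' Render the command line for one parameter combination
#'
#' Substitutes the placeholders of an external aligner template and returns
#' the argument vector verbatim — user data is never interpreted by a shell.
#' Numeric parameters are formatted exactly as the decimally-rounded grid
#' values print, so distinct combinations always render distinct commands.
#'
#' @param spec an external `"aligner_spec"`.
#' @param combo one-row data frame or list with `matrix`, `gop`, `gep`.
#' @param in_path,out_path input/output file paths.
#' @return list with `command` (program), `args` (character vector) and
#'   `stdout` (`out_path` when the template redirects, otherwise `""`).
#' @export
render_command <- function(spec, combo, in_path, out_path) {
  stopifnot(inherits(spec, "aligner_spec"))
  if (spec$is_builtin) stop("builtin aligner has no command line", call. = FALSE)
  mat <- as.character(combo$matrix)
  flag <- ""
  if (grepl("{matrix_flag}", spec$command_template, fixed = TRUE)) {
    if (is.null(spec$matrix_flag_map) || !(mat %in% names(spec$matrix_flag_map))) {
      stop(sprintf("aligner '%s' has no matrix flag mapping for '%s'",
                   spec$name, mat), call. = FALSE)
    }
    flag <- spec$matrix_flag_map[[mat]]
  }
  subst <- c("{input}" = in_path, "{output}" = out_path,
             "{gop}" = format(combo$gop, trim = TRUE, scientific = FALSE),
             "{gep}" = format(combo$gep, trim = TRUE, scientific = FALSE))
  toks <- strsplit(trimws(spec$command_template), "\\s+")[[1]]
  out <- character(0)
  for (tk in toks) {
    if (tk == "{matrix_flag}") {
      if (nzchar(flag)) out <- c(out, strsplit(trimws(flag), "\\s+")[[1]])
      next
    }
    for (ph in names(subst)) tk <- gsub(ph, subst[[ph]], tk, fixed = TRUE)
    out <- c(out, tk)
  }
  stdout_path <- ""
  redir <- which(out == ">")
  if (length(redir) == 1L && redir < length(out)) {
    stdout_path <- out[redir + 1L]
    out <- out[-c(redir, redir + 1L)]
  }
  list(command = out[1L], args = out[-1L], stdout = stdout_path)
}

#' Run an aligner on one case
#'
#' Writes the case inputs to FASTA, executes the aligner for the given
#' parameter combination, parses the resulting alignment and verifies that
#' every output row ungaps to its input sequence. Failures (non-zero exit,
#' timeout, missing output) are returned as an `"aligner_failure"` record so
#' a sweep can continue; an output that parses but does not conserve the
#' input sequences is raised as an error (an integrity violation, not a
#' tool failure).
#'
#' @param spec an `"aligner_spec"`.
#' @param combo list or one-row data frame with `matrix`, `gop`, `gep`.
#' @param case a [case_bundle()].
#' @param workdir scratch directory for the input/output files of external
#'   runs (created if missing, case files removed afterwards).
#' @return an [alignment()], or an `"aligner_failure"` (list with `case_id`,
#'   `status`, `stderr`).
#' @export
run_aligner <- function(spec, combo, case, workdir = tempdir()) {
  stopifnot(inherits(spec, "aligner_spec"), inherits(case, "case_bundle"))
  if (spec$is_builtin) {
    return(progressive_align(case$inputs, get_matrix(as.character(combo$matrix)),
                             combo$gop, combo$gep))
  }
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  stem <- sprintf("%s_%s_%s_%s", case$case_id, combo$matrix,
                  format(combo$gop, trim = TRUE), format(combo$gep, trim = TRUE))
  in_path <- file.path(workdir, paste0(stem, "_in.fasta"))
  out_path <- file.path(workdir, paste0(stem, "_out.fasta"))
  err_path <- file.path(workdir, paste0(stem, ".stderr"))
  on.exit(unlink(c(in_path, out_path, err_path)), add = TRUE)
  write_sequences(case$inputs, in_path)
  cmd <- render_command(spec, combo, in_path, out_path)
  status <- tryCatch(
    system2(cmd$command, cmd$args,
            stdout = if (nzchar(cmd$stdout)) cmd$stdout else FALSE,
            stderr = err_path, timeout = spec$timeout_s),
    error = function(e) -1L, warning = function(w) -1L)
  stderr_txt <- if (file.exists(err_path)) {
    paste(readLines(err_path, warn = FALSE), collapse = "\n")
  } else ""
  if (!identical(as.integer(status), 0L) || !file.exists(out_path)) {
    return(structure(list(case_id = case$case_id, status = status,
                          stderr = stderr_txt),
                     class = "aligner_failure"))
  }
  out <- read_fasta_alignment(out_path)
  got <- ungap(out)
  if (!setequal(names(got), names(case$inputs)) ||
      any(toupper(got[names(case$inputs)]) != toupper(case$inputs))) {
    stop(sprintf("aligner '%s' output for case '%s' does not conserve the input sequences",
                 spec$name, case$case_id), call. = FALSE)
  }
  # emit rows in the case input order
  ord <- match(names(case$inputs), out$ids)
  alignment(out$ids[ord], out$seqs[ord])
}

#' Read aligner specs from a YAML config
#'
#' The config maps aligner names to fields of [aligner_spec()] (see
#' `system.file("extdata", "aligners", "aligners.yaml", package =
#' "alnsweep")` for packaged MAFFT and CLUSTALW templates).
#'
#' @param path YAML file.
#' @return named list of `"aligner_spec"` objects.
#' @export
read_aligner_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read aligner configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(cfg)) {
    e <- cfg[[nm]]
    out[[nm]] <- aligner_spec(
      name = nm,
      command_template = e$command_template,
      matrix_flag_map = if (!is.null(e$matrix_flag_map)) unlist(e$matrix_flag_map),
      timeout_s = if (!is.null(e$timeout_s)) e$timeout_s else 600L,
      is_builtin = isTRUE(e$is_builtin))
  }
  out
}
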