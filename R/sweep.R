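# Parameter-grid construction and sweep execution over cases x combinations.

.decimal_places <- function(x) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0L) 0L else nchar(s) - dot
}

#' Specify a GOP x GEP x matrix grid
#'
#' Grid values are integer multiples of the step from the minimum, rounded
#' to the step's decimal precision, so they serialize losslessly and act as
#' stable keys (`1.2`, never `1.2000000000000002`). The default ranges span
#' GOP 0.1–3.0 in steps of 0.1 and GEP 0.03–1.50 in steps of 0.03 over all
#' six packaged matrices.
#'
#' @param gop_min,gop_max,gop_step gap-open penalty range and step.
#' @param gep_min,gep_max,gep_step gap-extension penalty range and step.
#' @param matrices matrix names to sweep, in tie-break order.
#' @return object of class `"grid_spec"`.
#' @export
grid_spec <- function(gop_min = 0.1, gop_max = 3.0, gop_step = 0.1,
                      gep_min = 0.03, gep_max = 1.50, gep_step = 0.03,
                      matrices = matrix_names()) {
  stopifnot(gop_min <= gop_max, gep_min <= gep_max,
            gop_step > 0, gep_step > 0, length(matrices) >= 1L)
  structure(list(gop_min = gop_min, gop_max = gop_max, gop_step = gop_step,
                 gep_min = gep_min, gep_max = gep_max, gep_step = gep_step,
                 matrices = toupper(matrices)),
            class = "grid_spec")
}

.grid_values <- function(lo, hi, step) {
  digits <- max(.decimal_places(lo), .decimal_places(step))
  k <- 0:floor((hi - lo) / step + 1e-9)
  round(lo + k * step, digits)
}

#' Expand a grid spec into parameter combinations
#'
#' @param spec a [grid_spec()].
#' @return data frame with columns `matrix`, `gop`, `gep`, ordered by matrix
#'   list order, then GOP ascending, then GEP ascending.
#' @examples
#' nrow(build_grid(grid_spec(1.0, 1.2, 0.1, 0.03, 0.06, 0.03, "BLOSUM62")))  # 6
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  gops <- .grid_values(spec$gop_min, spec$gop_max, spec$gop_step)
  geps <- .grid_values(spec$gep_min, spec$gep_max, spec$gep_step)
  if (length(gops) == 0L || length(geps) == 0L) {
    stop("empty parameter grid", call. = FALSE)
  }
  grid <- expand.grid(gep = geps, gop = gops, matrix = spec$matrices,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("matrix", "gop", "gep")]
  rownames(grid) <- NULL
  grid
}

.fmt_num <- function(x) {
  # element-wise: vectorized format() pads to a common width, which would
  # make checkpoint keys depend on their neighbours
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), character(1))
}

.combo_key <- function(case_id, matrix, gop, gep) {
  paste(case_id, matrix, .fmt_num(gop), .fmt_num(gep), sep = "\r")
}

.empty_sweep_table <- function() {
  data.frame(dataset_id = character(0), case_id = character(0),
             matrix = character(0), gop = numeric(0), gep = numeric(0),
             sps = numeric(0), cs = numeric(0), status = character(0),
             runtime_s = numeric(0), stringsAsFactors = FALSE)
}

#' Run a parameter sweep
#'
#' Evaluates every (case, combination) cell: aligns the case inputs with the
#' given aligner and parameters, scores the result against the case
#' reference with [sps()] and [cs()], and records one row per cell. Cells
#' whose aligner run fails are recorded with status `"FAILED"` (and `NA`
#' scores) rather than dropped; unreadable cases are skipped entirely (they
#' are absent from the table, which is a different condition from FAILED).
#'
#' When `checkpoint` is given, finished cells are appended to that TSV as
#' they complete and an interrupted sweep resumes without recomputing them.
#'
#' @param cases list of [case_bundle()] objects.
#' @param grid data frame from [build_grid()].
#' @param spec an `"aligner_spec"` (default: the built-in aligner).
#' @param checkpoint optional TSV path for incremental results / resume.
#' @param use_core_mask passed to [sps()]/[cs()].
#' @param workdir scratch directory for external aligner files.
#' @param verbose log one line per case.
#' @return the sweep table: data frame with columns `dataset_id`, `case_id`,
#'   `matrix`, `gop`, `gep`, `sps`, `cs`, `status`, `runtime_s`, sorted by
#'   (dataset, case, matrix order, gop, gep).
#' @export
run_sweep <- function(cases, grid, spec = builtin_aligner(), checkpoint = NULL,
                      use_core_mask = TRUE, workdir = tempdir(), verbose = FALSE) {
  stopifnot(length(cases) >= 1L, nrow(grid) >= 1L, inherits(spec, "aligner_spec"))
  done <- .empty_sweep_table()
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.delim(checkpoint, stringsAsFactors = FALSE)
  }
  done_keys <- .combo_key(done$case_id, done$matrix, done$gop, done$gep)
  rows <- list()
  matrix_rank <- stats::setNames(seq_along(unique(grid$matrix)), unique(grid$matrix))
  for (case in cases) {
    t_case <- Sys.time()
    n_new <- 0L
    for (g in seq_len(nrow(grid))) {
      combo <- grid[g, ]
      key <- .combo_key(case$case_id, combo$matrix, combo$gop, combo$gep)
      if (key %in% done_keys) next
      t0 <- Sys.time()
      aln <- tryCatch(run_aligner(spec, combo, case, workdir = workdir),
                      error = function(e) {
                        structure(list(case_id = case$case_id, status = NA_integer_,
                                       stderr = conditionMessage(e)),
                                  class = "aligner_failure")
                      })
      rt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      if (inherits(aln, "aligner_failure")) {
        rec <- data.frame(dataset_id = case$dataset_id, case_id = case$case_id,
                          matrix = combo$matrix, gop = combo$gop, gep = combo$gep,
                          sps = NA_real_, cs = NA_real_, status = "FAILED",
                          runtime_s = rt, stringsAsFactors = FALSE)
      } else {
        sc <- sps(aln, case$reference, use_core_mask = use_core_mask)
        cv <- cs(aln, case$reference, use_core_mask = use_core_mask)
        rec <- data.frame(dataset_id = case$dataset_id, case_id = case$case_id,
                          matrix = combo$matrix, gop = combo$gop, gep = combo$gep,
                          sps = sc$sps, cs = cv, status = "OK",
                          runtime_s = rt, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- rec
      n_new <- n_new + 1L
      if (!is.null(checkpoint)) {
        utils::write.table(rec, checkpoint, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !file.exists(checkpoint),
                           append = file.exists(checkpoint))
      }
    }
    if (verbose) {
      message(sprintf("case %s: %d cell(s) computed in %.1fs", case$case_id,
                      n_new, as.numeric(difftime(Sys.time(), t_case, units = "secs"))))
    }
  }
  tab <- rbind(done, do.call(rbind, c(list(.empty_sweep_table()), rows)))
  # keep only cells of the requested cases (a resumed checkpoint may hold more)
  tab <- tab[tab$case_id %in% vapply(cases, `[[`, character(1), "case_id"), ,
             drop = FALSE]
  ord <- order(tab$dataset_id, tab$case_id,
               matrix_rank[tab$matrix], tab$gop, tab$gep)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write / read a sweep table as TSV
#'
#' @param tab sweep table data frame.
#' @param path TSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_sweep_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
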