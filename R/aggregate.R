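# Reductions of a sweep table into the parameter-selection outputs:
# MEAN_SPS per combination per dataset, MAX_MEAN_SPS per matrix, and the
# optimal (matrix, GOP, GEP) per dataset; plus named-parameter-set
# comparison reports.

#' Mean SPS per (dataset, combination)
#'
#' MEAN_SPS: the unweighted arithmetic mean of the SPS over the cases of a
#' dataset at one (matrix, GOP, GEP) combination — each reference alignment
#' counts once. FAILED cells are excluded from the mean and counted in
#' `n_failed` (set `fail_as_zero = TRUE` for the harsher convention that
#' scores a failure as 0). A group with no successful cell is emitted with
#' `mean_sps = NA` and a warning.
#'
#' @param tab sweep table from [run_sweep()].
#' @param fail_as_zero score FAILED cells as 0 instead of excluding them.
#' @return data frame with columns `dataset_id`, `matrix`, `gop`, `gep`,
#'   `mean_sps`, `n_cases`, `n_failed`.
#' @export
mean_sps <- function(tab, fail_as_zero = FALSE) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1L)
  sps_val <- tab$sps
  if (fail_as_zero) sps_val[tab$status == "FAILED"] <- 0
  key <- interaction(tab$dataset_id, tab$matrix, tab$gop, tab$gep, drop = TRUE)
  idx <- split(seq_len(nrow(tab)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    ok <- !is.na(sps_val[ii])
    data.frame(dataset_id = tab$dataset_id[ii[1L]],
               matrix = tab$matrix[ii[1L]],
               gop = tab$gop[ii[1L]], gep = tab$gep[ii[1L]],
               mean_sps = if (any(ok)) mean(sps_val[ii][ok]) else NA_real_,
               n_cases = sum(ok),
               n_failed = sum(tab$status[ii] == "FAILED"),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(out$mean_sps)) {
    warning(sprintf("%d (dataset, combination) group(s) have no successful case",
                    sum(is.na(out$mean_sps))), call. = FALSE)
  }
  out <- out[order(out$dataset_id, out$matrix, out$gop, out$gep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MAX_MEAN_SPS per (dataset, matrix)
#'
#' For every dataset and substitution matrix, the maximum MEAN_SPS over the
#' GOP x GEP grid and the (GOP, GEP) achieving it. Ties prefer the smallest
#' GOP, then the smallest GEP.
#'
#' @param means output of [mean_sps()].
#' @return data frame with columns `dataset_id`, `matrix`, `max_mean_sps`,
#'   `gop`, `gep`.
#' @export
max_mean_sps <- function(means) {
  stopifnot(is.data.frame(means), nrow(means) >= 1L)
  means <- means[!is.na(means$mean_sps), , drop = FALSE]
  if (nrow(means) == 0L) stop("no successful combinations to maximize over", call. = FALSE)
  key <- interaction(means$dataset_id, means$matrix, drop = TRUE)
  idx <- split(seq_len(nrow(means)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    sub <- means[ii, , drop = FALSE]
    sub <- sub[order(-sub$mean_sps, sub$gop, sub$gep), , drop = FALSE]
    data.frame(dataset_id = sub$dataset_id[1L], matrix = sub$matrix[1L],
               max_mean_sps = sub$mean_sps[1L],
               gop = sub$gop[1L], gep = sub$gep[1L],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$dataset_id, out$matrix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal (matrix, GOP, GEP) per dataset
#'
#' The matrix whose MAX_MEAN_SPS is largest is the optimal matrix for the
#' dataset; its argmax (GOP, GEP) are the optimal gap penalties. Ties are
#' broken by `matrix_order` (default: the packaged listing order BLOSUM30,
#' BLOSUM45, BLOSUM62, BLOSUM80, PAM100, PAM200).
#'
#' @param rows output of [max_mean_sps()].
#' @param matrix_order character vector fixing the tie-break order.
#' @return data frame with columns `dataset_id`, `matrix`, `gop`, `gep`,
#'   `best_max_mean_sps`, one row per dataset.
#' @export
select_optimal <- function(rows, matrix_order = matrix_names()) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  rank <- stats::setNames(seq_along(matrix_order), toupper(matrix_order))
  mrank <- rank[toupper(rows$matrix)]
  mrank[is.na(mrank)] <- length(matrix_order) + 1L
  idx <- split(seq_len(nrow(rows)), rows$dataset_id)
  out <- do.call(rbind, lapply(idx, function(ii) {
    sub <- rows[ii, , drop = FALSE]
    sub <- sub[order(-sub$max_mean_sps, mrank[ii]), , drop = FALSE]
    data.frame(dataset_id = sub$dataset_id[1L], matrix = sub$matrix[1L],
               gop = sub$gop[1L], gep = sub$gep[1L],
               best_max_mean_sps = sub$max_mean_sps[1L],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$dataset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare named parameter sets over a benchmark
#'
#' Reports the per-dataset mean SPS of each named (matrix, GOP, GEP) set —
#' e.g. an aligner's defaults versus the optimum selected by
#' [select_optimal()] — in either of two modes: `"rerun"` aligns every case
#' afresh with each set, `"quote"` looks the values up in an existing sweep
#' table (the sets must lie on its grid).
#'
#' @param cases list of [case_bundle()] objects (rerun mode).
#' @param named_sets named list; each element a list/one-row data frame with
#'   `matrix`, `gop`, `gep`.
#' @param spec an `"aligner_spec"` (rerun mode).
#' @param mode `"rerun"` or `"quote"`.
#' @param sweep_table sweep table (quote mode).
#' @param use_core_mask,workdir as in [run_sweep()].
#' @return data frame: one row per (set, dataset) with `set`, `dataset_id`,
#'   `mean_sps`, `n_cases`, `n_failed`, `mode`.
#' @export
compare_parameter_sets <- function(cases = NULL, named_sets, spec = builtin_aligner(),
                                   mode = c("rerun", "quote"), sweep_table = NULL,
                                   use_core_mask = TRUE, workdir = tempdir()) {
  mode <- match.arg(mode)
  stopifnot(length(named_sets) >= 1L, !is.null(names(named_sets)))
  per_set <- lapply(names(named_sets), function(nm) {
    ps <- named_sets[[nm]]
    if (mode == "quote") {
      if (is.null(sweep_table)) stop("quote mode needs a sweep_table", call. = FALSE)
      hit <- sweep_table[toupper(sweep_table$matrix) == toupper(as.character(ps$matrix)) &
                           sweep_table$gop == ps$gop & sweep_table$gep == ps$gep, ,
                         drop = FALSE]
      if (nrow(hit) == 0L) {
        stop(sprintf("set '%s' (%s, %s, %s) is not on the sweep grid",
                     nm, ps$matrix, ps$gop, ps$gep), call. = FALSE)
      }
      tab <- hit
    } else {
      if (is.null(cases)) stop("rerun mode needs cases", call. = FALSE)
      grid <- data.frame(matrix = toupper(as.character(ps$matrix)),
                         gop = ps$gop, gep = ps$gep, stringsAsFactors = FALSE)
      tab <- run_sweep(cases, grid, spec, use_core_mask = use_core_mask,
                       workdir = workdir)
    }
    m <- mean_sps(tab)
    data.frame(set = nm, dataset_id = m$dataset_id, mean_sps = m$mean_sps,
               n_cases = m$n_cases, n_failed = m$n_failed, mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_set)
  rownames(out) <- NULL
  out
}
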