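#' Read and write lab-record tables
#'
#' Lab records travel as tab-separated text with a header row and columns
#' `patient_id`, `biomarker`, `value`, `visit_date`.
#'
#' @param path File path.
#' @return `read_lab_records()` returns a tibble of records.
#' @export
read_lab_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("records file not found: %s", path))
  rec <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           biomarker = readr::col_character(),
                           value = readr::col_double(),
                           .default = readr::col_guess()))
  required <- c("patient_id", "biomarker", "value")
  if (!all(required %in% names(rec)))
    abort(sprintf("records file %s lacks columns: %s", path,
                  paste(setdiff(required, names(rec)), collapse = ", ")))
  rec
}

#' @rdname read_lab_records
#' @param records Tibble of lab records.
#' @export
write_lab_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read and write clinarray matrices
#'
#' Clinarrays are stored as tab-separated text: a `biomarker` label column
#' followed by one column per patient, with missing cells written as the
#' literal token `NA`.
#'
#' @param path File path.
#' @return `read_clinarray()` returns a [new_clinarray()] object.
#' @export
read_clinarray <- function(path) {
  if (!file.exists(path)) abort(sprintf("clinarray file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           biomarker = readr::col_character(),
                           .default = readr::col_double()))
  if (!"biomarker" %in% names(tab))
    abort(sprintf("clinarray file %s lacks the biomarker column.", path))
  v <- as.matrix(tab[setdiff(names(tab), "biomarker")])
  rownames(v) <- tab$biomarker
  new_clinarray(v)
}

#' @rdname read_clinarray
#' @param x A clinarray.
#' @export
write_clinarray <- function(x, path) {
  stopifnot(inherits(x, "clinarray"))
  v <- unclass(x)
  tab <- tibble::as_tibble(v, rownames = NA)
  tab <- tibble::add_column(tab, biomarker = rownames(v), .before = 1)
  readr::write_tsv(tab, path, na = "NA")
  invisible(path)
}

#' Write the consensus report to disk
#'
#' Writes the per-biomarker consensus table as TSV alongside a small
#' human-readable summary, and (when an ensemble is supplied) a per-run
#' convergence log with the seed of every run.
#'
#' @param consensus A `clinarica_consensus`.
#' @param dir Output directory (created if needed).
#' @param ensemble Optional `clinarica_ensemble` for the run log.
#' @return Invisibly, the paths written.
#' @export
write_consensus_report <- function(consensus, dir, ensemble = NULL) {
  stopifnot(inherits(consensus, "clinarica_consensus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "consensus_report.tsv"),
             summary = file.path(dir, "consensus_summary.txt"))
  readr::write_tsv(tidy(consensus), paths["table"])
  writeLines(unclass(summary(consensus)), paths["summary"])
  if (!is.null(ensemble)) {
    paths["runs"] <- file.path(dir, "ensemble_runs.tsv")
    runs <- tibble::tibble(run = seq_len(ensemble$n_runs),
                           seed = ensemble$run_seeds,
                           converged = ensemble$converged)
    if (!is.null(ensemble$n_iter)) runs$n_iter <- ensemble$n_iter
    readr::write_tsv(runs, paths["runs"])
  }
  invisible(paths)
}
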