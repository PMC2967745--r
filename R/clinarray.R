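#' Clinarray matrices
#'
#' A clinarray matrix holds per-patient median biomarker values: rows are
#' biomarkers, columns are patients, `NA` marks patient-biomarker pairs with
#' no measurement. `new_clinarray()` wraps a labelled numeric matrix after
#' validating labels and finiteness.
#'
#' @param values Numeric matrix with unique rownames (biomarkers) and unique
#'   colnames (patients); non-missing entries must be finite.
#' @return A `clinarray` object (a classed matrix).
#' @export
new_clinarray <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("a clinarray must be a numeric matrix.")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("a clinarray needs biomarker rownames and patient colnames.")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    abort("biomarker and patient labels must be unique.")
  if (any(is.infinite(values) | is.nan(values)))
    abort("non-missing clinarray entries must be finite.")
  structure(values, class = c("clinarray", "matrix", "array"))
}

#' Build a clinarray from longitudinal lab records
#'
#' Aggregates long-format laboratory records into a biomarkers x patients
#' matrix: cell (b, p) is the median of all recorded values of biomarker b
#' for patient p across visits (even counts take the midpoint of the two
#' central values); pairs with no record are `NA`. Row order is the first-
#' appearance order of biomarkers in `records`, column order the first-
#' appearance order of patients, so deterministic input gives deterministic
#' output. The aggregation ignores `visit_date`: a clinarray summarizes a
#' patient's biomarker state across all visits, not its time course.
#'
#' @param records Data frame with columns `patient_id`, `biomarker`, `value`
#'   (finite numeric) and optionally `visit_date`. Repeated
#'   (patient, biomarker, visit) triples are allowed.
#' @return A [new_clinarray()] matrix.
#' @examples
#' rec <- tibble::tibble(patient_id = "P1", biomarker = "sodium",
#'                       value = c(1, 2, 100), visit_date = 1:3)
#' build_clinarray(rec)
#' @export
build_clinarray <- function(records) {
  required <- c("patient_id", "biomarker", "value")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    abort("records must be a data frame with columns patient_id, biomarker, value.")
  if (nrow(records) == 0L)
    abort("records is empty: cannot build a clinarray from no measurements.")
  bad <- which(!is.finite(records$value))
  if (length(bad)) {
    b1 <- bad[1]
    abort(sprintf(
      "non-finite value in record %d (patient %s, biomarker %s).",
      b1, records$patient_id[b1], records$biomarker[b1]))
  }

  bio_lev <- unique(as.character(records$biomarker))
  pat_lev <- unique(as.character(records$patient_id))
  med <- records |>
    dplyr::group_by(.data$biomarker, .data$patient_id) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  values <- matrix(NA_real_, length(bio_lev), length(pat_lev),
                   dimnames = list(bio_lev, pat_lev))
  values[cbind(match(as.character(med$biomarker), bio_lev),
               match(as.character(med$patient_id), pat_lev))] <- med$value
  new_clinarray(values)
}

#' Prune sparsely measured patients and biomarkers
#'
#' Applies two filter passes, each exactly once and in this order:
#' first every patient with fewer than `min_biomarkers_per_patient` distinct
#' observed biomarkers is dropped (strict `<`, so exactly 9 observed
#' biomarkers at the default threshold 10 means exclusion); then, among the
#' remaining patients, every biomarker observed in fewer than
#' `min_patient_fraction` of them is dropped (inclusive `>=` at the
#' boundary: a biomarker observed in exactly half the remaining patients
#' survives). The passes are not iterated: the second pass can push a
#' surviving patient's observed count back below the patient threshold, and
#' such patients are reported, not silently re-filtered. Surviving cell
#' values are never altered.
#'
#' @param x A [new_clinarray()] matrix.
#' @param min_biomarkers_per_patient Minimum distinct observed biomarkers a
#'   patient needs to be kept (default 10).
#' @param min_patient_fraction Minimum fraction of remaining patients in
#'   which a biomarker must be observed (default 0.5).
#' @return The pruned clinarray, with attributes `prune_report` (a tibble of
#'   dimensions before/after each pass; see [prune_report()]) and
#'   `sub_threshold_patients` (ids of surviving patients whose observed
#'   count fell below the patient threshold after the biomarker pass).
#' @export
prune_clinarray <- function(x, min_biomarkers_per_patient = 10,
                            min_patient_fraction = 0.5) {
  stopifnot(inherits(x, "clinarray"))
  v <- unclass(x)
  keep_p <- colSums(!is.na(v)) >= min_biomarkers_per_patient
  v1 <- v[, keep_p, drop = FALSE]
  if (ncol(v1) == 0L)
    abort("empty after pruning: every patient fell below the biomarker-count threshold.")
  keep_b <- rowSums(!is.na(v1)) >= min_patient_fraction * ncol(v1)
  v2 <- v1[keep_b, , drop = FALSE]
  if (nrow(v2) == 0L)
    abort("empty after pruning: every biomarker fell below the patient-coverage threshold.")

  report <- tibble::tibble(
    stage = c("input", "after_patient_filter", "after_biomarker_filter"),
    n_biomarkers = c(nrow(v), nrow(v1), nrow(v2)),
    n_patients = c(ncol(v), ncol(v1), ncol(v2))
  )
  sub <- colnames(v2)[colSums(!is.na(v2)) < min_biomarkers_per_patient]
  out <- new_clinarray(v2)
  attr(out, "prune_report") <- report
  attr(out, "sub_threshold_patients") <- sub
  out
}

#' Retrieve the pruning report of a pruned clinarray
#'
#' @param x A clinarray returned by [prune_clinarray()].
#' @return Tibble with one row per pruning stage and the surviving
#'   biomarker/patient counts (the shape in which pruned cohort sizes are
#'   conventionally reported).
#' @export
prune_report <- function(x) {
  rep <- attr(x, "prune_report")
  if (is.null(rep)) abort("x carries no prune_report; was it pruned?")
  rep
}

#' @export
print.clinarray <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<clinarray> %d biomarkers x %d patients, %.1f%% missing\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  utils::str(v, give.attr = FALSE)
  invisible(x)
}

#' Tidy a clinarray into long format
#'
#' @param x A clinarray.
#' @param drop_na Drop unobserved cells? Default `TRUE`.
#' @param ... Unused.
#' @return Tibble with columns `biomarker`, `patient_id`, `value`.
#' @exportS3Method generics::tidy
tidy.clinarray <- function(x, drop_na = TRUE, ...) {
  v <- unclass(x)
  out <- tibble::tibble(
    biomarker = rep(rownames(v), times = ncol(v)),
    patient_id = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' @rdname tidy.clinarray
#' @exportS3Method tibble::as_tibble
as_tibble.clinarray <- function(x, ..., drop_na = TRUE) tidy.clinarray(x, drop_na = drop_na)
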