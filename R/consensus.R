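#' Significant biomarkers by the top-fraction rule
#'
#' The first consensus rule: pool every absolute loading score (biomarker x
#' component x converged run) into one empirical distribution, set the
#' threshold at its upper `fraction` quantile (linear-interpolation
#' convention, `type = 7`), and return the biomarkers whose mean absolute
#' loading across components and converged runs reaches the threshold
#' (inclusive `>=`, so an all-tied ensemble returns every biomarker). The
#' sentence "mean loading in the top fraction of the distribution" admits a
#' second reading in which the threshold is taken from the distribution of
#' the per-biomarker means themselves; that reading is available as
#' `basis = "means"` and selects the top `fraction` share of biomarkers.
#' The pooled reading is the default.
#'
#' @param ensemble A `clinarica_ensemble`.
#' @param fraction Upper tail fraction in (0, 1); default 0.01 (top 1%).
#' @param basis `"pooled"` (threshold from the pooled score distribution,
#'   default) or `"means"` (threshold from the distribution of per-biomarker
#'   means).
#' @return List with `biomarkers` (selected, sorted by descending mean),
#'   `threshold`, and `means` (named vector over all biomarkers).
#' @export
significant_by_top_fraction <- function(ensemble, fraction = 0.01,
                                        basis = c("pooled", "means")) {
  basis <- match.arg(basis)
  stopifnot(inherits(ensemble, "clinarica_ensemble"))
  if (fraction <= 0 || fraction >= 1) abort("fraction must lie in (0, 1).")
  Ls <- ensemble$abs_loadings[ensemble$converged]
  if (length(Ls) == 0L) abort("ensemble has no converged runs.")
  means <- rowMeans(vapply(Ls, rowMeans, numeric(length(ensemble$biomarker_ids))))
  names(means) <- ensemble$biomarker_ids
  pool <- switch(basis,
                 pooled = unlist(Ls, use.names = FALSE),
                 means = unname(means))
  threshold <- unname(stats::quantile(pool, 1 - fraction, type = 7))
  sel <- means[means >= threshold]
  list(biomarkers = names(sort(sel, decreasing = TRUE)),
       threshold = threshold, means = means)
}

#' Significant biomarkers by argmax consistency
#'
#' The second consensus rule: in every converged run, record which biomarker
#' carries the highest absolute loading of each component; a biomarker is
#' significant only if it loads highest on at least one component in every
#' converged run (strict universality: winning all but one run is not
#' enough). Exact ties within a component column are broken by biomarker row
#' order and reported via a message. Selected biomarkers are ordered by
#' their total number of argmax events across runs and components.
#'
#' @param ensemble A `clinarica_ensemble`.
#' @return List with `biomarkers` (selected), `counts` (named: number of
#'   runs in which each biomarker is an argmax of >= 1 component), and
#'   `events` (named: total run x component argmax events).
#' @export
significant_by_argmax_consistency <- function(ensemble) {
  stopifnot(inherits(ensemble, "clinarica_ensemble"))
  Ls <- ensemble$abs_loadings[ensemble$converged]
  if (length(Ls) == 0L) abort("ensemble has no converged runs.")
  ids <- ensemble$biomarker_ids
  n_ties <- 0L
  per_run <- lapply(Ls, function(L) {
    am <- integer(ncol(L))
    for (cc in seq_len(ncol(L))) {
      mx <- max(L[, cc])
      w <- which(L[, cc] == mx)
      if (length(w) > 1L) n_ties <<- n_ties + 1L
      am[cc] <- w[1]
    }
    am
  })
  if (n_ties > 0L)
    message(sprintf("%d exact argmax ties broken by biomarker order.", n_ties))
  events <- tabulate(unlist(per_run), nbins = length(ids))
  counts <- tabulate(unlist(lapply(per_run, unique)), nbins = length(ids))
  names(events) <- names(counts) <- ids
  sel <- ids[counts == length(Ls)]
  sel <- sel[order(-events[sel], match(sel, ids))]
  list(biomarkers = sel, counts = counts, events = events)
}

#' Extract consensus-significant biomarkers from an ICA ensemble
#'
#' Applies both consensus rules ([significant_by_top_fraction()] and
#' [significant_by_argmax_consistency()]) to the same ensemble and records
#' whether they agree (set equality of the two biomarker lists) — the
#' reproducibility property the ensemble protocol is designed around.
#'
#' @param ensemble A `clinarica_ensemble`.
#' @param fraction,threshold_basis Passed to
#'   [significant_by_top_fraction()].
#' @return A `clinarica_consensus` object; see [tidy.clinarica_consensus()]
#'   and [glance.clinarica_consensus()] for tabular views, and
#'   [summary.clinarica_consensus()] for the rendered report.
#' @export
consensus_biomarkers <- function(ensemble, fraction = 0.01,
                                 threshold_basis = c("pooled", "means")) {
  threshold_basis <- match.arg(threshold_basis)
  top <- significant_by_top_fraction(ensemble, fraction, threshold_basis)
  am <- significant_by_argmax_consistency(ensemble)
  structure(
    list(significant_topfrac = top$biomarkers,
         significant_argmax = am$biomarkers,
         mean_abs_loading = top$means,
         threshold_value = top$threshold,
         argmax_counts = am$counts,
         argmax_events = am$events,
         methods_agree = setequal(top$biomarkers, am$biomarkers),
         fraction = fraction, threshold_basis = threshold_basis,
         n_runs_used = sum(ensemble$converged),
         n_runs = ensemble$n_runs,
         n_components = ensemble$n_components,
         biomarker_ids = ensemble$biomarker_ids),
    class = "clinarica_consensus"
  )
}

#' Per-biomarker consensus statistics
#'
#' @param x A `clinarica_consensus`.
#' @param ... Unused.
#' @return Tibble with one row per biomarker: `mean_abs_loading`,
#'   `argmax_count` (runs won), `argmax_events` (run x component wins), and
#'   logical significance flags for both rules, sorted by descending mean
#'   loading.
#' @exportS3Method generics::tidy
tidy.clinarica_consensus <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarker_ids,
    mean_abs_loading = unname(x$mean_abs_loading[x$biomarker_ids]),
    argmax_count = unname(x$argmax_counts[x$biomarker_ids]),
    argmax_events = unname(x$argmax_events[x$biomarker_ids]),
    significant_topfrac = x$biomarker_ids %in% x$significant_topfrac,
    significant_argmax = x$biomarker_ids %in% x$significant_argmax
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_loading))
}

#' @rdname tidy.clinarica_consensus
#' @exportS3Method generics::glance
glance.clinarica_consensus <- function(x, ...) {
  tibble::tibble(
    n_biomarkers = length(x$biomarker_ids),
    n_significant_topfrac = length(x$significant_topfrac),
    n_significant_argmax = length(x$significant_argmax),
    methods_agree = x$methods_agree,
    threshold_value = x$threshold_value,
    fraction = x$fraction,
    threshold_basis = x$threshold_basis,
    n_runs_used = x$n_runs_used,
    n_components = x$n_components
  )
}

#' Render the consensus report
#'
#' @param object A `clinarica_consensus`.
#' @param ... Unused.
#' @return A character vector of report lines (class
#'   `clinarica_consensus_summary`), printed as text. Lists both significant
#'   sets (with explicit "none significant" lines when empty), the threshold
#'   and convergence summary, and — when the two rules disagree — their
#'   symmetric difference.
#' @export
summary.clinarica_consensus <- function(object, ...) {
  x <- object
  fmt_set <- function(s) if (length(s)) paste(s, collapse = ", ") else "(none significant)"
  lines <- c(
    "Consensus significant biomarkers",
    sprintf("  runs used: %d of %d converged; %d components",
            x$n_runs_used, x$n_runs, x$n_components),
    sprintf("  top-fraction rule (fraction %.4g, basis %s, threshold %.6g):",
            x$fraction, x$threshold_basis, x$threshold_value),
    paste0("    ", fmt_set(x$significant_topfrac)),
    "  argmax-consistency rule:",
    paste0("    ", fmt_set(x$significant_argmax)),
    sprintf("  methods agree: %s", if (x$methods_agree) "yes" else "NO")
  )
  if (!x$methods_agree) {
    sdiff <- union(setdiff(x$significant_topfrac, x$significant_argmax),
                   setdiff(x$significant_argmax, x$significant_topfrac))
    lines <- c(lines, paste0("  symmetric difference: ", fmt_set(sdiff)))
  }
  structure(lines, class = "clinarica_consensus_summary")
}

#' @export
print.clinarica_consensus_summary <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.clinarica_consensus <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
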