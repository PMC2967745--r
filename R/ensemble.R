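#' Construct a loading ensemble
#'
#' Low-level constructor for the container the consensus stage consumes:
#' the absolute biomarker-loading matrices collected across FastICA runs.
#' [ica_ensemble()] builds one by actually running the decompositions; this
#' constructor is exported so ensembles can also be assembled directly
#' (e.g. for permutation checks).
#'
#' @param abs_loadings List of `m x k` nonnegative matrices, one per run,
#'   identical biomarker ordering and component count throughout.
#' @param biomarker_ids Character vector of the m biomarker labels.
#' @param run_seeds Integer vector of per-run seeds (pairwise distinct).
#' @param converged Logical vector flagging converged runs.
#' @return A `clinarica_ensemble` object.
#' @export
loading_ensemble <- function(abs_loadings, biomarker_ids,
                             run_seeds = seq_along(abs_loadings),
                             converged = rep(TRUE, length(abs_loadings))) {
  R <- length(abs_loadings)
  if (R == 0L) abort("an ensemble needs at least one run.")
  dims <- vapply(abs_loadings, dim, integer(2))
  if (any(dims[1, ] != length(biomarker_ids)) || any(dims[2, ] != dims[2, 1]))
    abort("every run must have the same biomarker count and component count.")
  if (any(vapply(abs_loadings, function(a) any(a < 0), logical(1))))
    abort("absolute loadings must be nonnegative.")
  if (length(run_seeds) != R || anyDuplicated(run_seeds))
    abort("run_seeds must be one distinct seed per run.")
  if (length(converged) != R)
    abort("converged must flag every run.")
  abs_loadings <- lapply(abs_loadings, function(a) {
    rownames(a) <- biomarker_ids
    a
  })
  structure(
    list(abs_loadings = abs_loadings, biomarker_ids = biomarker_ids,
         n_runs = R, run_seeds = as.integer(run_seeds),
         converged = as.logical(converged),
         n_components = dims[2, 1]),
    class = "clinarica_ensemble"
  )
}

#' Run a FastICA ensemble over random initializations
#'
#' FastICA's fixed-point iteration starts from a random rotation and can
#' settle in different local optima, so successive runs produce slightly
#' different results and components come out in no particular order. The
#' ensemble re-runs the decomposition `n_runs` times (the reference protocol
#' uses 500) on the same standardized matrix, varying only the
#' initialization seed, and collects the absolute loading matrices
#' `|mixing_est|` for consensus scoring. The component count is estimated
#' once, before the ensemble, and held fixed so components remain comparable
#' across runs. Per-run seeds are drawn without replacement from the master
#' seed, so any single run is reproducible in isolation. Non-converged runs
#' are flagged and excluded from all consensus statistics; more than 50%
#' non-convergence aborts with an ensemble-quality error.
#'
#' @param X A standardized complete clinarray (or matrix).
#' @param n_runs Number of FastICA runs (default 500).
#' @param n_components `"auto"` (scree elbow, estimated once) or a count.
#' @param contrast,tol,max_iter Passed to [fastica_rotation()].
#' @param master_seed Integer seed from which all per-run seeds derive.
#' @return A `clinarica_ensemble` (see [loading_ensemble()]) with extra
#'   fields `n_iter` (per run) and `eigenvalues`.
#' @export
ica_ensemble <- function(X, n_runs = 500, n_components = "auto",
                         contrast = c("logcosh", "cube"),
                         tol = 1e-6, max_iter = 500, master_seed = 1L) {
  contrast <- match.arg(contrast)
  if (n_runs < 1) abort("n_runs must be >= 1.")
  V <- .check_standardized(X)
  wh <- .whiten_auto(V, n_components)
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max - 1L, n_runs))
  runs <- lapply(seeds, function(s)
    .ica_single(V, wh, contrast = contrast, tol = tol,
                max_iter = max_iter, seed = s))
  converged <- vapply(runs, `[[`, logical(1), "converged")
  if (mean(converged) < 0.5)
    abort(sprintf(
      "ensemble quality: only %d of %d runs converged (>50%% required).",
      sum(converged), n_runs))
  if (any(!converged))
    message(sprintf("%d of %d runs did not converge and are excluded from consensus statistics.",
                    sum(!converged), n_runs))
  ens <- loading_ensemble(
    abs_loadings = lapply(runs, function(r) abs(r$mixing_est)),
    biomarker_ids = rownames(V),
    run_seeds = seeds,
    converged = converged
  )
  ens$n_iter <- vapply(runs, `[[`, integer(1), "n_iter")
  ens$eigenvalues <- wh$eigenvalues_all
  ens
}

#' @export
print.clinarica_ensemble <- function(x, ...) {
  cat(sprintf("<clinarica_ensemble> %d runs (%d converged), %d biomarkers, %d components\n",
              x$n_runs, sum(x$converged), length(x$biomarker_ids), x$n_components))
  invisible(x)
}

#' Tidy an ensemble into a long loading table
#'
#' @param x A `clinarica_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `run`, `run_seed`, `converged`, `component`,
#'   `biomarker`, `abs_loading`.
#' @exportS3Method generics::tidy
tidy.clinarica_ensemble <- function(x, ...) {
  m <- length(x$biomarker_ids); k <- x$n_components
  tibble::tibble(
    run = rep(seq_len(x$n_runs), each = m * k),
    run_seed = rep(x$run_seeds, each = m * k),
    converged = rep(x$converged, each = m * k),
    component = rep(rep(paste0("IC", seq_len(k)), each = m), times = x$n_runs),
    biomarker = rep(rep(x$biomarker_ids, times = k), times = x$n_runs),
    abs_loading = unlist(lapply(x$abs_loadings, as.vector), use.names = FALSE)
  )
}

#' @rdname tidy.clinarica_ensemble
#' @exportS3Method generics::glance
glance.clinarica_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    n_converged = sum(x$converged),
    convergence_rate = mean(x$converged),
    n_biomarkers = length(x$biomarker_ids),
    n_components = x$n_components
  )
}
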