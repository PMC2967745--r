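#' Whiten a row-standardized matrix
#'
#' Projects onto the top-`k` eigenpairs of the sample covariance (population
#' convention, `X %*% t(X) / n`) and rescales so the projected variables are
#' uncorrelated with unit variance: `Z = whitening_map %*% X` with
#' `cov(Z) = I`. Whitening is the standard FastICA preprocessing step: it
#' reduces the unmixing problem to finding an orthonormal rotation.
#'
#' @param X Numeric matrix with centered rows (biomarkers x patients).
#' @param k Number of components to retain; must not exceed the numerical
#'   rank (eigenvalues below `1e-12` of the largest count as null).
#' @return List with `Z` (k x n), `whitening_map` (k x m), `eigenvalues`
#'   (the k retained), and `eigenvalues_all` (full spectrum, for scree
#'   inspection).
#' @export
whiten_rows <- function(X, k) {
  X <- as.matrix(X)
  n <- ncol(X)
  C <- tcrossprod(X) / n
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (k < 1 || k > nrow(X))
    abort("k must lie in [1, nrow(X)].")
  if (vals[k] <= 1e-12 * vals[1])
    abort(sprintf("rank error: eigenvalue %d is numerically zero; X has rank < %d.", k, k))
  map <- diag(1 / sqrt(vals[seq_len(k)]), k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
  list(Z = map %*% X, whitening_map = map,
       eigenvalues = vals[seq_len(k)], eigenvalues_all = vals)
}

#' Estimate the number of components by the scree elbow
#'
#' Locates the elbow of the descending eigenvalue curve as the point of
#' maximum acceleration (second difference) of the decline and retains the
#' components before it: with eigenvalues `lambda[1] >= lambda[2] >= ...`,
#' the retained count is `argmax_j (lambda[j-1] - 2*lambda[j] +
#' lambda[j+1]) - 1` over interior points `j`, ties resolved toward the
#' smallest count. A perfectly linear decline has no elbow and yields 1.
#'
#' @param eigenvalues Nonnegative eigenvalues in descending order, length
#'   >= 3 (shorter spectra fall back to all components, with a warning).
#' @return Integer count of retained components.
#' @examples
#' n_components_scree(c(10, 9.5, 9, 1, 0.9, 0.8))  # 3
#' n_components_scree(c(5, 4, 3, 2, 1))            # 1 (no elbow)
#' @export
n_components_scree <- function(eigenvalues) {
  lam <- as.numeric(eigenvalues)
  if (any(lam < 0) || is.unsorted(rev(lam)))
    abort("eigenvalues must be nonnegative and in descending order.")
  L <- length(lam)
  if (L < 3L) {
    warn("fewer than 3 eigenvalues: scree elbow undefined, retaining all components.")
    return(L)
  }
  d2 <- lam[1:(L - 2)] - 2 * lam[2:(L - 1)] + lam[3:L]
  j <- which.max(d2) + 1L   # interior index of maximum acceleration
  max(j - 1L, 1L)
}

#' Symmetric fixed-point FastICA on whitened data
#'
#' Runs the parallel (symmetric) FastICA fixed-point iteration on an already
#' whitened matrix: starting from a random orthonormal `k x k` rotation, each
#' row is updated by `w <- E[z g(w'z)] - E[g'(w'z)] w` with the negentropy
#' contrast nonlinearity `g` (`tanh` for `logcosh`, `u^3` for `cube`),
#' followed by symmetric decorrelation `W <- (W W')^{-1/2} W`. Iteration
#' stops when every row's direction change satisfies
#' `|1 - |<w_new, w_old>|| < tol` (sign-invariant, matching ICA's sign
#' indeterminacy) or after `max_iter` sweeps; non-convergence is flagged,
#' not fatal. Symmetric (rather than deflation) estimation treats all
#' components on an equal footing, which the ensemble consensus stage
#' relies on.
#'
#' @param Z Whitened `k x n` matrix (covariance within `1e-4` of identity,
#'   checked).
#' @param contrast `"logcosh"` (default) or `"cube"`.
#' @param tol Convergence tolerance (default `1e-6`).
#' @param max_iter Maximum sweeps (default 500).
#' @param seed Integer seed for the random orthonormal initialization
#'   (ignored when `w_init` is given).
#' @param w_init Optional explicit `k x k` initialization.
#' @return List with `W` (orthonormal `k x k` rotation), `converged`, and
#'   `n_iter`.
#' @export
fastica_rotation <- function(Z, contrast = c("logcosh", "cube"),
                             tol = 1e-6, max_iter = 500, seed = 1L,
                             w_init = NULL) {
  contrast <- match.arg(contrast)
  if (tol <= 0) abort("tol must be positive.")
  Z <- as.matrix(Z)
  k <- nrow(Z); n <- ncol(Z)
  Cz <- tcrossprod(Z) / n
  if (max(abs(Cz - diag(k))) > 1e-4)
    abort("Z is not whitened: its covariance deviates from the identity by more than 1e-4.")

  W <- if (!is.null(w_init)) {
    as.matrix(w_init)
  } else {
    withr::with_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
  }
  W <- .sym_decorrelate(W)

  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WZ <- W %*% Z
    if (contrast == "logcosh") {
      G <- tanh(WZ)
      W1 <- G %*% t(Z) / n - diag(rowMeans(1 - G^2), k) %*% W
    } else {
      W1 <- (WZ^3) %*% t(Z) / n - diag(3 * rowMeans(WZ^2), k) %*% W
    }
    W1 <- .sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, n_iter = it)
}

# (W W')^{-1/2} W via SVD; returns an orthonormal matrix
.sym_decorrelate <- function(W) {
  sv <- svd(W)
  sv$u %*% t(sv$v)
}

#' Decompose a standardized clinarray with FastICA
#'
#' Composes the full single-run decomposition: eigendecomposition of the
#' sample covariance, component-count selection (scree elbow when
#' `n_components = "auto"`), whitening, and the symmetric FastICA rotation.
#' In the model `X = A S`, the returned `unmixing` is `W` in original
#' biomarker space (`sources_est = unmixing %*% X`, rows rescaled to unit
#' population variance) and `mixing_est` is its Moore-Penrose pseudoinverse,
#' the estimate of `A`: column c of `mixing_est` is the biomarker loading
#' vector of component c, the quantity the consensus stage scores.
#'
#' @param X A standardized complete clinarray (see
#'   [standardize_biomarkers()]) or an equivalent matrix.
#' @param n_components `"auto"` (scree elbow) or an explicit count.
#' @param contrast,tol,max_iter,seed Passed to [fastica_rotation()].
#' @return A `clinarica_ica` object: `unmixing` (k x m), `mixing_est`
#'   (m x k), `sources_est` (k x n), `eigenvalues` (full spectrum),
#'   `n_components`, `contrast`, `seed`, `converged`, `n_iter`.
#' @export
ica_decompose <- function(X, n_components = "auto",
                          contrast = c("logcosh", "cube"),
                          tol = 1e-6, max_iter = 500, seed = 1L) {
  contrast <- match.arg(contrast)
  V <- .check_standardized(X)
  n <- ncol(V)
  wh <- .whiten_auto(V, n_components)
  run <- .ica_single(V, wh, contrast = contrast, tol = tol,
                     max_iter = max_iter, seed = seed)
  structure(
    list(unmixing = run$unmixing, mixing_est = run$mixing_est,
         sources_est = run$sources_est, eigenvalues = wh$eigenvalues_all,
         n_components = nrow(wh$Z), contrast = contrast, seed = seed,
         converged = run$converged, n_iter = run$n_iter,
         biomarker_ids = rownames(V), patient_ids = colnames(V)),
    class = "clinarica_ica"
  )
}

# shared precondition: complete, rows centered and unit-variance
.check_standardized <- function(X) {
  V <- if (inherits(X, "clinarray")) unclass(X) else as.matrix(X)
  if (anyNA(V)) abort("X has missing cells; impute and standardize first.")
  if (max(abs(rowMeans(V))) > 1e-6 || max(abs(rowMeans(V^2) - 1)) > 1e-4)
    abort("X is not row-standardized (mean 0, unit population variance); see standardize_biomarkers().")
  V
}

.whiten_auto <- function(V, n_components) {
  n <- ncol(V)
  C <- tcrossprod(V) / n
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- if (identical(n_components, "auto")) {
    min(n_components_scree(vals), sum(vals > 1e-12 * vals[1]))
  } else {
    as.integer(n_components)
  }
  if (k > min(dim(V))) abort("n_components must not exceed min(dim(X)).")
  if (vals[k] <= 1e-12 * vals[1])
    abort(sprintf("rank error: X has numerical rank < %d.", k))
  map <- diag(1 / sqrt(vals[seq_len(k)]), k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
  list(Z = map %*% V, whitening_map = map, eigenvalues_all = vals)
}

# one FastICA run given a precomputed whitening; shared by ica_decompose()
# and ica_ensemble() so their outputs agree bit for bit
.ica_single <- function(V, wh, contrast, tol, max_iter, seed) {
  rot <- fastica_rotation(wh$Z, contrast = contrast, tol = tol,
                          max_iter = max_iter, seed = seed)
  unmixing <- rot$W %*% wh$whitening_map
  Y <- unmixing %*% V
  sdY <- sqrt(rowMeans(Y^2) - rowMeans(Y)^2)
  unmixing <- unmixing / sdY
  Y <- Y / sdY
  mixing_est <- MASS::ginv(unmixing)
  k <- nrow(Y)
  dimnames(mixing_est) <- list(rownames(V), paste0("IC", seq_len(k)))
  dimnames(unmixing) <- list(paste0("IC", seq_len(k)), rownames(V))
  dimnames(Y) <- list(paste0("IC", seq_len(k)), colnames(V))
  list(unmixing = unmixing, mixing_est = mixing_est, sources_est = Y,
       converged = rot$converged, n_iter = rot$n_iter)
}

#' @export
print.clinarica_ica <- function(x, ...) {
  cat(sprintf("<clinarica_ica> %d components, %d biomarkers x %d patients\n",
              x$n_components, length(x$biomarker_ids), length(x$patient_ids)))
  cat(sprintf("  contrast %s, seed %d, %s in %d iterations\n", x$contrast,
              x$seed, if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Tidy an ICA decomposition into a loading table
#'
#' @param x A `clinarica_ica` object.
#' @param ... Unused.
#' @return Tibble with columns `biomarker`, `component`, `loading` (entries
#'   of the estimated mixing matrix) and `abs_loading`.
#' @exportS3Method generics::tidy
tidy.clinarica_ica <- function(x, ...) {
  A <- x$mixing_est
  tibble::tibble(
    biomarker = rep(rownames(A), times = ncol(A)),
    component = rep(colnames(A), each = nrow(A)),
    loading = as.vector(A),
    abs_loading = abs(as.vector(A))
  )
}

#' @rdname tidy.clinarica_ica
#' @exportS3Method generics::glance
glance.clinarica_ica <- function(x, ...) {
  tibble::tibble(
    n_biomarkers = length(x$biomarker_ids),
    n_patients = length(x$patient_ids),
    n_components = x$n_components,
    contrast = x$contrast,
    converged = x$converged,
    n_iter = x$n_iter,
    seed = x$seed
  )
}
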