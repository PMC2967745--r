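#' Impute missing clinarray cells by weighted k-nearest neighbours
#'
#' Fills each missing cell (b, p) from the biomarker rows most similar to b,
#' following the KNNImpute conventions for expression-style matrices with
#' variables in rows: the distance between two biomarker rows is the
#' root-mean-square difference over their co-observed patients (normalizing
#' by the co-observed count so sparsity does not inflate distance); rows
#' sharing fewer than `min_shared` co-observed patients are ineligible as
#' neighbours. Among eligible rows observed at patient p, the `k` nearest
#' contribute their value at p with weight 1/distance; exact duplicates
#' (distance 0) take precedence with a plain mean. With fewer than `k`
#' candidates all are used; with none, the row mean of b is the fallback.
#' Observed entries are never touched, and the procedure is deterministic
#' (distance ties broken by row order).
#'
#' @param x A [new_clinarray()] matrix in which every row and column has at
#'   least one observed value.
#' @param k Number of neighbouring biomarker rows (default 10).
#' @param min_shared Minimum co-observed patients for a distance to be
#'   defined (default 3).
#' @return A complete clinarray (no `NA`).
#' @export
impute_knn <- function(x, k = 10, min_shared = 3) {
  stopifnot(inherits(x, "clinarray"))
  if (k < 1) abort("k must be >= 1.")
  v <- unclass(x)
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0L))
    abort(sprintf("biomarker %s has no observed value; cannot impute.",
                  rownames(v)[which(rowSums(obs) == 0L)[1]]))
  if (any(colSums(obs) == 0L))
    abort(sprintf("patient %s has no observed value; cannot impute.",
                  colnames(v)[which(colSums(obs) == 0L)[1]]))
  if (all(obs)) return(x)

  m <- nrow(v)
  out <- v
  row_means <- rowMeans(v, na.rm = TRUE)
  need <- which(rowSums(!obs) > 0L)
  for (b in need) {
    # distances from row b to every other row, over co-observed patients
    d <- rep(Inf, m)
    for (b2 in seq_len(m)[-b]) {
      sh <- obs[b, ] & obs[b2, ]
      ns <- sum(sh)
      if (ns >= min_shared)
        d[b2] <- sqrt(mean((v[b, sh] - v[b2, sh])^2))
    }
    for (p in which(!obs[b, ])) {
      cand <- which(obs[, p] & is.finite(d))
      if (length(cand) == 0L) {
        out[b, p] <- row_means[b]
        next
      }
      cand <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      dz <- d[cand] == 0
      out[b, p] <- if (any(dz)) {
        mean(v[cand[dz], p])
      } else {
        stats::weighted.mean(v[cand, p], w = 1 / d[cand])
      }
    }
  }
  new_clinarray(out)
}

#' Standardize biomarker rows to mean zero, unit variance
#'
#' Centers each biomarker row to mean 0 and scales it to unit variance,
#' using the population convention (denominator n) so that the whitening
#' step's covariance convention matches exactly. The per-row centers and
#' scales are kept as attributes for invertibility:
#' `x * scale + center` restores the input.
#'
#' @param x A complete clinarray with at least 2 patients.
#' @return The standardized clinarray with attributes `biomarker_center` and
#'   `biomarker_scale` (named numeric vectors).
#' @export
standardize_biomarkers <- function(x) {
  stopifnot(inherits(x, "clinarray"))
  v <- unclass(x)
  if (anyNA(v)) abort("clinarray has missing cells; impute before standardizing.")
  if (ncol(v) < 2L) abort("standardization needs at least 2 patients.")
  ctr <- rowMeans(v)
  centered <- v - ctr
  scl <- sqrt(rowMeans(centered^2))
  zero <- scl < 1e-12 * pmax(1, abs(ctr))
  if (any(zero))
    abort(sprintf("biomarker %s has zero variance and cannot be scaled to unit variance.",
                  rownames(v)[which(zero)[1]]))
  out <- new_clinarray(centered / scl)
  attr(out, "biomarker_center") <- stats::setNames(ctr, rownames(v))
  attr(out, "biomarker_scale") <- stats::setNames(scl, rownames(v))
  out
}
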