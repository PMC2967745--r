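#' Configure the synthetic lab-record generator
#'
#' Bundles and validates the parameters of the generative model behind
#' [sim_lab_records()]. The model draws `n_sources` mutually independent
#' standard-Laplace latent sources, mixes them into `n_biomarkers` observed
#' biomarker signals, adds per-biomarker observation noise, and emits
#' `visits_per_patient` jittered repeat measurements for every observed
#' patient-biomarker cell. A subset of biomarkers can be "planted" as
#' dominant markers of one latent source each, providing a known answer for
#' the downstream consensus stage.
#'
#' Defaults emulate a mid-sized disease cohort: 400 patients, a 30-biomarker
#' panel driven by 3 latent physiological factors, 3 visits per patient, and
#' 20% of patient-biomarker pairs never measured. Observation noise sd 2
#' (against unit-variance sources and background loadings bounded by 1)
#' makes background biomarkers noise-dominated (communality about 0.2) while
#' planted biomarkers stay strongly factor-driven (communality about 0.9),
#' the regime in which a handful of biomarkers dominate the latent factors.
#'
#' @param n_patients,n_biomarkers,n_sources Dimensions of the latent model;
#'   `n_sources` must not exceed `n_biomarkers`.
#' @param visits_per_patient Number of repeat measurements per observed cell.
#' @param visit_noise_sd Within-patient measurement jitter (sd, same units as
#'   the mixed signal).
#' @param observation_noise_sd Additive noise on the mixed signal (per cell).
#' @param missing_rate Probability in `[0, 1)` that a patient-biomarker pair
#'   is never measured.
#' @param n_planted Number of planted dominant biomarkers.
#' @param planted_gain Loading magnitude (>= 1) given to a planted biomarker
#'   on its designated component; its remaining loadings get magnitude
#'   `planted_gain / 2`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `clinarica_sim_config` list.
#' @examples
#' cfg <- sim_config(n_patients = 50, n_biomarkers = 12, n_sources = 2,
#'                   n_planted = 2, seed = 7)
#' sim <- sim_lab_records(cfg)
#' head(sim$records)
#' @export
sim_config <- function(n_patients = 400L,
                       n_biomarkers = 30L,
                       n_sources = 3L,
                       visits_per_patient = 3L,
                       visit_noise_sd = 0.5,
                       observation_noise_sd = 2,
                       missing_rate = 0.2,
                       n_planted = 3L,
                       planted_gain = 5,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_biomarkers = as.integer(n_biomarkers),
    n_sources = as.integer(n_sources),
    visits_per_patient = as.integer(visits_per_patient),
    visit_noise_sd = as.numeric(visit_noise_sd),
    observation_noise_sd = as.numeric(observation_noise_sd),
    missing_rate = as.numeric(missing_rate),
    n_planted = as.integer(n_planted),
    planted_gain = as.numeric(planted_gain),
    seed = as.integer(seed)
  )
  if (cfg$n_patients < 1L || cfg$n_biomarkers < 1L || cfg$n_sources < 1L)
    abort("n_patients, n_biomarkers and n_sources must be positive integers.")
  if (cfg$n_sources > cfg$n_biomarkers)
    abort("n_sources must not exceed n_biomarkers.")
  if (cfg$visits_per_patient < 1L)
    abort("visits_per_patient must be a positive integer.")
  if (cfg$visit_noise_sd < 0 || cfg$observation_noise_sd < 0)
    abort("noise standard deviations must be nonnegative.")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort("missing_rate must lie in [0, 1).")
  if (cfg$n_planted < 0L || cfg$n_planted > cfg$n_biomarkers)
    abort("n_planted must lie in [0, n_biomarkers].")
  if (cfg$planted_gain < 1)
    abort("planted_gain must be >= 1.")
  structure(cfg, class = "clinarica_sim_config")
}

#' Draw standardized independent Laplace sources
#'
#' Each of the `k` rows is an independent sample of `n` standard-Laplace
#' draws (a named super-Gaussian distribution, excess kurtosis 3), then
#' exactly standardized to mean 0 and population variance 1. Laplace sources
#' satisfy the non-Gaussianity FastICA's negentropy contrast requires.
#'
#' @param k Number of sources (rows), >= 1.
#' @param n Number of observations (columns), >= 2.
#' @param seed Integer seed.
#' @return A `k x n` matrix with rownames `IC1..ICk`.
#' @export
sim_sources <- function(k, n, seed = 1L) {
  if (k < 1L) abort("k must be a positive integer.")
  if (n < 2L) abort("n must be at least 2 (rows are standardized).")
  u <- withr::with_seed(seed, matrix(stats::runif(k * n) - 0.5, k, n))
  s <- -sign(u) * log1p(-2 * abs(u)) / sqrt(2)  # inverse-CDF standard Laplace
  s <- s - rowMeans(s)
  s <- s / sqrt(rowMeans(s^2))
  rownames(s) <- paste0("IC", seq_len(k))
  s
}

#' Draw a mixing matrix with optionally planted dominant biomarkers
#'
#' Background entries are Uniform(-1, 1): diffuse biomarkers weakly coupled
#' to every latent source, with bounded loadings. Each planted biomarker is
#' made a dominant, high-communality marker: its loading on a designated
#' component (planted biomarkers cycle through components in order) is set to
#' magnitude `gain`, and its remaining loadings to magnitude `gain / 2`,
#' signs inherited from the background draw. The planted loading is thus the
#' largest absolute entry of its column by construction whenever
#' `gain > max(gain / 2, 1)`. Column-rank deficiency (a zero-probability
#' event) is handled by redrawing with an incremented seed.
#'
#' @param m Number of biomarkers (rows).
#' @param k Number of components (columns), `k <= m`.
#' @param planted Integer vector of planted biomarker row indices (1-based).
#' @param gain Planted loading magnitude, >= 1.
#' @param seed Integer seed.
#' @return An `m x k` matrix of full column rank.
#' @export
sim_mixing <- function(m, k, planted = integer(0), gain = 5, seed = 1L) {
  if (k < 1L || m < 1L) abort("m and k must be positive integers.")
  if (k > m) abort("k must not exceed m: a mixing matrix needs at least as many biomarkers as components.")
  planted <- as.integer(planted)
  if (anyDuplicated(planted) || any(planted < 1L) || any(planted > m))
    abort("planted must be distinct row indices in [1, m].")
  if (gain < 1) abort("gain must be >= 1.")
  for (attempt in 0:24) {
    A <- withr::with_seed(seed + attempt, matrix(stats::runif(m * k, -1, 1), m, k))
    if (length(planted)) {
      comp <- ((seq_along(planted) - 1L) %% k) + 1L
      for (i in seq_along(planted)) {
        b <- planted[i]
        A[b, ] <- (gain / 2) * sign(A[b, ])
        A[b, comp[i]] <- gain * sign(A[b, comp[i]])
      }
    }
    if (qr(A)$rank == k) return(A)
  }
  abort("could not draw a full-column-rank mixing matrix.") # nocov
}

#' Generate longitudinal lab records with known latent structure
#'
#' Realizes the generative model described in [sim_config()]: latent cell
#' values `X = A S + E` (observation noise `E`), a missing-completely-at-
#' random mask at the patient-biomarker cell level, and
#' `visits_per_patient` independently jittered repeat measurements with
#' distinct ordinal visit days for every observed cell. Missing cells emit
#' no record at all, so the pruning and imputation stages downstream are
#' exercised. Output is byte-identical for identical configs.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{records}{tibble with columns `patient_id`, `biomarker`,
#'       `value`, `visit_date` (ordinal day), grouped by patient.}
#'     \item{truth}{a `clinarica_truth` list: `sources` (k x n), `mixing`
#'       (m x k), `planted_biomarkers`, `patient_ids`, `biomarker_ids`.}
#'   }
#' @export
sim_lab_records <- function(config = sim_config()) {
  if (!inherits(config, "clinarica_sim_config"))
    config <- do.call(sim_config, as.list(config))
  m <- config$n_biomarkers; n <- config$n_patients; k <- config$n_sources
  sub <- withr::with_seed(config$seed,
                          sample.int(.Machine$integer.max - 26L, 4L))

  S <- sim_sources(k, n, seed = sub[1])
  planted_idx <- if (config$n_planted > 0L) {
    withr::with_seed(sub[2], sort(sample.int(m, config$n_planted)))
  } else integer(0)
  A <- sim_mixing(m, k, planted = planted_idx, gain = config$planted_gain,
                  seed = sub[3])

  biomarker_ids <- sprintf("B%0*d", nchar(m), seq_len(m))
  patient_ids <- sprintf("P%0*d", nchar(n), seq_len(n))
  dimnames(A) <- list(biomarker_ids, rownames(S))
  colnames(S) <- patient_ids

  V <- config$visits_per_patient
  rec <- withr::with_seed(sub[4], {
    X <- A %*% S
    if (config$observation_noise_sd > 0)
      X <- X + matrix(stats::rnorm(m * n, 0, config$observation_noise_sd), m, n)
    miss <- matrix(stats::runif(m * n) < config$missing_rate, m, n)
    idx <- which(!miss)                 # column-major: grouped by patient
    b <- ((idx - 1L) %% m) + 1L
    p <- ((idx - 1L) %/% m) + 1L
    value <- rep(X[idx], each = V)
    if (config$visit_noise_sd > 0)
      value <- value + stats::rnorm(length(value), 0, config$visit_noise_sd)
    tibble::tibble(
      patient_id = rep(patient_ids[p], each = V),
      biomarker = rep(biomarker_ids[b], each = V),
      value = value,
      visit_date = rep(seq_len(V), times = length(idx))
    )
  })

  truth <- structure(
    list(sources = S, mixing = A,
         planted_biomarkers = biomarker_ids[planted_idx],
         patient_ids = patient_ids, biomarker_ids = biomarker_ids),
    class = "clinarica_truth"
  )
  list(records = rec, truth = truth)
}

#' @export
print.clinarica_sim_config <- function(x, ...) {
  cat("<clinarica_sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.clinarica_truth <- function(x, ...) {
  cat(sprintf("<clinarica_truth> %d sources x %d patients, %d biomarkers\n",
              nrow(x$sources), ncol(x$sources), nrow(x$mixing)))
  if (length(x$planted_biomarkers))
    cat("  planted:", paste(x$planted_biomarkers, collapse = ", "), "\n")
  invisible(x)
}
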