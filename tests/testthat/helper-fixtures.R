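# Small fixtures built in code.

# Long-format records for a hand-enumerable clinarray: explicit values per
# (patient, biomarker) pair; each value becomes one visit.
records_from_list <- function(cells) {
  purrr::imap_dfr(cells, function(vals, key) {
    parts <- strsplit(key, "\\.")[[1]]
    tibble::tibble(patient_id = parts[1], biomarker = parts[2],
                   value = vals, visit_date = seq_along(vals))
  })
}

# Clinarray with a given observation mask (TRUE = observed); values are
# deterministic row + column effects so imputation tests are predictable.
clinarray_from_mask <- function(mask, values = NULL) {
  m <- nrow(mask); n <- ncol(mask)
  v <- if (is.null(values)) outer(seq_len(m), seq_len(n), function(b, p) b + p / 10) else values
  v[!mask] <- NA_real_
  dimnames(v) <- list(sprintf("b%02d", seq_len(m)), sprintf("p%02d", seq_len(n)))
  new_clinarray(v)
}

# The 12 x 6 pruning fixture: patient p06 has only 4 observed biomarkers,
# biomarker b12 is observed in 2 of the 5 remaining patients; everything
# else fully observed. With thresholds (5, 0.5) pruning must give 11 x 5.
prune_fixture_12x6 <- function() {
  mask <- matrix(TRUE, 12, 6)
  mask[5:12, 6] <- FALSE               # p06: 4 observed biomarkers
  mask[12, c(1, 2, 3, 6)] <- FALSE     # b12: observed in p04, p05 only
  clinarray_from_mask(mask)
}

# A standardized planted-structure matrix generated through the full
# synthetic path (no missingness so no imputation noise).
standardized_planted <- function(n_patients = 1500, seed = 1,
                                 n_sources = 3, n_planted = 3, gain = 5,
                                 noise_sd = 2) {
  cfg <- sim_config(n_patients = n_patients, n_biomarkers = 30,
                    n_sources = n_sources, visits_per_patient = 1,
                    visit_noise_sd = 0, observation_noise_sd = noise_sd,
                    missing_rate = 0, n_planted = n_planted,
                    planted_gain = gain, seed = seed)
  sim <- sim_lab_records(cfg)
  list(X = standardize_biomarkers(build_clinarray(sim$records)),
       truth = sim$truth)
}
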