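test_that("whitening produces identity covariance from the top eigenpairs", {
  X <- sim_sources(2, 1000, seed = 2)       # unit-variance independent rows
  A <- matrix(c(2, 1, 1, 2), 2, 2)
  wh <- whiten_rows(A %*% X, 2)
  Cz <- tcrossprod(wh$Z) / ncol(wh$Z)
  expect_lt(max(abs(Cz - diag(2))), 1e-8)
  expect_equal(dim(wh$whitening_map), c(2L, 2L))

  # already-white input stays white
  wh2 <- whiten_rows(wh$Z, 2)
  expect_lt(max(abs(tcrossprod(wh2$Z) / ncol(wh2$Z) - diag(2))), 1e-8)
})

test_that("whitening refuses ranks the data cannot support", {
  X <- sim_sources(2, 200, seed = 1)
  X3 <- rbind(X, X[1, ] + X[2, ])           # rank 2 in 3 rows
  expect_error(whiten_rows(X3, 3), "rank")
})

test_that("the scree elbow matches hand-computed second differences", {
  expect_equal(n_components_scree(c(10, 9.5, 9, 1, 0.9, 0.8)), 3)
  expect_equal(n_components_scree(c(5, 4, 3, 2, 1)), 1)  # no elbow -> tie rule
  expect_warning(k <- n_components_scree(c(3, 1)), "fewer than 3")
  expect_equal(k, 2)
  expect_error(n_components_scree(c(1, 2, 3)), "descending")
})

test_that("the scree elbow finds a planted low-noise latent dimension", {
  cfg <- sim_config(n_patients = 400, n_biomarkers = 30, n_sources = 4,
                    visits_per_patient = 1, visit_noise_sd = 0,
                    observation_noise_sd = 0.05, missing_rate = 0,
                    n_planted = 0, seed = 19)
  sim <- sim_lab_records(cfg)
  std <- standardize_biomarkers(build_clinarray(sim$records))
  lam <- eigen(tcrossprod(unclass(std)) / ncol(std), symmetric = TRUE,
               only.values = TRUE)$values
  expect_equal(n_components_scree(lam), 4)
})

test_that("fastica returns an orthonormal rotation and demands white input", {
  Z <- whiten_rows(sim_sources(3, 2000, seed = 7), 3)$Z
  rot <- fastica_rotation(Z, seed = 1)
  expect_true(rot$converged)
  expect_lt(max(abs(tcrossprod(rot$W) - diag(3))), 1e-8)

  not_white <- matrix(c(3, 1, 1, 1), 2, 2) %*% sim_sources(2, 500, seed = 2)
  expect_error(fastica_rotation(not_white), "not whitened")
})

test_that("fastica separates an independent Laplace mixture", {
  S <- sim_sources(2, 5000, seed = 11)
  # self-separation: already-independent rows come back up to perm/sign
  whS <- whiten_rows(S, 2)
  rotS <- fastica_rotation(whS$Z, seed = 3)
  Y <- (rotS$W %*% whS$whitening_map) %*% S
  expect_true(all(match_abs_cor(Y, S) > 0.99))

  # global system: (W_white . whitening_map . A) is a signed permutation
  A <- matrix(c(2, 1, 1, 2), 2, 2)
  X <- A %*% S
  wh <- whiten_rows(X, 2)
  rot <- fastica_rotation(wh$Z, seed = 4)
  P <- rot$W %*% wh$whitening_map %*% A
  # each row: one entry near +-1, the other near 0
  expect_lt(max(abs(P[cbind(1:2, apply(abs(P), 1, which.min))])), 0.05)
  expect_lt(max(abs(1 - abs(P[cbind(1:2, apply(abs(P), 1, which.max))]))), 0.05)
  expect_lt(amari_error(P), 0.1)

  # cube contrast separates too
  rot_cube <- fastica_rotation(wh$Z, contrast = "cube", seed = 4)
  expect_lt(amari_error(rot_cube$W %*% wh$whitening_map %*% A), 0.1)
})

test_that("decompose recovers the mixing matrix up to perm/sign/scale", {
  k <- 3
  S <- sim_sources(k, 5000, seed = 23)
  A <- sim_mixing(10, k, seed = 31)
  X <- A %*% S
  sdr <- sqrt(rowMeans((X - rowMeans(X))^2))
  std <- new_clinarray(structure((X - rowMeans(X)) / sdr,
                                 dimnames = list(paste0("b", 1:10),
                                                 paste0("p", 1:5000))))
  dec <- ica_decompose(std, n_components = k, seed = 2)
  expect_true(dec$converged)
  # sources: unit variance and consistency with unmixing %*% X
  expect_lt(max(abs(rowMeans(dec$sources_est^2) -
                    rowMeans(dec$sources_est)^2 - 1)), 1e-8)
  expect_lt(max(abs(dec$sources_est - dec$unmixing %*% unclass(std))), 1e-8)
  # recovery: match components to truth, undo sign and scale, compare to
  # the row-standardized true mixing
  A_std <- A / sdr
  cors <- cor(t(dec$sources_est), t(S))
  perm <- apply(abs(cors), 2, which.max)
  expect_equal(sort(unname(perm)), 1:3)  # a genuine permutation
  signs <- sign(cors[cbind(perm, 1:3)])
  A_hat <- dec$mixing_est[, perm] %*% diag(signs)
  expect_lt(max(abs(A_hat - A_std)), 0.05)
  expect_lt(amari_error(dec$unmixing %*% A_std), 0.1)
})

test_that("full-rank decomposition reconstructs the data", {
  S <- sim_sources(4, 800, seed = 41)
  A <- sim_mixing(4, 4, seed = 42)
  X <- A %*% S
  sdr <- sqrt(rowMeans((X - rowMeans(X))^2))
  std <- new_clinarray(structure((X - rowMeans(X)) / sdr,
                                 dimnames = list(paste0("b", 1:4),
                                                 paste0("p", 1:800))))
  dec <- ica_decompose(std, n_components = 4, seed = 3)
  expect_lt(max(abs(dec$mixing_est %*% dec$sources_est - unclass(std))), 1e-6)
})

test_that("decomposition is deterministic given the seed", {
  sp <- standardized_planted(n_patients = 300, seed = 2)
  d1 <- ica_decompose(sp$X, n_components = 3, seed = 7)
  d2 <- ica_decompose(sp$X, n_components = 3, seed = 7)
  expect_identical(d1$unmixing, d2$unmixing)
  expect_identical(d1$mixing_est, d2$mixing_est)
})

test_that("decompose validates its input and tidies its output", {
  raw <- new_clinarray(matrix(1:12 * 1.0, 3, 4,
                              dimnames = list(paste0("b", 1:3), paste0("p", 1:4))))
  expect_error(ica_decompose(raw), "standardized")

  sp <- standardized_planted(n_patients = 200, seed = 3)
  dec <- ica_decompose(sp$X, n_components = 2, seed = 1)
  td <- tidy(dec)
  expect_named(td, c("biomarker", "component", "loading", "abs_loading"))
  expect_equal(nrow(td), 30 * 2)
  gl <- glance(dec)
  expect_equal(gl$n_components, 2L)
  expect_true(gl$converged)
})
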