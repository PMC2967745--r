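# hand-built ensembles -------------------------------------------------------

one_run_ensemble <- function(loadings) {
  loading_ensemble(list(abs(loadings)), biomarker_ids = rownames(loadings))
}

test_that("top-fraction rule matches a hand-computed pooled percentile", {
  # 100 biomarkers, one component, one run: scores {10, 1, 1, ..., 1};
  # pooled 99th percentile (type 7) is 1 + 0.01 * 9 = 1.09, so only the
  # loading-10 biomarker clears it
  L <- matrix(c(10, rep(1, 99)), ncol = 1,
              dimnames = list(sprintf("b%03d", 1:100), "IC1"))
  res <- significant_by_top_fraction(one_run_ensemble(L), fraction = 0.01)
  expect_identical(res$biomarkers, "b001")
  expect_equal(res$threshold, 1.09)

  # all-tied ensemble: the >= convention returns every biomarker
  Lt <- matrix(2, nrow = 5, ncol = 2,
               dimnames = list(paste0("b", 1:5), NULL))
  res_t <- significant_by_top_fraction(one_run_ensemble(Lt), fraction = 0.01)
  expect_setequal(res_t$biomarkers, paste0("b", 1:5))
})

test_that("means basis thresholds the distribution of per-biomarker means", {
  L <- matrix(c(5, 4, 1, 1, 1, 1, 1, 1, 1, 1), ncol = 1,
              dimnames = list(paste0("b", 1:10), NULL))
  res <- significant_by_top_fraction(one_run_ensemble(L), fraction = 0.2,
                                     basis = "means")
  expect_identical(res$biomarkers, c("b1", "b2"))
})

test_that("argmax consistency requires winning every converged run", {
  m <- 6
  ids <- paste0("b", 1:m)
  base <- matrix(0.1, m, 2, dimnames = list(ids, NULL))
  win <- function(r1, r2) { L <- base; L[r1, 1] <- 1; L[r2, 2] <- 1; L }
  # b1 wins component 1 in 9 of 10 runs, b2 in the tenth; b3 wins
  # component 2 always
  runs <- c(lapply(1:9, function(i) win(1, 3)), list(win(2, 3)))
  ens <- loading_ensemble(runs, ids)
  res <- significant_by_argmax_consistency(ens)
  expect_identical(res$biomarkers, "b3")       # strict universality
  expect_equal(unname(res$counts[c("b1", "b2", "b3")]), c(9, 1, 10))
  # counts conservation: run x component events sum to runs * components
  expect_equal(sum(res$events), 10 * 2)

  # single run: both winners
  single <- loading_ensemble(list(win(3, 5)), ids)
  expect_setequal(significant_by_argmax_consistency(single)$biomarkers,
                  c("b3", "b5"))
})

test_that("exact argmax ties break by biomarker order and are reported", {
  L <- matrix(c(1, 1, 0.2), ncol = 1, dimnames = list(paste0("b", 1:3), NULL))
  expect_message(res <- significant_by_argmax_consistency(one_run_ensemble(L)),
                 "ties")
  expect_identical(res$biomarkers, "b1")
})

test_that("non-converged runs are excluded from both statistics", {
  ids <- paste0("b", 1:4)
  good <- matrix(c(9, 1, 1, 1), ncol = 1, dimnames = list(ids, NULL))
  junk <- matrix(c(1, 9, 1, 1), ncol = 1, dimnames = list(ids, NULL))
  ens <- loading_ensemble(list(good, junk, good), ids,
                          converged = c(TRUE, FALSE, TRUE))
  res <- significant_by_argmax_consistency(ens)
  expect_identical(res$biomarkers, "b1")
  expect_equal(unname(res$counts["b2"]), 0)
  top <- significant_by_top_fraction(ens, fraction = 0.2)
  expect_identical(top$biomarkers, "b1")
})

test_that("consensus statistics are invariant to component permutation and sign", {
  sp <- standardized_planted(n_patients = 300, seed = 5, noise_sd = 0.5)
  ens <- ica_ensemble(sp$X, n_runs = 8, n_components = 3, master_seed = 2,
                      tol = 1e-4)
  scrambled <- ens
  scrambled$abs_loadings <- withr::with_seed(9, lapply(ens$abs_loadings, function(L) {
    L[, sample(ncol(L))]   # per-run column permutation; |.| kills sign flips
  }))
  a <- consensus_biomarkers(ens, fraction = 0.1, threshold_basis = "means")
  b <- consensus_biomarkers(scrambled, fraction = 0.1, threshold_basis = "means")
  expect_identical(a$significant_topfrac, b$significant_topfrac)
  expect_identical(a$significant_argmax, b$significant_argmax)
  expect_equal(a$mean_abs_loading, b$mean_abs_loading)
  expect_equal(a$argmax_counts, b$argmax_counts)
})

# ensembles from real decompositions ------------------------------------------

test_that("a one-run ensemble equals the single decomposition", {
  sp <- standardized_planted(n_patients = 250, seed = 8, noise_sd = 0.5)
  ens <- ica_ensemble(sp$X, n_runs = 1, n_components = 3, master_seed = 31,
                      tol = 1e-4)
  dec <- ica_decompose(sp$X, n_components = 3, seed = ens$run_seeds[1],
                       tol = 1e-4)
  expect_identical(ens$abs_loadings[[1]], abs(dec$mixing_est))
})

test_that("ensembles are reproducible and stable across initializations", {
  sp <- standardized_planted(n_patients = 500, seed = 10, noise_sd = 0.5)
  e1 <- ica_ensemble(sp$X, n_runs = 10, n_components = 3, master_seed = 5,
                     tol = 1e-4)
  e2 <- ica_ensemble(sp$X, n_runs = 10, n_components = 3, master_seed = 5,
                     tol = 1e-4)
  expect_identical(e1$abs_loadings, e2$abs_loadings)
  expect_identical(e1$run_seeds, e2$run_seeds)
  expect_false(anyDuplicated(e1$run_seeds) > 0)

  # well-separated mixture: every run's components match run 1's after
  # permutation alignment
  ref <- e1$abs_loadings[[1]]
  for (r in 2:10) {
    cors <- abs(cor(e1$abs_loadings[[r]], ref))
    expect_true(all(apply(cors, 2, max) > 0.95))
  }
})

test_that("an ensemble that mostly fails to converge aborts", {
  sp <- standardized_planted(n_patients = 200, seed = 12)
  expect_error(
    suppressMessages(ica_ensemble(sp$X, n_runs = 4, n_components = 3,
                                  max_iter = 1, tol = 1e-12, master_seed = 1)),
    "ensemble quality")
})

test_that("planted biomarkers are recovered by both rules, which agree", {
  sp <- standardized_planted(n_patients = 1500, seed = 1)
  ens <- ica_ensemble(sp$X, n_runs = 20, n_components = 3, master_seed = 7)
  cons <- consensus_biomarkers(ens, fraction = 0.1, threshold_basis = "means")
  expect_setequal(cons$significant_topfrac, sp$truth$planted_biomarkers)
  expect_setequal(cons$significant_argmax, sp$truth$planted_biomarkers)
  expect_true(cons$methods_agree)
})

test_that("raising the planted gain never loses a planted biomarker", {
  for (gain in c(3, 5, 8)) {
    sp <- standardized_planted(n_patients = 1500, seed = 4, gain = gain)
    ens <- ica_ensemble(sp$X, n_runs = 10, n_components = 3, master_seed = 3)
    cons <- consensus_biomarkers(ens, fraction = 0.1, threshold_basis = "means")
    expect_true(all(sp$truth$planted_biomarkers %in% cons$significant_argmax),
                label = sprintf("argmax recovery at gain %g", gain))
    expect_true(all(sp$truth$planted_biomarkers %in% cons$significant_topfrac),
                label = sprintf("top-fraction recovery at gain %g", gain))
  }
})

test_that("the consensus report renders edge cases explicitly", {
  ids <- paste0("b", 1:4)
  L1 <- matrix(c(9, 1, 1, 1), ncol = 1, dimnames = list(ids, NULL))
  L2 <- matrix(c(1, 9, 1, 1), ncol = 1, dimnames = list(ids, NULL))
  ens <- loading_ensemble(list(L1, L2), ids)
  cons <- consensus_biomarkers(ens, fraction = 0.25)
  expect_false(cons$methods_agree)           # argmax set empty, topfrac not
  lines <- summary(cons)
  expect_true(any(grepl("none significant", lines)))
  expect_true(any(grepl("symmetric difference", lines)))

  td <- tidy(cons)
  expect_equal(nrow(td), 4)
  gl <- glance(cons)
  expect_false(gl$methods_agree)
  expect_equal(gl$n_runs_used, 2)
})
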