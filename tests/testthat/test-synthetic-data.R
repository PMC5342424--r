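test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(n_psp = 17, n_samples = 17), "n_psp")
  expect_error(simulation_config(n_active_genes = 200), "n_active_genes")
  expect_error(simulation_config(n_active_features_per_gene = 300),
               "n_active_features_per_gene")
  expect_error(simulation_config(coeff_rank = 0), "coeff_rank")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
})

test_that("planted coefficients have the promised support, rank and time structure", {
  cfg <- simulation_config(n_features = 30, n_genes = 10, n_timepoints = 3,
                           n_active_genes = 6, n_active_features_per_gene = 5,
                           coeff_rank = 2, temporal_jitter = 0.1, seed = 7)
  W <- generate_coefficients(cfg)
  expect_equal(dim(W), c(30, 10, 3))
  nz_cols <- which(apply(W != 0, 2, any))
  expect_equal(nz_cols, attr(W, "active_genes"), ignore_attr = TRUE)
  expect_length(nz_cols, 6)
  # per-gene nonzero rows identical across time
  for (j in nz_cols) {
    supp <- lapply(seq_len(3), function(t) which(W[, j, t] != 0))
    expect_length(unique(supp), 1)
    expect_length(supp[[1]], 5)
  }
  # singular-value oracle: numerical rank of the unfolding <= coeff_rank
  sv <- svd(matrix(W, 30))$d
  expect_lte(sum(sv > 1e-8 * max(sv)), 2)

  # zero jitter forces exact time constancy
  W0 <- generate_coefficients(simulation_config(
    n_features = 30, n_genes = 10, n_timepoints = 3, n_active_genes = 6,
    n_active_features_per_gene = 5, coeff_rank = 2, temporal_jitter = 0,
    seed = 7))
  expect_equal(W0[, , 1], W0[, , 2])
  expect_equal(W0[, , 1], W0[, , 3])

  # no active genes -> all-zero tensor
  Wz <- generate_coefficients(simulation_config(n_active_genes = 0, seed = 1))
  expect_true(all(Wz == 0))
})

test_that("generated cohorts match the study geometry and are deterministic", {
  coh <- generate_dataset(simulation_config(seed = 11))
  expect_equal(dim(coh$X), c(17, 225, 4))
  expect_equal(dim(coh$Y), c(17, 119))
  expect_equal(sum(coh$labels == "PsP"), 5)
  expect_equal(sum(coh$labels == "TTP"), 12)
  # standardization of every feature column at every time point
  for (t in 1:4) {
    expect_lt(max(abs(colMeans(coh$X[, , t]))), 1e-10)
    expect_lt(max(abs(apply(coh$X[, , t], 2, sd) - 1)), 1e-10)
  }
  coh2 <- generate_dataset(simulation_config(seed = 11))
  expect_identical(coh$X, coh2$X)
  expect_identical(coh$Y, coh2$Y)
  expect_identical(coh$W_true, coh2$W_true)
  coh3 <- generate_dataset(simulation_config(seed = 12))
  expect_false(identical(coh$Y, coh3$Y))
})

test_that("noise-free, shift-free expression equals the time-averaged linear predictor", {
  cfg <- small_profile(seed = 5, noise_sd = 0, effect_size = 0)
  coh <- generate_dataset(cfg)
  signal <- Reduce(`+`, lapply(1:3, function(t) coh$X[, , t] %*% coh$W_true[, , t])) / 3
  expect_equal(unname(coh$Y), unname(signal), tolerance = 1e-12)
})

test_that("planted coefficients are recoverable by least squares on the time-averaged design", {
  cfg <- small_profile(seed = 6, noise_sd = 0, effect_size = 0,
                       temporal_jitter = 0)
  coh <- generate_dataset(cfg)
  Xbar <- Reduce(`+`, lapply(1:3, function(t) coh$X[, , t])) / 3
  What <- solve(crossprod(Xbar), crossprod(Xbar, coh$Y))
  expect_lt(max(abs(What - coh$W_true[, , 1])), 1e-6)
})

test_that("the planted group shift converges to effect_size in large samples", {
  cfg <- small_profile(seed = 8, n_samples = 2000, n_psp = 700,
                       effect_size = 2)
  coh <- generate_dataset(cfg)
  act <- coh$active_genes
  diffs <- colMeans(coh$Y[coh$labels == "PsP", act, drop = FALSE]) -
    colMeans(coh$Y[coh$labels == "TTP", act, drop = FALSE])
  expect_true(all(abs(diffs - 2) < 0.1))
})

test_that("validation cohorts shift biomarkers upward in PsP and stay independent", {
  cfg <- simulation_config(seed = 21)
  vc <- generate_validation_cohort(cfg, biomarkers = c(3, 10))
  expect_equal(nrow(vc$Y), 21)
  expect_equal(sum(vc$labels == "PsP"), 6)
  expect_identical(vc$active_genes, c(3L, 10L))
  # with a large cohort and effect 3 each biomarker separates cleanly
  big <- generate_validation_cohort(simulation_config(seed = 3,
                                                      effect_size = 3),
                                    biomarkers = 1:2,
                                    n_samples = 200, n_psp = 60)
  p <- vapply(1:2, function(j)
    wilcoxon_p(big$Y[big$labels == "PsP", j], big$Y[big$labels == "TTP", j]),
    numeric(1))
  expect_true(all(p < 0.005))
  expect_warning(nullc <- generate_validation_cohort(cfg, integer(0)),
                 "empty biomarker")
  expect_equal(length(nullc$active_genes), 0)
})
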