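small_cfg <- function(...) {
  sim_config(n_female = 40, n_male = 40, n_traits = 8,
             replicate_subset = 12, ...)
}

test_that("generation is byte-identical under the same seed", {
  a <- generate_cohort(small_cfg(), seed = 99)
  b <- generate_cohort(small_cfg(), seed = 99)
  expect_identical(a$measurements, b$measurements)
  expect_identical(as.data.frame(a$covariates), as.data.frame(b$covariates))
  expect_identical(a$truth$z, b$truth$z)
  c_ <- generate_cohort(small_cfg(), seed = 100)
  expect_false(identical(a$measurements, c_$measurements))
})

test_that("config validation and pathology injection guard their inputs", {
  expect_error(sim_config(sigma_me = -1))
  expect_error(sim_config(beta_female = c(1, 2)))
  cfg <- small_cfg()
  expect_error(inject_pathology(cfg, "measurement_error", "T99", 3),
               "unknown trait")
  expect_error(inject_pathology(cfg, "gremlins", "T01", 1), "unknown")
  # zero DA shift leaves the config unchanged
  same <- inject_pathology(cfg, "DA", "T01", 0)
  expect_equal(same$da_shift, cfg$da_shift)
})

test_that("the generated tables respect the configured structure", {
  cfg <- sim_config()
  coh <- generate_cohort(cfg, seed = 12)
  m <- coh$measurements
  expect_s3_class(m, "fa_measurements")
  expect_equal(length(unique(m$individual_id)), 303)
  expect_equal(sum(table(unique(
    data.frame(m$individual_id, m$sex))[, 2]) == c(149, 154)), 2)
  # replicate 2 only for the designated subset
  rep2_ids <- unique(m$individual_id[m$replicate == 2L])
  expect_setequal(rep2_ids, coh$truth$replicate_ids)
  expect_length(rep2_ids, 30)
  # covariate missingness below 5% per variable
  mr <- missingness_report(coh$covariates)
  expect_true(all(mr$fraction < 0.08))
  # instability scale matches its definition exactly
  beta_i <- t(coh$truth$beta[, coh$truth$sex])
  expect_equal(coh$truth$s,
               exp(rowSums(coh$truth$z * beta_i)), tolerance = 1e-12)
})

test_that("categorical level frequencies track the configuration", {
  coh <- generate_cohort(sim_config(), seed = 13)
  spec <- coh$config$covariate_spec
  for (v in c("breastfed", "gestation_length", "season_birth")) {
    freq_obs <- prop.table(table(coh$truth$covariates_full[[v]]))
    expect_lt(max(abs(freq_obs - spec[[v]]$freqs)), 0.08)
  }
  # ~42% breastfed, as in the emulated cohort
  expect_lt(abs(mean(coh$truth$covariates_full$breastfed == "yes") - 0.42),
            0.08)
})

test_that("asymmetry magnitude scales with the instability scale", {
  cfg <- sim_config(beta_female = c(-0.8, 0, 0, 0))  # strong effect
  coh <- generate_cohort(cfg, seed = 14)
  tt <- trait_table(coh$measurements)
  mean_abs <- tapply(tt$abs_d, tt$individual_id, mean)
  s <- coh$truth$s[names(mean_abs)]
  expect_gt(cor(log(mean_abs), log(s)), 0.5)
})

test_that("injected pathologies surface in the targeted screens only", {
  cfg <- sim_config()
  cfg <- inject_pathology(cfg, "DA", "T03", 0.15)
  cfg <- inject_pathology(cfg, "antisymmetry", "T07", 0.30)
  coh <- generate_cohort(cfg, seed = 15)
  tt <- trait_table(coh$measurements)
  rep <- run_screen(tt, coh$measurements)
  expect_lt(rep$da_p_adj[rep$trait_id == "T03"], 0.05)
  expect_lt(rep$anti_p_adj[rep$trait_id == "T07"], 0.05)
  expect_lt(rep$anti_stat[rep$trait_id == "T07"], 0)
  # unaffected traits keep their Holm-adjusted p-values clean
  clean <- !rep$trait_id %in% c("T03", "T07")
  expect_true(all(rep$da_p_adj[clean] > 0.05, na.rm = TRUE))
})

test_that("antisymmetry injection is detected in most seeds", {
  hits <- vapply(1:15, function(s) {
    cfg <- inject_pathology(sim_config(), "antisymmetry", "T05", 0.30)
    coh <- generate_cohort(cfg, seed = 500 + s)
    tt <- trait_table(coh$measurements)
    d <- tt$d[tt$trait_id == "T05"]
    antisymmetry_test(d)$platykurtic
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("four latent factors leave a visible scree elbow", {
  coh <- generate_cohort(sim_config(), seed = 16)
  imp <- impute_famd(coh$covariates, ncp = 5)
  m <- famd(imp, ndim = 6)
  eig <- m$eigenvalues
  # the 4 leading eigenvalues stand off the bulk that follows
  expect_gt(mean(eig[1:4]), 1.3 * mean(eig[5:10]))
})

test_that("dimension alignment recovers the latent factors", {
  coh <- generate_cohort(sim_config(), seed = 17)
  imp <- impute_famd(coh$covariates, ncp = 5)
  m <- famd(imp, ndim = 4)
  al <- align_dims_to_truth(m$ind_coords, coh$truth$z)
  expect_setequal(al$map$dim, 1:4)
  expect_true(all(abs(al$map$correlation) > 0.4))
  # aligned scores correlate positively with their factors
  for (f in 1:4) {
    expect_gt(cor(al$aligned[, f], coh$truth$z[, f]), 0.4)
  }
})
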