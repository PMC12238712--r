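test_that("replicate bias test matches the closed-form t oracle", {
  same <- c(5.1, 5.3, 4.9, 5.0)
  r <- replicate_bias_test(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  shifted <- replicate_bias_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(shifted$exact_bias)
  expect_equal(shifted$p, 0)

  first <- c(5.0, 5.2, 4.9); second <- c(5.1, 5.1, 5.0)
  r2 <- replicate_bias_test(first, second)
  o <- oracle_t(second - first)
  expect_equal(r2$t, o$t, tolerance = 1e-12)
  expect_equal(r2$df, o$df)
  expect_equal(r2$p, o$p, tolerance = 1e-12)

  expect_error(replicate_bias_test(c(1, 2), c(1, 2)), "at least 3")
})

test_that("error-vs-asymmetry screen uses a strict inequality", {
  expect_true(error_vs_asymmetry_screen(c(0.30, 0.30),
                                        c(0.10, 0.10))$exclude)
  expect_false(error_vs_asymmetry_screen(0.05, 0.20)$exclude)
  expect_false(error_vs_asymmetry_screen(c(0.1, 0.2),
                                         c(0.2, 0.1))$exclude)  # equal means
  expect_error(error_vs_asymmetry_screen(numeric(0), 0.1),
               "non-empty")
})

test_that("Grubbs scan flags gross outliers and is idempotent", {
  tight <- c(0.1, -0.1, 0.0, 0.05, -0.05)
  expect_length(grubbs_scan(tight)$outlier_ids, 0)

  d <- c(0.1, -0.1, 0.0, 0.05, 5.0)
  g <- grubbs_scan(d, alpha = 0.05)
  expect_equal(g$outlier_ids, "5")
  # verify G and the critical value against the independent formula
  expect_equal(g$G_values[1], max(abs(d - mean(d))) / sd(d),
               tolerance = 1e-12)
  expect_equal(g$critical_values[1], oracle_grubbs_crit(5, 0.05),
               tolerance = 1e-12)

  # idempotence: rescanning the cleaned vector finds nothing
  cleaned <- d[-5]
  expect_length(grubbs_scan(cleaned)$outlier_ids, 0)

  const <- grubbs_scan(rep(0.2, 6))
  expect_true(const$degenerate)
  expect_length(const$outlier_ids, 0)
})

test_that("directional asymmetry is a one-sample t-test of mean zero", {
  sym <- c(-0.2, -0.1, 0, 0.1, 0.2)
  r <- directional_asymmetry_test(sym)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  d <- c(0.2, 0.25, 0.3, 0.22)
  r2 <- directional_asymmetry_test(d)
  o <- oracle_t(d)
  expect_equal(r2$t, o$t, tolerance = 1e-12)
  expect_equal(r2$p, o$p, tolerance = 1e-12)
  expect_lt(r2$p, 0.05)

  set.seed(4)
  wide <- c(rnorm(200, 0, 10))
  wide <- wide - mean(wide)  # exactly mean 0, huge spread
  expect_gt(directional_asymmetry_test(wide)$p, 0.9)
})

test_that("antisymmetry flags platykurtosis from a two-mode mixture", {
  set.seed(11)
  bimodal <- c(rnorm(25, -1, 0.1), rnorm(25, 1, 0.1))
  r <- antisymmetry_test(bimodal)
  expect_true(r$platykurtic)
  expect_lt(r$statistic, 0)
  expect_equal(r$kurtosis, oracle_kurtosis(bimodal), tolerance = 1e-12)

  expect_true(antisymmetry_test(rep(0.3, 10))$degenerate)
  expect_error(antisymmetry_test(rnorm(5)), "at least 8")
})

test_that("antisymmetry type-I rate on normal data stays near alpha", {
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    antisymmetry_test(rnorm(500))$platykurtic
  }, logical(1))
  expect_gte(mean(!flags), 0.90)
})

test_that("size dependence is Spearman with tie-averaged ranks", {
  inc <- size_dependence_test(1:20 / 10, 1:20)
  expect_equal(inc$overall$rho, 1)

  set.seed(9)
  a <- runif(200); s <- sample(a)  # independent permutation
  ind <- size_dependence_test(a, s)
  expect_lt(abs(ind$overall$rho), 0.15)
  expect_gt(ind$overall$p, 0.05)

  g <- size_dependence_test(c(a, runif(4)), c(s, runif(4)),
                            groups = c(rep("F", 200), rep("M", 4)))
  expect_true(g$by_group$M$skipped)
  expect_equal(g$by_group$M$reason, "too_few_observations")
  expect_false(g$by_group$F$skipped)
})

test_that("Holm adjustment matches the step-down formula and its invariants", {
  expect_equal(holm_correct(0.03)$adjusted, 0.03)
  hand <- holm_correct(c(0.01, 0.04, 0.03))
  expect_equal(hand$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(rep(1, 5))$adjusted, rep(1, 5))
  expect_false(any(holm_correct(rep(1, 5))$reject))
  expect_error(holm_correct(c(0.1, 1.2)), "\\[0, 1\\]")

  # dominance and order invariance over random vectors
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_correct(p)$adjusted
    expect_true(all(adj >= p))
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(holm_correct(p[perm])$adjusted, adj[perm])
  }
})

test_that("run_screen excludes exactly the error-inflated traits", {
  cfg <- sim_config(n_traits = 22)
  cfg <- inject_pathology(cfg, "measurement_error", c("T05", "T13"),
                          magnitude = 3)
  coh <- generate_cohort(cfg, seed = 42)
  tt <- trait_table(coh$measurements)
  rep <- run_screen(tt, coh$measurements)
  err_excluded <- rep$trait_id[rep$error_exceeds_asymmetry]
  expect_setequal(err_excluded, c("T05", "T13"))
  expect_false(any(rep$retained[rep$trait_id %in% c("T05", "T13")]))
})

test_that("the 28-trait replay retains 20 traits", {
  coh <- generate_cohort(replay_sim_config(), seed = 5)
  tt <- trait_table(coh$measurements)
  rep <- run_screen(tt, coh$measurements)
  s <- attr(rep, "summary")
  expect_equal(s$screened, 28)
  expect_equal(s$excluded_error, 6)
  expect_equal(s$excluded_low_presence, 2)
  expect_equal(s$retained, 20)
})
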