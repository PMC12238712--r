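test_that("intercept-only logistic recovers the closed-form log-odds", {
  y <- c(rep(1, 45), rep(0, 252))
  fit <- fit_logistic(y)
  expect_equal(fit$coefficients$estimate, log(45 / 252), tolerance = 1e-8)
  expect_equal(fit$n, 297)
})

test_that("a known odds ratio of 3 yields slope log 3", {
  # grouped 2x2: x=0 odds 30/70, x=1 odds 90/70 -> OR exactly 3
  y <- c(rep(1, 30), rep(0, 70), rep(1, 90), rep(0, 70))
  x <- c(rep(0, 100), rep(1, 160))
  fit <- fit_logistic(y, cbind(x = x))
  expect_equal(fit$coefficients$estimate[2], log(3), tolerance = 1e-6)
})

test_that("the IRLS fit matches a direct likelihood-maximisation oracle", {
  set.seed(14)
  X <- matrix(rnorm(120 * 2), 120, 2, dimnames = list(NULL, c("d1", "d2")))
  eta <- -0.5 + 0.8 * X[, 1] - 0.4 * X[, 2]
  y <- rbinom(120, 1, plogis(eta))
  fit <- fit_logistic(y, X)
  o <- oracle_logistic(y, X)
  expect_equal(fit$coefficients$estimate, o, tolerance = 1e-6)
  expect_lte(fit$residual_deviance, fit$null_deviance)
})

test_that("degenerate outcomes and separation are reported", {
  expect_error(fit_logistic(rep(1, 20)), "single class")
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_warning(fit <- fit_logistic(y, cbind(x = x)), "separation")
  expect_true(fit$separation)
})

test_that("lack of fit is the upper-tail chi-square of the residual deviance", {
  set.seed(15)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(0.5 * X[, 1]))
  fit <- fit_logistic(y, X)
  expect_equal(fit$lack_of_fit_p,
               pchisq(fit$residual_deviance, fit$residual_df,
                      lower.tail = FALSE), tolerance = 1e-12)
  expect_gte(fit$lack_of_fit_p, 0)
  expect_lte(fit$lack_of_fit_p, 1)
  # deviance equal to a large df sits near the chi-square median
  expect_equal(pchisq(1000, 1000, lower.tail = FALSE), 0.5,
               tolerance = 0.02)
})

test_that("sex-stratified fits are independent and report per-sex n", {
  set.seed(16)
  n <- 160
  ids <- sprintf("i%03d", 1:n)
  dims <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(ids, paste0("dim", 1:4)))
  fa <- structure(data.frame(
    individual_id = ids, n_observed_traits = 20L,
    composite_raw = rnorm(n), composite_z = rnorm(n),
    high_fa = rbinom(n, 1, 0.2), included = TRUE,
    sex = factor(rep(c("F", "M"), each = n / 2), levels = c("F", "M")),
    stringsAsFactors = FALSE), class = c("fa_index_result", "data.frame"))
  res <- sex_stratified_run(fa, dims)
  expect_named(res$fits, c("F", "M"))
  expect_equal(res$fits$F$n, 80)
  expect_equal(res$fits$M$n, 80)

  # identical data passed as both sexes gives identical fits
  fa2 <- fa; fa2$sex <- factor(rep(c("F", "M"), n / 2),
                               levels = c("F", "M"))
  fa_dup <- rbind(fa, fa)
  fa_dup$individual_id <- c(paste0(ids, "F"), paste0(ids, "M"))
  fa_dup$sex <- factor(rep(c("F", "M"), each = n), levels = c("F", "M"))
  dims_dup <- rbind(dims, dims)
  rownames(dims_dup) <- fa_dup$individual_id
  class(fa_dup) <- c("fa_index_result", "data.frame")
  res2 <- sex_stratified_run(fa_dup, dims_dup)
  expect_equal(res2$fits$F$coefficients$estimate,
               res2$fits$M$coefficients$estimate, tolerance = 1e-10)
})

test_that("the high-FA sex chi-square has no continuity correction", {
  counts <- rbind(M = c(high = 25, low = 126), F = c(high = 20, low = 126))
  r <- high_fa_sex_chisq(counts)
  expect_equal(round(r$X2, 2), 0.47)
  expect_equal(r$df, 1)
  expect_equal(round(r$p, 2), 0.49)

  eq <- high_fa_sex_chisq(rbind(c(10, 90), c(10, 90)))
  expect_equal(eq$X2, 0)
  expect_equal(eq$p, 1)

  # hand formula sum (O - E)^2 / E
  tab <- rbind(c(30, 70), c(10, 90))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(high_fa_sex_chisq(tab)$X2, sum((tab - E)^2 / E),
               tolerance = 1e-12)
  expect_error(high_fa_sex_chisq(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("one-way ANOVA agrees with the sum-of-squares oracle", {
  same <- group_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)

  set.seed(17)
  v2 <- rnorm(30); g2 <- rep(c("a", "b"), each = 15)
  aov2 <- group_anova(v2, g2)
  t2 <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(aov2$F, unname(t2$statistic)^2, tolerance = 1e-10)

  v3 <- c(0.1, 0.2, 0.05, -0.3, -0.5, -0.39, 0.0, 0.02, -0.1)
  g3 <- rep(c("uk_france", "other", "ireland"), each = 3)
  expect_equal(group_anova(v3, g3)$F, oracle_anova_F(v3, g3),
               tolerance = 1e-12)
  expect_error(group_anova(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("Welch t matches the hand formulas and its equal-variance limit", {
  x <- c(5.1, 5.4, 4.9, 5.2); y <- c(4.2, 4.8, 4.1, 5.0, 4.4)
  r <- welch_t(c(x, y), rep(c("a", "b"), c(4, 5)))
  o <- oracle_welch(x, y)
  expect_equal(abs(r$t), abs(o$t), tolerance = 1e-10)
  expect_equal(r$df, o$df, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)

  same <- welch_t(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$t, 0)

  set.seed(18)
  eqv <- c(rnorm(50), rnorm(50))
  df <- welch_t(eqv, rep(c("a", "b"), each = 50))$df
  expect_lt(abs(df - 98), 10)

  degen <- welch_t(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})
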