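# Independent oracles, coded from the textbook formulas and kept separate
# from the implementation paths they check.

# Paired / one-sample t statistic from the closed form d-bar / (s_d / sqrt(n)).
oracle_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Two-sided Grubbs critical value from the explicit t-quantile formula.
oracle_grubbs_crit <- function(n, alpha) {
  t2 <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

# Moment kurtosis with n-denominator moments.
oracle_kurtosis <- function(x) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m4 <- sum((x - mean(x))^4) / n
  m4 / m2^2
}

# Holm step-down adjustment applied literally to the sorted p-values.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Composite FA index in one line per step, for tiny worked examples.
oracle_composite <- function(abs_d_mat, min_traits) {
  z <- apply(abs_d_mat, 2, function(c) (c - mean(c, na.rm = TRUE)) /
               sd(c, na.rm = TRUE))
  raw <- rowMeans(z, na.rm = TRUE)
  k <- rowSums(!is.na(z))
  inc <- k >= min_traits
  zz <- rep(NA_real_, length(raw))
  zz[inc] <- (raw[inc] - mean(raw[inc])) / sd(raw[inc])
  list(raw = raw, z = zz, included = inc)
}

# FAMD encoding + eigendecomposition coded independently: explicit column
# construction and eigen() of the weighted cross-product (not svd()).
oracle_famd <- function(quant_df, cat_df) {
  n <- if (!is.null(quant_df)) nrow(quant_df) else nrow(cat_df)
  cols <- list()
  if (!is.null(quant_df)) {
    for (v in names(quant_df)) {
      x <- quant_df[[v]]
      cols[[length(cols) + 1L]] <- (x - mean(x)) /
        sqrt(sum((x - mean(x))^2) / n)
    }
  }
  if (!is.null(cat_df)) {
    for (v in names(cat_df)) {
      f <- factor(cat_df[[v]])
      for (lev in levels(f)) {
        y <- as.numeric(f == lev)
        p <- mean(y)
        cols[[length(cols) + 1L]] <- (y - p) / sqrt(p)
      }
    }
  }
  X <- do.call(cbind, cols)
  ev <- eigen(crossprod(X) / n, symmetric = TRUE)
  keep <- ev$values > 1e-10
  list(eigenvalues = ev$values[keep], vectors = ev$vectors[, keep,
                                                           drop = FALSE])
}

# Logistic log-likelihood maximised by a generic optimiser.
oracle_logistic <- function(y, X) {
  Xd <- cbind(1, X)
  nll <- function(b) {
    eta <- as.vector(Xd %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(Xd)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  ni <- tapply(values, groups, length)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# Welch t and Welch-Satterthwaite df from the hand formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Null simulation config shared by calibration tests: no injected effects.
null_sim_config <- function(...) {
  sim_config(beta_female = rep(0, 4), beta_male = rep(0, 4), ...)
}

# The 28-trait replay configuration: 6 error-inflated traits and 2 traits
# with very low presence.
replay_sim_config <- function() {
  cfg <- sim_config(n_traits = 28)
  cfg <- inject_pathology(cfg, "measurement_error",
                          sprintf("T%02d", 1:6), magnitude = 3)
  cfg$trait_presence[c("T27", "T28")] <- 0.10
  cfg
}
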