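# Sex-stratified logistic regression of high FA on FAMD dimension scores,
# plus the descriptive contingency and group-comparison tests.

#' Logistic regression of a binary outcome on dimension scores
#'
#' Maximum-likelihood fit (binomial family, logit link, iteratively
#' reweighted least squares) with Wald tests per term, null/residual
#' deviances and the residual-deviance lack-of-fit p-value.
#'
#' @param y Binary 0/1 outcome vector; both classes must be present.
#' @param X Numeric predictor matrix (dimension scores), one column per
#'   dimension; an intercept is added. May be NULL/zero-column for an
#'   intercept-only fit.
#' @param label Optional stratum label (e.g. sex) carried in the result.
#' @return An object of class \code{fa_logistic}: \code{coefficients} (data
#'   frame with \code{estimate}, \code{se}, \code{z}, \code{p}),
#'   \code{null_deviance}, \code{null_df}, \code{residual_deviance},
#'   \code{residual_df}, \code{lack_of_fit_p}, \code{converged},
#'   \code{separation}, \code{n}, \code{label}.
#' @export
fit_logistic <- function(y, X = NULL, label = NA_character_) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("dim", seq_len(ncol(X)))
  }
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (ncol(X) > 0 && qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("predictor matrix is rank-deficient", call. = FALSE)
  }
  dat <- data.frame(y = y)
  form <- if (ncol(X) > 0) {
    dat <- cbind(dat, as.data.frame(X))
    stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + ")))
  } else stats::as.formula("y ~ 1")
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  sm <- summary(fit)
  co <- sm$coefficients
  separation <- any(abs(co[, "Estimate"]) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (separation) {
    warning("possible complete separation: diverging coefficient(s)")
  }
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], z = co[, "z value"],
                      p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  res <- structure(list(
    coefficients = coefs,
    null_deviance = fit$null.deviance, null_df = fit$df.null,
    residual_deviance = fit$deviance, residual_df = fit$df.residual,
    converged = fit$converged, separation = separation,
    n = length(y), label = label, glm = fit), class = "fa_logistic")
  res$lack_of_fit_p <- lack_of_fit(res)
  res
}

#' Residual-deviance lack-of-fit test
#'
#' Upper-tail chi-square probability of the residual deviance at its residual
#' degrees of freedom; small values indicate the model fits worse than chance
#' would allow.
#'
#' @param fit An \code{fa_logistic}.
#' @return The lack-of-fit p-value.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "fa_logistic"))
  stats::pchisq(fit$residual_deviance, df = fit$residual_df,
                lower.tail = FALSE)
}

#' @export
print.fa_logistic <- function(x, ...) {
  if (!is.na(x$label)) cat("Stratum:", x$label, "\n")
  cat("Logistic fit, n = ", x$n, "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat("Null deviance ", format(x$null_deviance, digits = 5), " on ",
      x$null_df, " df; residual deviance ",
      format(x$residual_deviance, digits = 5), " on ", x$residual_df,
      " df; lack-of-fit p = ", format(x$lack_of_fit_p, digits = 2),
      "\n", sep = "")
  invisible(x)
}

#' Sex-stratified logistic regressions of high FA on dimension scores
#'
#' Fits one logistic model per sex: high FA (0/1) on the FAMD individual
#' coordinates, matched by individual id. Only individuals included in the
#' FA index (enough observed traits) enter.
#'
#' @param fa An \code{fa_index_result} with a \code{sex} column (from
#'   [fa_index()]).
#' @param dims Matrix of FAMD individual coordinates with individual ids as
#'   rownames (\code{ind_coords} of an \code{fa_famd}).
#' @param min_ratio Warn when a stratum has fewer than \code{min_ratio}
#'   observations per estimated parameter (default 10).
#' @return A list of class \code{fa_sex_fits}: \code{fits} (named list of
#'   \code{fa_logistic} per sex) and \code{table}, a combined per-term
#'   data frame over both sexes.
#' @export
sex_stratified_run <- function(fa, dims, min_ratio = 10) {
  stopifnot(inherits(fa, "fa_index_result"))
  fa_inc <- fa[fa$included, , drop = FALSE]
  idx <- match(fa_inc$individual_id, rownames(dims))
  if (anyNA(idx)) {
    stop("FA individuals missing from the dimension-score matrix: ",
         paste(utils::head(fa_inc$individual_id[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  X <- dims[idx, , drop = FALSE]
  sexes <- sort(unique(as.character(fa_inc$sex)))
  if (length(sexes) < 2) warning("only one sex present")
  fits <- lapply(sexes, function(s) {
    rows <- which(as.character(fa_inc$sex) == s)
    p_params <- ncol(X) + 1
    if (length(rows) < min_ratio * p_params) {
      warning("stratum ", s, " has ", length(rows), " rows for ", p_params,
              " parameters")
    }
    fit_logistic(fa_inc$high_fa[rows], X[rows, , drop = FALSE], label = s)
  })
  names(fits) <- sexes
  table <- do.call(rbind, lapply(fits, function(f) {
    cbind(sex = f$label, f$coefficients,
          lack_of_fit_p = f$lack_of_fit_p, n = f$n)
  }))
  rownames(table) <- NULL
  structure(list(fits = fits, table = table), class = "fa_sex_fits")
}

#' @export
print.fa_sex_fits <- function(x, ...) {
  for (f in x$fits) { print(f); cat("\n") }
  invisible(x)
}

#' Chi-square test of high-FA counts by sex
#'
#' Pearson chi-square on the 2 x 2 high/low-FA by sex table, without
#' continuity correction (the convention that matches hand computation of
#' \eqn{\sum (O - E)^2 / E} at df = 1).
#'
#' @param counts A 2 x 2 matrix of counts (rows = sex, columns = high/low).
#' @return A list with \code{X2}, \code{df}, \code{p}.
#' @export
high_fa_sex_chisq <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the contingency table", call. = FALSE)
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected cell count of zero",
                                  call. = FALSE)
  list(X2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' One-way fixed-effects ANOVA
#'
#' @param values Numeric response vector.
#' @param groups Group labels, >= 2 groups with n >= 2 each.
#' @return A list with \code{F}, \code{df1}, \code{df2}, \code{p} and the
#'   per-group means.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value,
       group_means = tapply(values, groups, mean))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite (fractional) degrees of
#' freedom, comparing the response between two groups.
#'
#' @param values Numeric response vector.
#' @param groups Two-level group labels, n >= 2 per group.
#' @return A list with \code{t}, \code{df}, \code{p} and the group means;
#'   \code{degenerate} is TRUE when both groups have zero variance.
#' @export
welch_t <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) != 2 || any(table(groups) < 2)) {
    stop("need exactly 2 groups with >= 2 observations each", call. = FALSE)
  }
  split_vals <- split(values, groups)
  if (all(vapply(split_vals, stats::sd, numeric(1)) == 0)) {
    m <- vapply(split_vals, mean, numeric(1))
    return(list(t = NA_real_, df = NA_real_, p = if (m[1] == m[2]) 1 else 0,
                group_means = m, degenerate = TRUE))
  }
  tt <- stats::t.test(values ~ groups)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       group_means = vapply(split_vals, mean, numeric(1)),
       degenerate = FALSE)
}
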