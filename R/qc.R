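# Pre-FA screening battery: replicate bias, measurement error vs asymmetry,
# Grubbs outlier scans, directional asymmetry, antisymmetry, size dependence,
# Holm (sequential Bonferroni) correction across traits.

#' Paired t-test for replicate measurement bias
#'
#' Two-sided paired t-test of second-session minus first-session measurements
#' of the same casts. A systematic shift between sessions indicates
#' intra-observer bias and disqualifies the trait.
#'
#' @param first,second Paired numeric vectors (mm) of equal length, n >= 3.
#' @return A list with \code{t}, \code{df}, \code{p}, \code{mean_diff} and
#'   \code{exact_bias} (TRUE when the differences have zero variance but a
#'   nonzero mean, where the t statistic is undefined yet the bias is exact).
#' @export
replicate_bias_test <- function(first, second) {
  ok <- is.finite(first) & is.finite(second)
  first <- first[ok]; second <- second[ok]
  n <- length(first)
  if (length(second) != n) stop("paired vectors must have equal length",
                                call. = FALSE)
  if (n < 3) stop("need at least 3 replicate pairs", call. = FALSE)
  diffs <- second - first
  if (stats::sd(diffs) == 0) {
    if (mean(diffs) == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  exact_bias = FALSE))
    }
    return(list(t = NA_real_, df = n - 1L, p = 0, mean_diff = mean(diffs),
                exact_bias = TRUE))
  }
  tt <- stats::t.test(second, first, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(diffs), exact_bias = FALSE)
}

#' Measurement-error versus asymmetry screen
#'
#' A trait is unusable for FA when its mean replicate measurement error
#' \eqn{|m_2 - m_1|} exceeds its mean unsigned asymmetry \eqn{|R - L|}: the
#' asymmetry signal is then indistinguishable from error. The comparison is a
#' strict inequality; equality does not exclude.
#'
#' @param me Per-observation absolute replicate differences (mm).
#' @param fa Per-individual unsigned asymmetries (mm).
#' @return A list with \code{mean_me}, \code{mean_fa}, \code{exclude}.
#' @export
error_vs_asymmetry_screen <- function(me, fa) {
  me <- me[is.finite(me)]; fa <- fa[is.finite(fa)]
  if (length(me) == 0 || length(fa) == 0) {
    stop("need non-empty error and asymmetry vectors", call. = FALSE)
  }
  mean_me <- mean(me); mean_fa <- mean(fa)
  list(mean_me = mean_me, mean_fa = mean_fa,
       exclude = mean_me > mean_fa)
}

# Two-sided Grubbs critical value at level alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Grubbs outlier scan
#'
#' Repeatedly tests the most extreme signed asymmetry against the Grubbs
#' critical value, removing confirmed outliers one at a time until no point
#' exceeds the threshold or fewer than 3 points remain. Confirms visually
#' suspected irregular raw measurements.
#'
#' @param d Numeric vector of signed asymmetries.
#' @param alpha Significance level per step (default 0.05).
#' @param ids Optional identifiers aligned with \code{d}; indices used when
#'   omitted.
#' @return A list with \code{outlier_ids} (in removal order), \code{G_values},
#'   \code{critical_values}, and \code{degenerate} (TRUE when the scan stopped
#'   because the remaining values have zero spread).
#' @export
grubbs_scan <- function(d, alpha = 0.05, ids = NULL) {
  keep <- is.finite(d)
  d <- d[keep]
  if (is.null(ids)) ids <- seq_along(d) else ids <- ids[keep]
  if (length(d) < 3) stop("need at least 3 observations", call. = FALSE)
  out_ids <- character(0); gs <- numeric(0); crits <- numeric(0)
  degenerate <- FALSE
  repeat {
    n <- length(d)
    if (n < 3) break
    s <- stats::sd(d)
    if (s == 0) { degenerate <- TRUE; break }
    dev <- abs(d - mean(d))
    i <- which.max(dev)
    G <- dev[i] / s
    crit <- grubbs_critical(n, alpha)
    if (G > crit) {
      out_ids <- c(out_ids, as.character(ids[i]))
      gs <- c(gs, G); crits <- c(crits, crit)
      d <- d[-i]; ids <- ids[-i]
    } else break
  }
  list(outlier_ids = out_ids, G_values = gs, critical_values = crits,
       degenerate = degenerate)
}

#' Directional asymmetry test
#'
#' One-sample two-sided t-test of the mean signed asymmetry against zero.
#' Directional asymmetry (a consistent side bias) inflates FA indices and
#' must be detected before interpretation.
#'
#' @param d Numeric vector of signed asymmetries, n >= 3.
#' @return A list with \code{t}, \code{df}, \code{p}, \code{mean_d},
#'   \code{degenerate}.
#' @export
directional_asymmetry_test <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0,
                mean_d = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_d = mean(d), degenerate = FALSE)
}

# Sample kurtosis b2 = m4 / m2^2 with n-denominator moments.
sample_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  m4 / m2^2
}

# Anscombe-Glynn transformation of the kurtosis statistic to an approximate
# standard normal deviate. Negative Z indicates platykurtosis.
kurtosis_z <- function(x) {
  n <- length(x)
  b2 <- sample_kurtosis(x)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  std <- (b2 - eb2) / sqrt(vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  inner <- 1 + std * sqrt(2 / (A - 4))
  if (inner <= 0) {
    # beyond the transformation's domain: kurtosis so far below normal that
    # the deviate saturates
    return(list(b2 = b2, z = -Inf))
  }
  z <- (1 - 2 / (9 * A) - ((1 - 2 / A) / inner)^(1 / 3)) /
    sqrt(2 / (9 * A))
  list(b2 = b2, z = z)
}

#' Antisymmetry test
#'
#' Antisymmetry — one side consistently larger but randomly which — produces a
#' bimodal, platykurtic distribution of signed asymmetries. The test is an
#' Anscombe-Glynn kurtosis test: antisymmetry is flagged only when kurtosis is
#' significantly below the normal value (negative direction). A Shapiro-Wilk
#' omnibus normality p-value is reported alongside for reference but is not
#' itself the flag.
#'
#' @param d Numeric vector of signed asymmetries, n >= 8.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list with \code{statistic} (kurtosis z), \code{p} (two-sided
#'   kurtosis p), \code{kurtosis}, \code{platykurtic} (flag),
#'   \code{shapiro_p}, \code{degenerate}.
#' @export
antisymmetry_test <- function(d, alpha = 0.05) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 8) stop("need at least 8 observations for the kurtosis test",
                  call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, kurtosis = NA_real_,
                platykurtic = FALSE, shapiro_p = NA_real_, degenerate = TRUE))
  }
  kz <- kurtosis_z(d)
  p <- 2 * stats::pnorm(-abs(kz$z))
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(d)$p.value else NA_real_
  list(statistic = kz$z, p = p, kurtosis = kz$b2,
       platykurtic = (p < alpha) && (kz$z < 0),
       shapiro_p = sw, degenerate = FALSE)
}

#' Size dependence of asymmetry
#'
#' Spearman rank correlation (average ranks for ties) between unsigned
#' asymmetry and trait size, in the pooled sample and optionally within
#' groups (sexes). A significant correlation means asymmetry scales with
#' size, and sex differences in the within-group correlations indicate
#' dimorphism in the size-asymmetry relation.
#'
#' @param abs_d Unsigned asymmetries.
#' @param size Trait sizes \eqn{(R+L)/2}, same length.
#' @param groups Optional group labels (e.g. sex) aligned with the data.
#' @param min_n Minimum observations per tested group (default 5).
#' @return A list with \code{overall = list(rho, p, n)} and, when groups are
#'   given, \code{by_group}, a named list of the same shape; groups below
#'   \code{min_n} or with a constant vector carry \code{skipped = TRUE} with a
#'   \code{reason}.
#' @export
size_dependence_test <- function(abs_d, size, groups = NULL, min_n = 5) {
  one <- function(a, s) {
    ok <- is.finite(a) & is.finite(s)
    a <- a[ok]; s <- s[ok]
    if (length(a) < min_n) {
      return(list(rho = NA_real_, p = NA_real_, n = length(a),
                  skipped = TRUE, reason = "too_few_observations"))
    }
    if (stats::sd(a) == 0 || stats::sd(s) == 0) {
      return(list(rho = NA_real_, p = NA_real_, n = length(a),
                  skipped = TRUE, reason = "constant_input"))
    }
    ct <- suppressWarnings(
      stats::cor.test(a, s, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(a),
         skipped = FALSE, reason = NA_character_)
  }
  res <- list(overall = one(abs_d, size))
  if (!is.null(groups)) {
    res$by_group <- lapply(split(seq_along(abs_d), groups),
                           function(i) one(abs_d[i], size[i]))
  }
  res
}

#' Holm (sequential Bonferroni) correction
#'
#' Step-down adjustment controlling the family-wise error rate: with the raw
#' p-values sorted ascending, the i-th adjusted value is the running maximum
#' of \eqn{\min(1, (m - i + 1) p_{(i)})}.
#'
#' @param p Vector of raw p-values in \eqn{[0, 1]} (\code{NA} passed through).
#' @param alpha Rejection level for the flags (default 0.05).
#' @return A list with \code{adjusted} (same order as input) and
#'   \code{reject}.
#' @export
holm_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(p, method = "holm")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted < alpha)
}

#' Default QC configuration
#'
#' @param alpha Significance level used by every screen (default 0.05).
#' @param grubbs_alpha Level for the outlier scan (default 0.05).
#' @param min_presence Minimum fraction of individuals with the trait
#'   observed for it to be retained (default 0.25).
#' @param exclude_on_bias If TRUE, traits also fail on Holm-significant
#'   directional asymmetry / antisymmetry / size dependence; by default these
#'   are reported but only error screens and low presence force exclusion.
#' @return A list of class \code{fa_qc_config}.
#' @export
qc_config <- function(alpha = 0.05, grubbs_alpha = 0.05,
                      min_presence = 0.25, exclude_on_bias = FALSE) {
  structure(list(alpha = alpha, grubbs_alpha = grubbs_alpha,
                 min_presence = min_presence,
                 exclude_on_bias = exclude_on_bias),
            class = "fa_qc_config")
}

#' Run the full pre-FA screening battery
#'
#' For every trait: paired replicate-bias t-test and the measurement-error
#' versus asymmetry screen (on the twice-measured subset), an iterative
#' Grubbs outlier scan on signed asymmetries, directional-asymmetry and
#' antisymmetry tests, and Spearman size-dependence overall and by sex. The
#' p-values of each test kind are Holm-corrected across traits (one family
#' per test kind). A trait is dropped when its replicate bias is
#' Holm-significant, its mean measurement error exceeds its mean unsigned
#' asymmetry, or too few individuals carry it.
#'
#' @param tt A trait table from [trait_table()] (analysis replicate).
#' @param measurements The full measurement table (supplies the replicate
#'   pairs; traits with no replicate-2 rows skip the error screens).
#' @param config A [qc_config()].
#' @return A data frame of class \code{fa_screen_report}, one row per trait,
#'   with an attribute \code{summary} (counts screened / excluded by error /
#'   excluded by low presence / retained) and attribute \code{outliers}
#'   (data frame of trait_id, individual_id cells flagged by Grubbs).
#' @export
run_screen <- function(tt, measurements, config = qc_config()) {
  stopifnot(inherits(config, "fa_qc_config"))
  m <- validate_measurements(measurements)
  traits <- unique(tt$trait_id)
  n_sample <- length(unique(m$individual_id))

  # replicate pairs per trait: value at replicate 2 minus replicate 1,
  # matched on (individual, side)
  m1 <- m[m$replicate == 1L, ]
  m2 <- m[m$replicate == 2L, ]
  pairs <- merge(m1[c("individual_id", "trait_id", "side", "value_mm")],
                 m2[c("individual_id", "trait_id", "side", "value_mm")],
                 by = c("individual_id", "trait_id", "side"),
                 suffixes = c("_1", "_2"))

  rows <- vector("list", length(traits))
  outlier_rows <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    sub <- tt[tt$trait_id == tr, ]
    pr <- pairs[pairs$trait_id == tr, ]
    n_obs <- nrow(sub)

    rb <- if (nrow(pr) >= 3) {
      replicate_bias_test(pr$value_mm_1, pr$value_mm_2)
    } else list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = NA_real_, exact_bias = FALSE)

    ev <- if (nrow(pr) >= 1 && n_obs >= 1) {
      error_vs_asymmetry_screen(abs(pr$value_mm_2 - pr$value_mm_1), sub$abs_d)
    } else list(mean_me = NA_real_, mean_fa = mean(sub$abs_d),
                exclude = FALSE)

    gs <- if (n_obs >= 3) {
      grubbs_scan(sub$d, alpha = config$grubbs_alpha,
                  ids = sub$individual_id)
    } else list(outlier_ids = character(0), degenerate = FALSE)
    if (length(gs$outlier_ids) > 0) {
      outlier_rows[[length(outlier_rows) + 1L]] <-
        data.frame(trait_id = tr, individual_id = gs$outlier_ids,
                   stringsAsFactors = FALSE)
    }

    # pattern tests run on the outlier-cleaned signed differences
    clean <- sub[!sub$individual_id %in% gs$outlier_ids, ]
    da <- if (nrow(clean) >= 3) directional_asymmetry_test(clean$d) else
      list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = FALSE)
    anti <- if (nrow(clean) >= 8) antisymmetry_test(clean$d, config$alpha) else
      list(statistic = NA_real_, p = NA_real_, kurtosis = NA_real_,
           platykurtic = FALSE, shapiro_p = NA_real_, degenerate = FALSE)
    sd_test <- size_dependence_test(clean$abs_d, clean$size,
                                    groups = clean$sex)
    rho_f <- sd_test$by_group[["F"]]; rho_m <- sd_test$by_group[["M"]]
    if (is.null(rho_f)) rho_f <- list(rho = NA_real_, p = NA_real_)
    if (is.null(rho_m)) rho_m <- list(rho = NA_real_, p = NA_real_)

    rows[[k]] <- data.frame(
      trait_id = tr, n_obs = n_obs,
      presence = n_obs / n_sample,
      replicate_bias_t = rb$t, replicate_bias_df = rb$df,
      replicate_bias_p = rb$p, exact_bias = rb$exact_bias,
      mean_me = ev$mean_me, mean_fa = ev$mean_fa,
      error_exceeds_asymmetry = isTRUE(ev$exclude),
      n_outliers = length(gs$outlier_ids),
      da_t = da$t, da_df = da$df, da_p = da$p,
      anti_stat = anti$statistic, anti_p = anti$p,
      kurtosis = anti$kurtosis, shapiro_p = anti$shapiro_p,
      size_rho = sd_test$overall$rho, size_p = sd_test$overall$p,
      size_rho_f = rho_f$rho, size_p_f = rho_f$p,
      size_rho_m = rho_m$rho, size_p_m = rho_m$p,
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)

  # Holm families: one per test kind, across traits
  rep$replicate_bias_p_adj <- holm_correct(rep$replicate_bias_p)$adjusted
  rep$da_p_adj <- holm_correct(rep$da_p)$adjusted
  rep$anti_p_adj <- holm_correct(rep$anti_p)$adjusted
  rep$size_p_adj <- holm_correct(rep$size_p)$adjusted

  alpha <- config$alpha
  bias_fail <- (!is.na(rep$replicate_bias_p_adj) &
                  rep$replicate_bias_p_adj < alpha) | rep$exact_bias
  error_fail <- rep$error_exceeds_asymmetry
  presence_fail <- rep$presence < config$min_presence
  pattern_fail <- rep(FALSE, nrow(rep))
  if (config$exclude_on_bias) {
    pattern_fail <- (!is.na(rep$da_p_adj) & rep$da_p_adj < alpha) |
      (!is.na(rep$anti_p_adj) & rep$anti_p_adj < alpha &
         !is.na(rep$anti_stat) & rep$anti_stat < 0) |
      (!is.na(rep$size_p_adj) & rep$size_p_adj < alpha)
  }
  rep$retained <- !(bias_fail | error_fail | presence_fail | pattern_fail)
  rep$exclusion_reason <- ifelse(
    !rep$retained,
    paste0(ifelse(bias_fail, "replicate_bias;", ""),
           ifelse(error_fail, "error_exceeds_asymmetry;", ""),
           ifelse(presence_fail, "low_presence;", ""),
           ifelse(pattern_fail, "pattern_bias;", "")),
    "")

  attr(rep, "summary") <- list(
    screened = nrow(rep),
    excluded_error = sum(bias_fail | error_fail),
    excluded_low_presence = sum(presence_fail & !(bias_fail | error_fail)),
    retained = sum(rep$retained))
  attr(rep, "outliers") <- if (length(outlier_rows) > 0) {
    do.call(rbind, outlier_rows)
  } else data.frame(trait_id = character(0), individual_id = character(0))
  class(rep) <- c("fa_screen_report", "data.frame")
  rep
}

#' @export
print.fa_screen_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Pre-FA trait screen: ", s$screened, " traits screened, ",
      s$excluded_error, " excluded by error screens, ",
      s$excluded_low_presence, " excluded by low presence, ",
      s$retained, " retained\n", sep = "")
  print(as.data.frame(x)[c("trait_id", "n_obs", "mean_me", "mean_fa",
                           "n_outliers", "retained", "exclusion_reason")],
        ...)
  invisible(x)
}

#' Drop Grubbs-flagged cells from a trait table
#'
#' Removal is cell-level: only the flagged individual x trait asymmetry is
#' dropped, not the whole individual.
#'
#' @param tt A trait table.
#' @param report An \code{fa_screen_report} (its \code{outliers} attribute
#'   lists the cells).
#' @return The trait table without the flagged cells.
#' @export
remove_outliers <- function(tt, report) {
  out <- attr(report, "outliers")
  if (is.null(out) || nrow(out) == 0) return(tt)
  drop <- paste(tt$trait_id, tt$individual_id, sep = "\r") %in%
    paste(out$trait_id, out$individual_id, sep = "\r")
  tt[!drop, , drop = FALSE]
}
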