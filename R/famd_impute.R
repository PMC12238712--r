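# Regularised iterative FAMD imputation of missing mixed-data cells:
# an EM-like loop alternating encoding, truncated SVD with shrunken singular
# values, and reconstruction of the missing cells only.

#' Per-variable missingness report
#'
#' @param cov A covariate table (data frame; an \code{individual_id} column
#'   is ignored).
#' @param threshold Flagging threshold on the missing fraction (default
#'   0.05).
#' @return A data frame with \code{variable}, \code{n_missing},
#'   \code{fraction} and \code{flagged}.
#' @export
missingness_report <- function(cov, threshold = 0.05) {
  vars <- setdiff(names(cov), "individual_id")
  n <- nrow(cov)
  miss <- vapply(cov[vars], function(x) sum(is.na(x)), integer(1))
  data.frame(variable = vars, n_missing = unname(miss),
             fraction = unname(miss) / n,
             flagged = unname(miss) / n > threshold,
             stringsAsFactors = FALSE)
}

#' Regularised iterative FAMD imputation
#'
#' Fills missing cells of a mixed quantitative/categorical table so that a
#' complete FAMD can be fitted. Missing quantitative cells start at column
#' means and missing categorical cells at the observed category proportions
#' (fuzzy memberships); the loop then encodes the current completed table,
#' truncates its weighted SVD at \code{ncp} components with singular values
#' shrunk by the mean discarded eigenvalue (\eqn{d_l (d_l^2 -
#' \hat\sigma^2)/d_l^2}), back-transforms the reconstruction to the original
#' scales, overwrites the missing cells only, and repeats until the summed
#' squared change in the imputed cells, relative to the previous iteration,
#' falls below \code{tol}. Column means, scales and category proportions are
#' recomputed every iteration. With \code{ncp = 0} the result is plain
#' mean/proportion imputation in a single pass.
#'
#' @param cov A covariate table with missing cells (\code{NA}).
#' @param schema Optional \code{fa_schema}; inferred when \code{NULL}.
#' @param ncp Number of components for the reconstruction (default 5).
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000); non-convergence warns and
#'   flags the result.
#' @param seed Optional seed set before the run; the algorithm itself is
#'   deterministic, so this only shields downstream code that draws random
#'   numbers.
#' @return An object of class \code{fa_imputation}: \code{completed} (data
#'   frame, categorical cells hard-assigned to the highest-membership level),
#'   \code{quant} and \code{fuzzy} (the internal completed blocks; fuzzy
#'   memberships are nonnegative and sum to 1 per cell), \code{iterations},
#'   \code{final_change}, \code{converged}, \code{ncp}, and the missingness
#'   masks. Observed cells are returned exactly as supplied.
#' @export
impute_famd <- function(cov, schema = NULL, ncp = 5, tol = 1e-6,
                        max_iter = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- split_mixed(cov, schema)
  quant <- parts$quant
  fuzzy <- parts$fuzzy
  n <- if (!is.null(quant)) nrow(quant) else nrow(fuzzy[[1]])

  all_missing_row <- rep(TRUE, n)
  if (!is.null(quant)) all_missing_row <- all_missing_row &
      apply(quant, 1, function(r) all(is.na(r)))
  for (Y in fuzzy) all_missing_row <- all_missing_row & is.na(Y[, 1])
  if (any(all_missing_row)) {
    stop("row(s) with every cell missing cannot be imputed: ",
         paste(utils::head(which(all_missing_row), 5), collapse = ", "),
         call. = FALSE)
  }

  quant_miss <- if (!is.null(quant)) is.na(quant) else NULL
  fuzzy_miss <- lapply(fuzzy, function(Y) is.na(Y[, 1]))
  if (!is.null(quant)) {
    if (any(colSums(!quant_miss) == 0)) {
      stop("a quantitative variable has no observed values", call. = FALSE)
    }
    for (j in seq_len(ncol(quant))) {
      quant[quant_miss[, j], j] <- mean(quant[!quant_miss[, j], j])
    }
  }
  for (v in names(fuzzy)) {
    Y <- fuzzy[[v]]
    miss <- fuzzy_miss[[v]]
    if (all(miss)) stop("categorical variable '", v,
                        "' has no observed values", call. = FALSE)
    props <- colMeans(Y[!miss, , drop = FALSE])
    if (any(miss)) {
      Y[miss, ] <- matrix(props, sum(miss), length(props), byrow = TRUE)
    }
    fuzzy[[v]] <- Y
  }

  n_missing <- sum(quant_miss) + sum(vapply(fuzzy_miss, sum, integer(1)) *
                                       vapply(fuzzy, ncol, integer(1)))
  if (n_missing == 0 || ncp == 0) {
    return(finish_imputation(parts$ids, quant, fuzzy, quant_miss, fuzzy_miss,
                             parts$schema, iterations = 1L,
                             final_change = 0, converged = TRUE, ncp = ncp))
  }

  extract_imputed <- function(quant, fuzzy) {
    vals <- numeric(0)
    if (!is.null(quant)) vals <- c(vals, quant[quant_miss])
    for (v in names(fuzzy)) {
      vals <- c(vals, as.vector(fuzzy[[v]][fuzzy_miss[[v]], , drop = FALSE]))
    }
    vals
  }

  prev <- extract_imputed(quant, fuzzy)
  converged <- FALSE
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    enc <- encode_parts(quant, fuzzy)
    if (iter == 1L && ncp >= min(n - 1, ncol(enc$X))) {
      stop("ncp (", ncp, ") must be below the rank of the encoded matrix",
           call. = FALSE)
    }
    S <- enc$X / sqrt(n)
    sv <- svd(S)
    eig <- sv$d^2
    tail_idx <- seq(ncp + 1, length(eig))
    sigma2 <- mean(eig[tail_idx][eig[tail_idx] > 1e-12 * eig[1]])
    if (!is.finite(sigma2)) sigma2 <- 0
    d_shrunk <- pmax((sv$d[seq_len(ncp)]^2 - sigma2), 0) /
      sv$d[seq_len(ncp)]
    Xhat <- sqrt(n) * sv$u[, seq_len(ncp), drop = FALSE] %*%
      (d_shrunk * t(sv$v[, seq_len(ncp), drop = FALSE]))
    colnames(Xhat) <- enc$col_info$column

    # back-transform and overwrite missing cells only
    ci <- enc$col_info
    if (!is.null(quant)) {
      for (j in seq_len(ncol(quant))) {
        row <- which(ci$column == colnames(quant)[j])
        fitted <- Xhat[, row] * ci$scale[row] + ci$center[row]
        quant[quant_miss[, j], j] <- fitted[quant_miss[, j]]
      }
    }
    for (v in names(fuzzy)) {
      rows <- which(ci$variable == v)
      fitted <- sweep(Xhat[, rows, drop = FALSE], 2, sqrt(ci$prop[rows]), "*")
      fitted <- sweep(fitted, 2, ci$prop[rows], "+")
      miss <- fuzzy_miss[[v]]
      if (any(miss)) {
        Fm <- fitted[miss, , drop = FALSE]
        Fm[Fm < 0] <- 0
        rs <- rowSums(Fm)
        zero <- rs == 0
        if (any(zero)) Fm[zero, ] <- matrix(ci$prop[rows], sum(zero),
                                            length(rows), byrow = TRUE)
        Fm <- Fm / rowSums(Fm)
        # levels unobserved at encoding time keep membership 0
        lev <- colnames(fuzzy[[v]])
        full <- matrix(0, sum(miss), length(lev),
                       dimnames = list(NULL, lev))
        full[, ci$level[rows]] <- Fm
        fuzzy[[v]][miss, ] <- full
      }
    }

    cur <- extract_imputed(quant, fuzzy)
    change <- sum((cur - prev)^2) / max(sum(prev^2), .Machine$double.eps)
    prev <- cur
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("imputation did not converge in ", max_iter,
            " iterations (relative change ", format(change), ")")
  }
  finish_imputation(parts$ids, quant, fuzzy, quant_miss, fuzzy_miss,
                    parts$schema, iterations = iter, final_change = change,
                    converged = converged, ncp = ncp)
}

# Assemble the fa_imputation result object with hard categorical assignments.
finish_imputation <- function(ids, quant, fuzzy, quant_miss, fuzzy_miss,
                              schema, iterations, final_change, converged,
                              ncp) {
  completed <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (v in names(schema)) {
    if (schema[[v]]$type == "quantitative") {
      completed[[v]] <- quant[, v]
    } else {
      Y <- fuzzy[[v]]
      hard <- colnames(Y)[max.col(Y, ties.method = "first")]
      completed[[v]] <- factor(hard, levels = schema[[v]]$levels)
    }
  }
  structure(list(completed = completed, ids = ids, quant = quant,
                 fuzzy = fuzzy, quant_missing = quant_miss,
                 fuzzy_missing = fuzzy_miss, schema = schema,
                 iterations = iterations, final_change = final_change,
                 converged = converged, ncp = ncp),
            class = "fa_imputation")
}

#' @export
print.fa_imputation <- function(x, ...) {
  n_miss <- sum(x$quant_missing) +
    sum(vapply(x$fuzzy_missing, sum, integer(1)))
  cat("Regularised iterative FAMD imputation: ", n_miss,
      " missing cell(s), ncp = ", x$ncp, ", ", x$iterations,
      " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      " (final relative change ", format(x$final_change), ")\n", sep = "")
  invisible(x)
}
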