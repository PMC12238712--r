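# Factor analysis of mixed data (FAMD) from its weighted-SVD definition:
# quantitative columns standardised as in PCA, category indicator columns
# proportion-weighted as in MCA, one decomposition over both.

# Assemble the encoded matrix from a quantitative block and a list of fuzzy
# category membership matrices (rows sum to 1 per variable). Shared by the
# public encoder and the imputation loop, which feeds fuzzy memberships.
encode_parts <- function(quant, fuzzy) {
  n <- if (!is.null(quant)) nrow(quant) else nrow(fuzzy[[1]])
  blocks <- list(); info <- list()
  if (!is.null(quant) && ncol(quant) > 0) {
    for (j in seq_len(ncol(quant))) {
      x <- quant[, j]
      mu <- mean(x)
      s <- sqrt(mean((x - mu)^2))  # n-denominator sd
      if (s == 0) stop("quantitative variable '", colnames(quant)[j],
                       "' has zero variance", call. = FALSE)
      blocks[[length(blocks) + 1L]] <- (x - mu) / s
      info[[length(info) + 1L]] <- data.frame(
        column = colnames(quant)[j], variable = colnames(quant)[j],
        kind = "quantitative", level = NA_character_,
        center = mu, scale = s, prop = NA_real_, stringsAsFactors = FALSE)
    }
  }
  for (v in names(fuzzy)) {
    Y <- fuzzy[[v]]
    p <- colMeans(Y)
    observed <- p > 0
    if (sum(observed) < 2) {
      stop("categorical variable '", v, "' has fewer than 2 observed levels",
           call. = FALSE)
    }
    Y <- Y[, observed, drop = FALSE]
    p <- p[observed]
    for (k in seq_along(p)) {
      blocks[[length(blocks) + 1L]] <- (Y[, k] - p[k]) / sqrt(p[k])
      info[[length(info) + 1L]] <- data.frame(
        column = paste(v, colnames(Y)[k], sep = "="), variable = v,
        kind = "categorical", level = colnames(Y)[k],
        center = p[k], scale = sqrt(p[k]), prop = p[k],
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, blocks)
  info <- do.call(rbind, info)
  colnames(X) <- info$column
  n_quant <- sum(info$kind == "quantitative")
  cat_vars <- unique(info$variable[info$kind == "categorical"])
  total_inertia <- n_quant +
    sum(vapply(cat_vars,
               function(v) sum(info$variable == v) - 1, numeric(1)))
  structure(list(X = X, col_info = info, n = n,
                 row_weight = 1 / n, total_inertia = total_inertia),
            class = "fa_encoded")
}

# Split a complete covariate data frame into the quantitative block and hard
# (0/1) fuzzy membership matrices according to the schema.
split_mixed <- function(data, schema) {
  data <- as.data.frame(data)
  if ("individual_id" %in% names(data)) {
    ids <- as.character(data$individual_id)
    data$individual_id <- NULL
  } else {
    ids <- as.character(seq_len(nrow(data)))
  }
  if (is.null(schema)) schema <- infer_schema(data)
  quant_vars <- names(schema)[vapply(schema, function(e)
    e$type == "quantitative", logical(1))]
  cat_vars <- setdiff(names(schema), quant_vars)
  quant <- if (length(quant_vars) > 0) {
    as.matrix(data[quant_vars])
  } else NULL
  fuzzy <- lapply(cat_vars, function(v) {
    x <- factor(as.character(data[[v]]), levels = schema[[v]]$levels)
    Y <- matrix(0, nrow(data), nlevels(x),
                dimnames = list(NULL, levels(x)))
    idx <- !is.na(x)
    Y[cbind(which(idx), as.integer(x[idx]))] <- 1
    Y[!idx, ] <- NA
    Y
  })
  names(fuzzy) <- cat_vars
  list(ids = ids, quant = quant, fuzzy = fuzzy, schema = schema)
}

#' Encode a mixed covariate table for FAMD
#'
#' Quantitative columns are centred and scaled to unit variance (n
#' denominator). Each category indicator column is divided by the square root
#' of its proportion and centred, so a categorical variable with K observed
#' levels contributes K - 1 to the total inertia and a quantitative variable
#' contributes 1.
#'
#' @param data A complete (no missing cells) covariate data frame; an
#'   \code{individual_id} column is carried through as row identity.
#' @param schema Optional \code{fa_schema}; inferred from column classes when
#'   \code{NULL}.
#' @return An object of class \code{fa_encoded}: the encoded matrix \code{X},
#'   per-column metadata \code{col_info}, the row weight \code{1/n} and the
#'   \code{total_inertia}.
#' @export
encode_mixed <- function(data, schema = NULL) {
  parts <- split_mixed(data, schema)
  if (!is.null(parts$quant) && anyNA(parts$quant)) {
    stop("missing quantitative cells; impute first", call. = FALSE)
  }
  if (any(vapply(parts$fuzzy, anyNA, logical(1)))) {
    stop("missing categorical cells; impute first", call. = FALSE)
  }
  enc <- encode_parts(parts$quant, parts$fuzzy)
  rownames(enc$X) <- parts$ids
  enc
}

#' Fit FAMD by weighted singular value decomposition
#'
#' Decomposes the row-weighted encoded matrix \eqn{X / \sqrt{n}}; eigenvalues
#' are the squared singular values, individual coordinates have variance
#' equal to the eigenvalue of their dimension (n denominator), and column
#' contributions to a dimension sum to 100 percent. Each dimension's sign is
#' fixed so that its largest-magnitude column coordinate is positive.
#'
#' @param encoded An \code{fa_encoded} from [encode_mixed()].
#' @param ndim Number of dimensions to retain in the coordinate output
#'   (default 5, capped at the matrix rank for eigenvalue reporting).
#' @return An object of class \code{fa_famd}: \code{eigenvalues},
#'   \code{percent}, \code{cumulative}, \code{ind_coords} (n x ndim),
#'   \code{col_coords}, \code{contrib} (percent, columns x dims),
#'   \code{var_contrib} (percent, variables x dims), \code{sq_loadings},
#'   \code{col_info}, \code{total_inertia}, \code{rank}.
#' @export
famd_fit <- function(encoded, ndim = 5) {
  stopifnot(inherits(encoded, "fa_encoded"))
  n <- encoded$n
  S <- encoded$X / sqrt(n)
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (ndim > rank) {
    stop("ndim (", ndim, ") exceeds the matrix rank (", rank, ")",
         call. = FALSE)
  }
  d <- sv$d[seq_len(rank)]
  U <- sv$u[, seq_len(rank), drop = FALSE]
  V <- sv$v[, seq_len(rank), drop = FALSE]
  # sign convention: largest-|.| column coordinate positive per dimension
  for (l in seq_len(rank)) {
    g <- V[, l] * d[l]
    if (g[which.max(abs(g))] < 0) {
      V[, l] <- -V[, l]; U[, l] <- -U[, l]
    }
  }
  eig <- d^2
  percent <- 100 * eig / encoded$total_inertia
  keep <- seq_len(ndim)
  F_ind <- sqrt(n) * U[, keep, drop = FALSE] %*% diag(d[keep], ndim)
  G_col <- V[, keep, drop = FALSE] %*% diag(d[keep], ndim)
  contrib <- 100 * V[, keep, drop = FALSE]^2
  dimnames(F_ind) <- list(rownames(encoded$X), paste0("dim", keep))
  dimnames(G_col) <- list(encoded$col_info$column, paste0("dim", keep))
  dimnames(contrib) <- dimnames(G_col)
  var_contrib <- rowsum(contrib, group = encoded$col_info$variable)
  sq_loadings <- G_col^2
  structure(list(
    eigenvalues = eig, percent = percent, cumulative = cumsum(percent),
    ind_coords = F_ind, col_coords = G_col, contrib = contrib,
    var_contrib = var_contrib, sq_loadings = sq_loadings,
    col_info = encoded$col_info, total_inertia = encoded$total_inertia,
    rank = rank, ndim = ndim, n = n), class = "fa_famd")
}

#' Factor analysis of mixed data
#'
#' One-call wrapper: encodes a complete mixed table (or the fuzzy completed
#' table of an imputation result) and fits the weighted SVD.
#'
#' @param data A complete covariate data frame, or an \code{fa_imputation}
#'   from [impute_famd()] (its fuzzy categorical memberships are decomposed
#'   directly).
#' @param schema Optional \code{fa_schema}.
#' @param ndim Dimensions to retain (default 5).
#' @return An \code{fa_famd} model; see [famd_fit()].
#' @export
famd <- function(data, schema = NULL, ndim = 5) {
  if (inherits(data, "fa_imputation")) {
    enc <- encode_parts(data$quant, data$fuzzy)
    rownames(enc$X) <- data$ids
  } else {
    enc <- encode_mixed(data, schema)
  }
  famd_fit(enc, ndim = ndim)
}

#' @export
print.fa_famd <- function(x, ...) {
  cat("FAMD: ", x$n, " individuals, total inertia ",
      format(x$total_inertia), ", rank ", x$rank, "\n", sep = "")
  sp <- screeplot_data(x)
  print(utils::head(sp, max(x$ndim, 5)), row.names = FALSE, ...)
  invisible(x)
}

#' Scree data for dimension retention
#'
#' @param model An \code{fa_famd}.
#' @return A data frame with \code{dimension}, \code{eigenvalue},
#'   \code{percent} and monotone \code{cumulative} percent of total inertia.
#' @export
screeplot_data <- function(model) {
  stopifnot(inherits(model, "fa_famd"))
  data.frame(dimension = seq_along(model$eigenvalues),
             eigenvalue = model$eigenvalues,
             percent = model$percent,
             cumulative = model$cumulative)
}

#' Top contributing variables and categories for a dimension
#'
#' @param model An \code{fa_famd}.
#' @param dim Dimension index (within the fitted \code{ndim}).
#' @param k Number of entries to return (default 10).
#' @param by \code{"variable"} for variable-level contributions or
#'   \code{"column"} for per-column (per-category) contributions with the
#'   sign of association from the column coordinate.
#' @return A data frame ranked by descending contribution (ties broken by
#'   name for determinism).
#' @export
top_contributors <- function(model, dim, k = 10,
                             by = c("variable", "column")) {
  stopifnot(inherits(model, "fa_famd"))
  by <- match.arg(by)
  if (dim < 1 || dim > model$ndim) {
    stop("dim must be in 1..", model$ndim, call. = FALSE)
  }
  if (by == "variable") {
    tab <- data.frame(variable = rownames(model$var_contrib),
                      contribution = model$var_contrib[, dim],
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$contribution, tab$variable), ]
  } else {
    tab <- data.frame(column = rownames(model$contrib),
                      variable = model$col_info$variable,
                      kind = model$col_info$kind,
                      contribution = model$contrib[, dim],
                      coordinate = model$col_coords[, dim],
                      sign = ifelse(model$col_coords[, dim] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$contribution, tab$column), ]
  }
  rownames(tab) <- NULL
  utils::head(tab, k)
}
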