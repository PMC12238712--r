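# Composite fluctuating-asymmetry index: per-trait standardisation of
# unsigned asymmetries over the full sample, per-individual averaging over
# observed traits, z-standardisation of the composite, high-FA dichotomy.

#' Standardise one trait's unsigned asymmetries
#'
#' z-scores computed over every individual with the trait observed (the full
#' sample for that trait), pooling sexes, with the sample standard deviation
#' (n - 1 denominator).
#'
#' @param abs_d Numeric vector of unsigned asymmetries (\code{NA} = trait not
#'   observed; preserved in the output).
#' @return A numeric vector of z-scores, or \code{NULL} with a warning when
#'   the observed values have zero variance (the trait carries no asymmetry
#'   signal and is dropped).
#' @export
standardize_trait_asymmetry <- function(abs_d) {
  obs <- abs_d[!is.na(abs_d)]
  if (length(obs) < 2) {
    warning("trait has fewer than 2 observations; dropped")
    return(NULL)
  }
  s <- stats::sd(obs)
  if (s == 0) {
    warning("trait has zero asymmetry variance; dropped")
    return(NULL)
  }
  (abs_d - mean(obs)) / s
}

#' Minimum-trait inclusion threshold
#'
#' Half the maximum number of traits, rounded up: an individual must carry at
#' least this many traits for a stable composite index.
#'
#' @param n_traits Total number of retained traits (>= 1).
#' @return An integer threshold.
#' @export
min_trait_threshold <- function(n_traits) {
  stopifnot(n_traits >= 1)
  as.integer(ceiling(n_traits / 2))
}

#' High-FA dichotomy
#'
#' @param composite_z z-standardised composite FA values.
#' @param cutoff Threshold (default 1); the comparison is strict, so a value
#'   exactly at the cutoff is classed low/average.
#' @return Integer 0/1 vector: 1 = high FA.
#' @export
dichotomize <- function(composite_z, cutoff = 1.0) {
  stopifnot(all(is.finite(composite_z)))
  as.integer(composite_z > cutoff)
}

#' Composite FA index from per-trait z-scores
#'
#' Each individual's composite is the mean of their observed per-trait
#' standardised unsigned asymmetries (sum divided by the number of observed
#' traits). Individuals below the minimum-trait threshold are excluded, the
#' composite is then z-standardised over the included individuals, and the
#' high-FA indicator assigned.
#'
#' @param z_by_trait Numeric matrix, individuals x traits, of per-trait
#'   z-scores with \code{NA} for unobserved cells; rownames identify
#'   individuals.
#' @param min_traits Minimum observed traits for inclusion (default: the
#'   ceiling-half rule on the column count).
#' @param cutoff High-FA cutoff on the z scale (default 1).
#' @return A data frame of class \code{fa_index_result}: \code{individual_id},
#'   \code{n_observed_traits}, \code{composite_raw}, \code{composite_z},
#'   \code{high_fa}, \code{included}.
#' @export
composite_index <- function(z_by_trait,
                            min_traits = min_trait_threshold(ncol(z_by_trait)),
                            cutoff = 1.0) {
  stopifnot(is.matrix(z_by_trait))
  k <- rowSums(!is.na(z_by_trait))
  raw <- rowSums(z_by_trait, na.rm = TRUE) / k
  raw[k == 0] <- NA_real_
  included <- k >= min_traits
  if (!any(included)) {
    stop("no individual reaches the minimum trait count (", min_traits, ")",
         call. = FALSE)
  }
  z <- rep(NA_real_, length(raw))
  z[included] <- (raw[included] - mean(raw[included])) /
    stats::sd(raw[included])
  high <- rep(NA_integer_, length(raw))
  high[included] <- dichotomize(z[included], cutoff)
  res <- data.frame(
    individual_id = rownames(z_by_trait),
    n_observed_traits = as.integer(k),
    composite_raw = raw,
    composite_z = z,
    high_fa = high,
    included = included,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("fa_index_result", "data.frame")
  res
}

#' Build the composite FA index from a trait table
#'
#' Convenience wrapper: restricts to the retained traits, standardises each
#' trait's unsigned asymmetries over the full sample, and assembles the
#' composite index.
#'
#' @param tt A trait table (outlier-cleaned).
#' @param traits Character vector of retained trait ids (default: all traits
#'   present).
#' @param min_traits Inclusion threshold; default is the ceiling-half rule on
#'   the number of retained traits.
#' @param cutoff High-FA cutoff (default 1).
#' @return An \code{fa_index_result} (see [composite_index()]) with the sex of
#'   each individual attached as column \code{sex}.
#' @export
fa_index <- function(tt, traits = NULL, min_traits = NULL, cutoff = 1.0) {
  if (!is.null(traits)) tt <- tt[tt$trait_id %in% traits, , drop = FALSE]
  if (nrow(tt) == 0) stop("no measurements for the requested traits",
                          call. = FALSE)
  mat <- trait_matrix(tt, "abs_d")
  zs <- lapply(seq_len(ncol(mat)), function(j) {
    z <- withCallingHandlers(
      standardize_trait_asymmetry(mat[, j]),
      warning = function(w) {
        warning("trait '", colnames(mat)[j], "': ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
    z
  })
  keep <- !vapply(zs, is.null, logical(1))
  zmat <- do.call(cbind, zs[keep])
  colnames(zmat) <- colnames(mat)[keep]
  rownames(zmat) <- rownames(mat)
  if (is.null(min_traits)) min_traits <- min_trait_threshold(ncol(zmat))
  res <- composite_index(zmat, min_traits = min_traits, cutoff = cutoff)
  sex_by_id <- tt$sex[match(res$individual_id, tt$individual_id)]
  res$sex <- factor(as.character(sex_by_id), levels = c("F", "M"))
  res
}

#' @export
print.fa_index_result <- function(x, ...) {
  inc <- x$included
  cat("Composite FA index: ", nrow(x), " individuals, ", sum(inc),
      " included, ", sum(x$high_fa[inc] == 1L), " high-FA\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
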