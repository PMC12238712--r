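# End-to-end orchestration: simulate (or load) -> QC -> FA index ->
# imputation -> FAMD -> sex-stratified regression, with optional CSV
# artifacts and a reproducibility manifest.

#' Run the full FA analysis pipeline
#'
#' Executes the stages in order on a cohort: trait-table construction, the
#' pre-FA QC battery, outlier removal, composite FA index with the high-FA
#' dichotomy, covariate missingness report, regularised iterative FAMD
#' imputation, FAMD, and sex-stratified logistic regression of high FA on
#' the retained dimensions. A stage failure stops the run with the failing
#' stage named.
#'
#' @param cohort An \code{fa_cohort} from [generate_cohort()], or a list
#'   with elements \code{measurements} (validated measurement table) and
#'   \code{covariates} (\code{fa_covariates}).
#' @param qc_cfg A [qc_config()].
#' @param ndim FAMD dimensions retained for the regressions (default 4).
#' @param ncp Imputation components (default 5).
#' @param cutoff High-FA cutoff on the composite z scale (default 1).
#' @param min_traits Minimum observed traits for FA inclusion; default is the
#'   ceiling-half rule on the retained trait count.
#' @param out_dir Optional directory; when given, per-stage CSV artifacts and
#'   a manifest are written there.
#' @return A list of class \code{fa_pipeline}: \code{screen}, \code{fa},
#'   \code{missingness}, \code{imputation}, \code{famd}, \code{fits},
#'   \code{retained_traits}, \code{manifest}.
#' @export
run_pipeline <- function(cohort, qc_cfg = qc_config(), ndim = 4, ncp = 5,
                         cutoff = 1.0, min_traits = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tt <- stage("trait_table", trait_table(cohort$measurements, replicate = 1L))
  screen <- stage("qc", run_screen(tt, cohort$measurements, qc_cfg))
  retained <- screen$trait_id[screen$retained]
  if (length(retained) == 0) stop("pipeline stage 'qc' failed: no trait ",
                                  "survived the screen", call. = FALSE)
  tt_clean <- stage("outliers", remove_outliers(tt, screen))
  fa <- stage("fa_index",
              fa_index(tt_clean, traits = retained,
                       min_traits = min_traits, cutoff = cutoff))
  missing_rep <- stage("missingness",
                       missingness_report(cohort$covariates))
  imp <- stage("impute",
               impute_famd(cohort$covariates,
                           schema = attr(cohort$covariates, "schema"),
                           ncp = ncp))
  model <- stage("famd", famd(imp, ndim = ndim))
  fits <- stage("regress",
                sex_stratified_run(fa, model$ind_coords))

  manifest <- list(
    n_individuals = length(unique(cohort$measurements$individual_id)),
    n_traits_screened = nrow(screen),
    n_traits_retained = length(retained),
    min_traits = if (is.null(min_traits))
      min_trait_threshold(length(retained)) else min_traits,
    fa_cutoff = cutoff,
    n_included = sum(fa$included),
    n_high_fa = sum(fa$high_fa[fa$included] == 1L),
    famd_ndim = ndim, impute_ncp = ncp,
    impute_iterations = imp$iterations,
    seed = if (inherits(cohort, "fa_cohort")) cohort$seed else NA)
  res <- structure(list(screen = screen, fa = fa,
                        missingness = missing_rep, imputation = imp,
                        famd = model, fits = fits,
                        retained_traits = retained, manifest = manifest),
                   class = "fa_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

# Write per-stage CSV artifacts plus a manifest.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    as.data.frame(df), file.path(out_dir, name), row.names = FALSE)
  w(res$screen, "screen_report.csv")
  w(res$fa, "fa_index.csv")
  w(res$missingness, "missingness.csv")
  w(res$imputation$completed, "covariates_complete.csv")
  w(screeplot_data(res$famd), "scree.csv")
  ic <- data.frame(individual_id = rownames(res$famd$ind_coords),
                   res$famd$ind_coords)
  w(ic, "ind_coords.csv")
  w(data.frame(variable = rownames(res$famd$var_contrib),
               res$famd$var_contrib), "contributions.csv")
  w(res$fits$table, "regression.csv")
  man <- res$manifest
  writeLines(paste(names(man), vapply(man, function(v)
    paste(format(v), collapse = " "), character(1)), sep = ": "),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.fa_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("FA pipeline run\n",
      "  traits: ", m$n_traits_screened, " screened, ",
      m$n_traits_retained, " retained (min for inclusion: ",
      m$min_traits, ")\n",
      "  individuals: ", m$n_individuals, " measured, ", m$n_included,
      " included, ", m$n_high_fa, " high-FA\n",
      "  FAMD: ", m$famd_ndim, " dimensions; imputation ncp ",
      m$impute_ncp, " (", m$impute_iterations, " iterations)\n", sep = "")
  print(x$fits)
  invisible(x)
}
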