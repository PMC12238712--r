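# Synthetic cohort generator: bilateral measurements with FA / DA /
# antisymmetry / measurement-error components, mixed covariates driven by
# latent factors, and the ground truth needed for recovery tests.

#' Default mixed covariate specification
#'
#' Twenty-one early-life variables (6 quantitative, 15 categorical) emulating
#' a mid-century growth-study health-history battery: parental ages and
#' education, occupation and group-membership categories, pregnancy history,
#' gestational descriptors, infant feeding, illness history, and two
#' deciduous FA summary scores. Each variable carries a loading vector onto
#' the four latent factors (parental age; breastfeeding; socioeconomic
#' status; parental condition); variables with all-zero loadings are pure
#' noise. Category frequencies approximate the cohort being emulated (e.g.
#' ~42\% breastfed).
#'
#' @return A named list; each element has \code{type} ("quantitative" or
#'   "categorical"), \code{loadings} (length 4), and either \code{mean}/
#'   \code{sd} or \code{levels}/\code{freqs}.
#' @export
default_covariate_spec <- function() {
  q <- function(loadings, mean, sd)
    list(type = "quantitative", loadings = loadings, mean = mean, sd = sd)
  c_ <- function(loadings, levels, freqs)
    list(type = "categorical", loadings = loadings, levels = levels,
         freqs = freqs / sum(freqs))
  edu_levels <- c("lt_grade8", "some_high_school", "vocational",
                  "junior_matric", "senior_matric", "some_university",
                  "university")
  occ_levels <- c("business_finance", "sciences", "health", "education_law",
                  "arts_culture", "sales_service", "trades_transport",
                  "agriculture", "manufacturing")
  list(
    mother_age = q(c(1.2, 0, 0, 0), 28.9, 4.6),
    father_age = q(c(1.2, 0, 0, 0), 31.8, 5.4),
    mother_period_birth = c_(c(-1.0, 0, 0, 0),
                             c("prewar", "wwi", "roaring20s", "depression"),
                             c(0.09, 0.26, 0.63, 0.02)),
    mother_education = c_(c(0, 0, 1.1, 0.4), edu_levels,
                          c(0.18, 0.30, 0.14, 0.07, 0.12, 0.10, 0.07)),
    father_education = c_(c(0, 0, 1.1, 0.4), edu_levels,
                          c(0.20, 0.27, 0.11, 0.08, 0.09, 0.07, 0.15)),
    mother_group = c_(c(0, 0, 0, 0.8),
                      c("british_french", "irish", "other_european"),
                      c(0.73, 0.12, 0.12)),
    father_group = c_(c(0, 0, 0, 0.8),
                      c("british_french", "irish", "other_european"),
                      c(0.69, 0.15, 0.13)),
    father_occupation = c_(c(0, 0, 0.9, 0.5), occ_levels,
                           c(0.11, 0.10, 0.03, 0.04, 0.03, 0.28, 0.23,
                             0.06, 0.11)),
    prior_miscarriage = c_(c(0, 0, 0, 0), c("no", "yes"), c(0.78, 0.22)),
    parity = c_(c(0, 0, 0, 0),
                c("nulliparous", "primiparous", "multiparous"),
                c(0.27, 0.40, 0.33)),
    year_of_birth = q(c(0, 0, 0, 0.7), 1950.2, 1.0),
    season_birth = c_(c(0, 0, 0, 0),
                      c("winter", "spring", "summer", "fall"),
                      c(0.24, 0.29, 0.24, 0.23)),
    gestation_length = c_(c(0, 0, 0, 0), c("term", "early", "late"),
                          c(0.88, 0.06, 0.06)),
    birthweight_kg = q(c(0, 0, 0, -0.6), 3.36, 0.48),
    breastfed = c_(c(0, 1.2, 0, 0), c("no", "yes"), c(0.58, 0.42)),
    breastfed_duration = c_(c(0, 1.2, 0, 0),
                            c("none", "lt_1mo", "m1_2", "m2_6", "m6_plus"),
                            c(0.57, 0.08, 0.11, 0.10, 0.14)),
    formula_type = c_(c(0, -1.0, 0, 0),
                      c("none_breastfed", "homemade", "manufactured"),
                      c(0.11, 0.74, 0.15)),
    sick_before_1 = c_(c(0, 0, 0, 0), c("no", "yes"), c(0.92, 0.08)),
    sick_before_3 = c_(c(0, 0, 0, 0), c("no", "yes"), c(0.46, 0.54)),
    fa_dmdbl = q(c(0, 0, 0, -0.8), 0, 1),
    fa_gest = q(c(0, 0, 0, -0.8), 0, 1))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults reproduce the structure of the cohort being emulated: 303
#' individuals (149 F, 154 M), 20 bilateral traits with mean sizes in the
#' 2-7 mm intercuspal range measured once (a 30-cast subset twice), four
#' latent factors driving 21 mixed covariates, female-only negative effects
#' of factors 2 and 4 on the log developmental-instability scale, under 5\%
#' covariate missingness, and measurement-cell missingness whose
#' two-component mixture gives a mean of about 17.8 observed traits with
#' roughly 2\% of individuals below the 10-trait inclusion threshold.
#'
#' @param n_female,n_male Sex counts (defaults 149 / 154).
#' @param n_traits Number of bilateral traits (default 20).
#' @param trait_size Mean trait sizes in mm (default evenly spaced 2-7).
#' @param sigma_t Per-trait FA standard deviation in mm (default evenly
#'   spaced 0.06-0.14).
#' @param sigma_size Between-individual trait-size sd in mm (default 0.25).
#' @param sigma_me Replicate measurement-error sd in mm (default 0.03).
#' @param replicate_subset Number of individuals measured twice (default 30).
#' @param n_latent Latent factor count (default 4).
#' @param covariate_spec Covariate specification (default
#'   [default_covariate_spec()]).
#' @param beta_female,beta_male Length-\code{n_latent} coefficient vectors on
#'   the log instability scale (defaults: female c(0, -0.25, 0, -0.30); male
#'   zeros).
#' @param covariate_mcar Per-variable MCAR rate for covariates (default
#'   0.03).
#' @param obs_prob_main Per-cell trait observation probability for typical
#'   individuals (default 0.905).
#' @param sparse_frac Fraction of sparsely-cast individuals (default 0.03).
#' @param sparse_range Observation-probability range for sparse individuals
#'   (default c(0.15, 0.65)).
#' @param da_shift Named or full-length vector of directional-asymmetry mean
#'   shifts in mm (default 0).
#' @param antisym_mode Named or full-length vector of antisymmetry mode
#'   separations in mm (0 = no antisymmetry).
#' @param trait_me_sd Per-trait measurement-error sd override (default
#'   \code{sigma_me} everywhere).
#' @param size_dep_gamma Per-trait exponent tying asymmetry sd to individual
#'   trait size (default 0 = none).
#' @param trait_presence Per-trait observation-probability multiplier
#'   (default 1; small values emulate rarely expressed traits).
#' @return A validated list of class \code{fa_sim_config}.
#' @export
sim_config <- function(n_female = 149, n_male = 154, n_traits = 20,
                       trait_size = NULL, sigma_t = NULL, sigma_size = 0.25,
                       sigma_me = 0.03, replicate_subset = 30, n_latent = 4,
                       covariate_spec = default_covariate_spec(),
                       beta_female = c(0, -0.25, 0, -0.30),
                       beta_male = rep(0, 4),
                       covariate_mcar = 0.03,
                       obs_prob_main = 0.905, sparse_frac = 0.03,
                       sparse_range = c(0.15, 0.65),
                       da_shift = NULL, antisym_mode = NULL,
                       trait_me_sd = NULL, size_dep_gamma = NULL,
                       trait_presence = NULL) {
  traits <- sprintf("T%02d", seq_len(n_traits))
  expand <- function(x, default) {
    full <- stats::setNames(rep(default, n_traits), traits)
    if (!is.null(x)) {
      if (!is.null(names(x))) full[names(x)] <- x
      else { stopifnot(length(x) == n_traits); full[] <- x }
    }
    full
  }
  if (is.null(trait_size)) trait_size <- seq(2, 7, length.out = n_traits)
  if (is.null(sigma_t)) sigma_t <- seq(0.06, 0.14, length.out = n_traits)
  trait_size <- expand(trait_size, NA_real_)
  sigma_t <- expand(sigma_t, NA_real_)
  cfg <- list(
    n_female = n_female, n_male = n_male,
    n_individuals = n_female + n_male,
    n_traits = n_traits, traits = traits,
    trait_size = trait_size, sigma_t = sigma_t, sigma_size = sigma_size,
    sigma_me = sigma_me, replicate_subset = replicate_subset,
    n_latent = n_latent, covariate_spec = covariate_spec,
    beta_female = beta_female, beta_male = beta_male,
    covariate_mcar = covariate_mcar,
    obs_prob_main = obs_prob_main, sparse_frac = sparse_frac,
    sparse_range = sparse_range,
    da_shift = expand(da_shift, 0),
    antisym_mode = expand(antisym_mode, 0),
    trait_me_sd = expand(trait_me_sd, sigma_me),
    size_dep_gamma = expand(size_dep_gamma, 0),
    trait_presence = expand(trait_presence, 1))
  validate_sim_config(cfg)
  structure(cfg, class = "fa_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_female > 0, cfg$n_male > 0, cfg$n_traits >= 1,
            all(cfg$trait_size > 0), all(cfg$sigma_t > 0),
            cfg$sigma_size > 0, cfg$sigma_me > 0,
            cfg$replicate_subset >= 0,
            cfg$replicate_subset <= cfg$n_individuals,
            cfg$n_latent >= 1,
            length(cfg$beta_female) == cfg$n_latent,
            length(cfg$beta_male) == cfg$n_latent,
            cfg$covariate_mcar >= 0, cfg$covariate_mcar <= 1,
            cfg$obs_prob_main >= 0, cfg$obs_prob_main <= 1,
            cfg$sparse_frac >= 0, cfg$sparse_frac <= 1,
            all(cfg$sparse_range >= 0), all(cfg$sparse_range <= 1),
            all(cfg$trait_me_sd > 0),
            all(cfg$trait_presence >= 0), all(cfg$trait_presence <= 1))
  for (v in names(cfg$covariate_spec)) {
    sp <- cfg$covariate_spec[[v]]
    if (length(sp$loadings) != cfg$n_latent) {
      stop("covariate '", v, "' loading vector length != n_latent",
           call. = FALSE)
    }
    if (sp$type == "categorical" &&
        (length(sp$levels) != length(sp$freqs) || any(sp$freqs <= 0))) {
      stop("covariate '", v, "' has inconsistent levels/freqs",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Inject a targeted assumption violation into a simulation config
#'
#' Amends the configuration so that the generator's output for the chosen
#' traits violates exactly one assumption the QC battery screens for.
#'
#' @param config An \code{fa_sim_config}.
#' @param kind One of \code{"measurement_error"} (replicate error sd set to
#'   \code{magnitude} x the trait's FA sd), \code{"DA"} (mean signed
#'   asymmetry shifted by \code{magnitude} mm), \code{"antisymmetry"}
#'   (signed asymmetry becomes a symmetric two-mode mixture with modes at
#'   +/- \code{magnitude} mm), or \code{"size_dependence"} (asymmetry sd
#'   scales with individual size to the power \code{magnitude}).
#' @param traits Trait ids to affect.
#' @param magnitude Strength of the injection (units per \code{kind}).
#' @return The amended config.
#' @export
inject_pathology <- function(config, kind, traits, magnitude) {
  stopifnot(inherits(config, "fa_sim_config"))
  unknown <- setdiff(traits, config$traits)
  if (length(unknown) > 0) {
    stop("unknown trait(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  switch(kind,
    measurement_error = {
      config$trait_me_sd[traits] <- magnitude * config$sigma_t[traits]
    },
    DA = { config$da_shift[traits] <- config$da_shift[traits] + magnitude },
    antisymmetry = { config$antisym_mode[traits] <- magnitude },
    size_dependence = { config$size_dep_gamma[traits] <- magnitude },
    stop("unknown pathology kind: ", kind, call. = FALSE))
  validate_sim_config(config)
  config
}

# Draw one covariate column from the latent scores.
draw_covariate <- function(sp, z) {
  n <- nrow(z)
  u <- as.vector(z %*% sp$loadings) + stats::rnorm(n)
  u <- u / sqrt(sum(sp$loadings^2) + 1)   # standardise the latent index
  if (sp$type == "quantitative") {
    sp$mean + sp$sd * u
  } else {
    cuts <- stats::qnorm(cumsum(sp$freqs))
    cuts[length(cuts)] <- Inf
    lev <- sp$levels[findInterval(u, c(-Inf, utils::head(cuts, -1)))]
    factor(lev, levels = sp$levels)
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws latent factor scores, builds the mixed covariates from them, sets
#' each individual's developmental-instability scale
#' \eqn{s_i = \exp(\sum_d \beta_{d,sex} z_{id})}, draws per-trait signed
#' asymmetries \eqn{d \sim N(\mathrm{DA}_t, (\sigma_t s_i)^2)} (or a
#' symmetric two-mode mixture for antisymmetry-injected traits), splits them
#' into sides around an individual trait size, adds replicate-2
#' re-measurement error for the designated subset, and applies the
#' missingness masks. Fully deterministic under \code{seed}.
#'
#' @param config An \code{fa_sim_config}.
#' @param seed Integer seed.
#' @return A list of class \code{fa_cohort}: \code{measurements} (validated
#'   long table), \code{covariates} (\code{fa_covariates} with missing
#'   cells), \code{truth} (latent scores \code{z}, instability scale
#'   \code{s}, sexes, injected betas, pre-missingness covariates, replicate
#'   subset ids, per-trait pathology settings) and \code{config}.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "fa_sim_config"))
  set.seed(seed)
  n <- config$n_individuals
  ids <- sprintf("I%04d", seq_len(n))
  sex <- sample(c(rep("F", config$n_female), rep("M", config$n_male)))

  # latent factors and covariates
  z <- matrix(stats::rnorm(n * config$n_latent), n, config$n_latent,
              dimnames = list(ids, paste0("z", seq_len(config$n_latent))))
  cov_full <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (v in names(config$covariate_spec)) {
    cov_full[[v]] <- draw_covariate(config$covariate_spec[[v]], z)
  }

  # instability scale and signed asymmetries
  beta <- cbind(F = config$beta_female, M = config$beta_male)
  s <- exp(rowSums(z * t(beta[, sex])))
  traits <- config$traits
  nt <- config$n_traits
  T_it <- matrix(stats::rnorm(n * nt,
                              mean = rep(config$trait_size, each = n),
                              sd = config$sigma_size), n, nt,
                 dimnames = list(ids, traits))
  sd_it <- outer(s, config$sigma_t)
  gam <- rep(config$size_dep_gamma, each = n)
  sd_it <- sd_it * (pmax(T_it, 0.1) /
                      rep(config$trait_size, each = n))^gam
  d_it <- matrix(stats::rnorm(n * nt,
                              mean = rep(config$da_shift, each = n),
                              sd = sd_it), n, nt,
                 dimnames = list(ids, traits))
  anti <- which(config$antisym_mode > 0)
  for (t in anti) {
    mode_sign <- sample(c(-1, 1), n, replace = TRUE)
    d_it[, t] <- mode_sign * config$antisym_mode[t] +
      stats::rnorm(n, 0, config$sigma_t[t] * s)
  }
  L <- T_it - d_it / 2
  R <- T_it + d_it / 2

  # missingness: two-component observation-probability mixture x per-trait
  # presence multiplier; a missing cell drops both sides
  sparse <- stats::runif(n) < config$sparse_frac
  p_obs <- ifelse(sparse,
                  stats::runif(n, config$sparse_range[1],
                               config$sparse_range[2]),
                  config$obs_prob_main)
  observed <- matrix(stats::runif(n * nt), n, nt) <
    (p_obs %o% config$trait_presence[traits])

  # replicate-2 re-measurement error for the designated subset
  rep_ids <- sample(ids, config$replicate_subset)
  in_rep <- ids %in% rep_ids
  me_sd <- config$trait_me_sd[traits]
  L2 <- L + matrix(stats::rnorm(n * nt, 0, rep(me_sd, each = n)), n, nt)
  R2 <- R + matrix(stats::rnorm(n * nt, 0, rep(me_sd, each = n)), n, nt)

  idx <- which(observed, arr.ind = TRUE)
  base <- data.frame(
    individual_id = ids[idx[, 1]],
    sex = sex[idx[, 1]],
    trait_id = traits[idx[, 2]],
    stringsAsFactors = FALSE)
  meas <- rbind(
    cbind(base, side = "L", replicate = 1L, value_mm = L[idx]),
    cbind(base, side = "R", replicate = 1L, value_mm = R[idx]))
  rep_rows <- in_rep[idx[, 1]]
  if (any(rep_rows)) {
    meas <- rbind(meas,
      cbind(base[rep_rows, ], side = "L", replicate = 2L,
            value_mm = L2[idx][rep_rows]),
      cbind(base[rep_rows, ], side = "R", replicate = 2L,
            value_mm = R2[idx][rep_rows]))
  }
  meas <- validate_measurements(meas)

  # covariate MCAR
  cov_obs <- cov_full
  for (v in names(config$covariate_spec)) {
    mask <- stats::runif(n) < config$covariate_mcar
    cov_obs[[v]][mask] <- NA
  }
  schema <- infer_schema_from_spec(config$covariate_spec)
  cov_obs <- validate_covariates(cov_obs, schema)

  truth <- list(z = z, s = s, sex = stats::setNames(sex, ids),
                beta = beta, covariates_full = cov_full,
                replicate_ids = rep_ids,
                pathology = list(da_shift = config$da_shift,
                                 antisym_mode = config$antisym_mode,
                                 trait_me_sd = config$trait_me_sd,
                                 size_dep_gamma = config$size_dep_gamma,
                                 trait_presence = config$trait_presence))
  structure(list(measurements = meas, covariates = cov_obs, truth = truth,
                 config = config, seed = seed), class = "fa_cohort")
}

# Schema implied by a covariate specification.
infer_schema_from_spec <- function(spec) {
  schema <- lapply(spec, function(sp) {
    if (sp$type == "quantitative") list(type = "quantitative", levels = NULL)
    else list(type = "categorical", levels = sp$levels)
  })
  structure(schema, class = "fa_schema")
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$config$n_individuals, " individuals (",
      x$config$n_female, " F, ", x$config$n_male, " M), ",
      x$config$n_traits, " bilateral traits, seed ", x$seed, "\n", sep = "")
  cat(nrow(x$measurements), " measurement rows; ",
      sum(vapply(as.data.frame(x$covariates)[-1],
                 function(c) sum(is.na(c)), integer(1))),
      " missing covariate cells\n", sep = "")
  invisible(x)
}

#' Align FAMD dimensions with the generator's latent factors
#'
#' Recovery-test utility: matches each true latent factor to the estimated
#' dimension with the largest absolute correlation (greedily, without
#' replacement) and returns sign-aligned scores so that injected coefficient
#' signs are comparable across seeds despite the SVD's sign and order
#' indeterminacy.
#'
#' @param coords FAMD individual coordinates (rownames = individual ids).
#' @param z True latent scores (rownames = individual ids).
#' @return A list with \code{aligned} (matrix, one column per true factor,
#'   sign-corrected) and \code{map} (data frame: factor, dim, sign,
#'   correlation).
#' @export
align_dims_to_truth <- function(coords, z) {
  common <- intersect(rownames(coords), rownames(z))
  Cm <- stats::cor(z[common, , drop = FALSE], coords[common, , drop = FALSE])
  n_f <- nrow(Cm)
  map <- data.frame(factor = seq_len(n_f), dim = NA_integer_,
                    sign = NA_real_, correlation = NA_real_)
  avail <- seq_len(ncol(Cm))
  for (f in order(-apply(abs(Cm), 1, max))) {
    j <- avail[which.max(abs(Cm[f, avail]))]
    map$dim[f] <- j
    map$sign[f] <- sign(Cm[f, j])
    map$correlation[f] <- Cm[f, j]
    avail <- setdiff(avail, j)
    if (length(avail) == 0) break
  }
  aligned <- sweep(coords[, map$dim, drop = FALSE], 2, map$sign, "*")
  colnames(aligned) <- paste0("factor", map$factor)
  list(aligned = aligned, map = map)
}
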