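# Required columns of a bilateral measurement table, in canonical order.
MEASUREMENT_COLUMNS <- c("individual_id", "sex", "trait_id", "side",
                         "replicate", "value_mm")

#' Validate a bilateral measurement table
#'
#' Checks the invariants of the long-format measurement layout: one row per
#' (individual, trait, side, replicate) key, strictly positive values in mm,
#' sides restricted to \code{L}/\code{R}, replicate numbers at least 1, and a
#' single sex per individual.
#'
#' @param m A data frame with columns \code{individual_id}, \code{sex},
#'   \code{trait_id}, \code{side}, \code{replicate}, \code{value_mm}.
#' @return The validated table, invisibly, with \code{sex} and \code{side}
#'   normalised to factors and class \code{fa_measurements} attached.
#' @export
validate_measurements <- function(m) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(m))
  if (length(missing_cols) > 0) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.data.frame(m)[MEASUREMENT_COLUMNS]
  m$individual_id <- as.character(m$individual_id)
  m$trait_id <- as.character(m$trait_id)
  m$replicate <- as.integer(m$replicate)
  m$value_mm <- as.numeric(m$value_mm)

  bad_side <- !m$side %in% c("L", "R")
  if (any(bad_side)) {
    stop("invalid side value(s) at row(s): ",
         paste(utils::head(which(bad_side), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- !m$sex %in% c("F", "M")
  if (any(bad_sex)) {
    stop("invalid sex value(s) at row(s): ",
         paste(utils::head(which(bad_sex), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_value <- !is.finite(m$value_mm) | m$value_mm <= 0
  if (any(bad_value)) {
    stop("non-positive or non-finite value_mm at row(s): ",
         paste(utils::head(which(bad_value), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_rep <- is.na(m$replicate) | m$replicate < 1L
  if (any(bad_rep)) {
    stop("replicate must be a positive integer; offending row(s): ",
         paste(utils::head(which(bad_rep), 10), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(m$individual_id, m$trait_id, m$side, m$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (individual_id, trait_id, side, replicate) key(s) at ",
         "row(s): ", paste(utils::head(which(dup), 10), collapse = ", "),
         call. = FALSE)
  }
  sex_per_id <- tapply(as.character(m$sex), m$individual_id,
                       function(s) length(unique(s)))
  if (any(sex_per_id > 1)) {
    stop("sex is not constant within individual(s): ",
         paste(names(sex_per_id)[sex_per_id > 1], collapse = ", "),
         call. = FALSE)
  }
  m$sex <- factor(as.character(m$sex), levels = c("F", "M"))
  m$side <- factor(as.character(m$side), levels = c("L", "R"))
  class(m) <- c("fa_measurements", "data.frame")
  invisible(m)
}

#' Read a bilateral measurement table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing
#' \code{individual_id}, \code{sex}, \code{trait_id}, \code{side},
#' \code{replicate}, \code{value_mm}.
#'
#' @param path Path to the CSV file.
#' @return A validated measurement table (see [validate_measurements()]).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(individual_id = "character",
                                      sex = "character",
                                      trait_id = "character",
                                      side = "character"),
                       fileEncoding = "UTF-8")
  validate_measurements(m)
}

#' Write a measurement table to CSV
#'
#' @param m A measurement table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Declare a mixed covariate schema
#'
#' A schema maps every covariate column to a declared type. Quantitative
#' variables are real-valued; categorical variables carry a finite level set.
#'
#' @param ... Named entries, each either the string \code{"quantitative"} or a
#'   character vector of category levels (declaring a categorical variable).
#' @return An object of class \code{fa_schema}: a named list with elements
#'   \code{type} and \code{levels} per variable.
#' @export
covariate_schema <- function(...) {
  entries <- list(...)
  if (length(entries) == 0 || is.null(names(entries)) ||
      any(names(entries) == "")) {
    stop("every schema entry must be named", call. = FALSE)
  }
  schema <- lapply(entries, function(e) {
    if (identical(e, "quantitative")) {
      list(type = "quantitative", levels = NULL)
    } else if (is.character(e) && length(e) >= 2) {
      list(type = "categorical", levels = e)
    } else {
      stop("schema entries must be \"quantitative\" or a vector of >= 2 ",
           "levels", call. = FALSE)
    }
  })
  structure(schema, class = "fa_schema")
}

#' Infer a covariate schema from column classes
#'
#' Numeric columns become quantitative; character and factor columns become
#' categorical with their observed levels.
#'
#' @param covariates A covariate data frame (an \code{individual_id} column is
#'   ignored).
#' @return An \code{fa_schema}.
#' @export
infer_schema <- function(covariates) {
  vars <- setdiff(names(covariates), "individual_id")
  schema <- lapply(vars, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      list(type = "quantitative", levels = NULL)
    } else {
      lev <- if (is.factor(x)) levels(x) else sort(unique(stats::na.omit(as.character(x))))
      list(type = "categorical", levels = lev)
    }
  })
  names(schema) <- vars
  structure(schema, class = "fa_schema")
}

#' Read a covariate schema from a YAML file
#'
#' The file maps each variable name to \code{type: quantitative} or
#' \code{type: categorical} with a \code{levels} list.
#'
#' @param path Path to the YAML file.
#' @return An \code{fa_schema}.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- lapply(raw, function(e) {
    if (identical(e$type, "quantitative")) {
      list(type = "quantitative", levels = NULL)
    } else if (identical(e$type, "categorical")) {
      list(type = "categorical", levels = as.character(e$levels))
    } else {
      stop("schema type must be 'quantitative' or 'categorical'",
           call. = FALSE)
    }
  })
  structure(schema, class = "fa_schema")
}

#' Read a covariate table from CSV
#'
#' One row per individual; empty strings and \code{NA} are treated as missing.
#' When a schema is supplied the columns are coerced and checked against it;
#' otherwise a schema is inferred from the column classes.
#'
#' @param path Path to the CSV file.
#' @param schema Optional \code{fa_schema}.
#' @return A data frame of class \code{fa_covariates} with attribute
#'   \code{schema}.
#' @export
read_covariates <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cov <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  validate_covariates(cov, schema)
}

#' Validate a covariate table against a schema
#'
#' @param cov Covariate data frame with an \code{individual_id} column.
#' @param schema Optional \code{fa_schema}; inferred when \code{NULL}.
#' @return The table with categorical columns coerced to factors at the
#'   declared levels, class \code{fa_covariates}, and the schema attached as
#'   attribute \code{schema}.
#' @export
validate_covariates <- function(cov, schema = NULL) {
  if (!"individual_id" %in% names(cov)) {
    stop("covariate table must have an individual_id column", call. = FALSE)
  }
  cov <- as.data.frame(cov)
  cov$individual_id <- as.character(cov$individual_id)
  if (anyDuplicated(cov$individual_id)) {
    stop("covariate table must have one row per individual", call. = FALSE)
  }
  if (is.null(schema)) schema <- infer_schema(cov)
  vars <- names(schema)
  missing_vars <- setdiff(vars, names(cov))
  if (length(missing_vars) > 0) {
    stop("covariate table is missing declared variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  undeclared <- setdiff(names(cov), c("individual_id", vars))
  if (length(undeclared) > 0) {
    stop("undeclared covariate column(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  for (v in vars) {
    if (schema[[v]]$type == "quantitative") {
      cov[[v]] <- as.numeric(cov[[v]])
    } else {
      x <- as.character(cov[[v]])
      bad <- !is.na(x) & !x %in% schema[[v]]$levels
      if (any(bad)) {
        stop("variable '", v, "' has value(s) outside its declared levels: ",
             paste(unique(x[bad]), collapse = ", "), call. = FALSE)
      }
      cov[[v]] <- factor(x, levels = schema[[v]]$levels)
    }
  }
  cov <- cov[c("individual_id", vars)]
  attr(cov, "schema") <- schema
  class(cov) <- c("fa_covariates", "data.frame")
  cov
}

#' Write a covariate table to CSV
#'
#' Missing cells are written as empty strings.
#'
#' @param cov Covariate table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_covariates <- function(cov, path) {
  utils::write.csv(as.data.frame(cov), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-trait signed asymmetry table
#'
#' Computes, for every individual x trait with both sides present at the
#' requested replicate, the signed difference \eqn{d = R - L}, the unsigned
#' asymmetry \eqn{|R - L|} and the trait size \eqn{(R + L)/2}, all in mm.
#' Cells where either side is missing are absent from the output, never zero.
#'
#' @param m A validated measurement table.
#' @param replicate Which replicate to use (default 1, the analysis
#'   measurement; replicate 2 is the re-measurement subset).
#' @return A data frame of class \code{fa_trait_table} with columns
#'   \code{individual_id}, \code{sex}, \code{trait_id}, \code{d},
#'   \code{abs_d}, \code{size}.
#' @export
trait_table <- function(m, replicate = 1L) {
  m <- validate_measurements(m)
  mr <- m[m$replicate == as.integer(replicate), , drop = FALSE]
  if (nrow(mr) == 0) {
    stop("replicate ", replicate, " is absent from the measurement table",
         call. = FALSE)
  }
  left <- mr[mr$side == "L", c("individual_id", "sex", "trait_id", "value_mm")]
  right <- mr[mr$side == "R", c("individual_id", "trait_id", "value_mm")]
  names(left)[names(left) == "value_mm"] <- "L"
  names(right)[names(right) == "value_mm"] <- "R"
  tt <- merge(left, right, by = c("individual_id", "trait_id"))
  if (nrow(tt) == 0) {
    stop("no individual x trait cell has both sides at replicate ", replicate,
         call. = FALSE)
  }
  tt$d <- tt$R - tt$L
  tt$abs_d <- abs(tt$d)
  tt$size <- (tt$R + tt$L) / 2
  tt <- tt[order(tt$trait_id, tt$individual_id),
           c("individual_id", "sex", "trait_id", "d", "abs_d", "size")]
  rownames(tt) <- NULL
  class(tt) <- c("fa_trait_table", "data.frame")
  tt
}

#' Wide individual-by-trait matrix from a trait table
#'
#' @param tt An \code{fa_trait_table}.
#' @param value Which column to spread: \code{"abs_d"}, \code{"d"} or
#'   \code{"size"}.
#' @return A numeric matrix, individuals in rows (named), traits in columns
#'   (named); missing cells are \code{NA}.
#' @export
trait_matrix <- function(tt, value = c("abs_d", "d", "size")) {
  value <- match.arg(value)
  ids <- sort(unique(tt$individual_id))
  traits <- sort(unique(tt$trait_id))
  mat <- matrix(NA_real_, length(ids), length(traits),
                dimnames = list(ids, traits))
  mat[cbind(match(tt$individual_id, ids), match(tt$trait_id, traits))] <-
    tt[[value]]
  mat
}
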