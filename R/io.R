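## File plumbing: CSV readers/writers with schema checks, run configuration,
## and a minimal leveled logger.  All tables use a header row; ids are kept
## as opaque strings throughout.

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

telo_log <- function(level, ...) {
  thr <- getOption("telotraj.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

read_csv_checked <- function(path, required, label) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(label, " file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  d
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a phenotype table
#'
#' Expected header columns: \code{animal_id}, \code{age_months},
#' \code{log_rltl} (or \code{raw_rltl}, which is natural-log transformed on
#' the way in), \code{birth_year}, \code{genetic_group}, \code{plate},
#' \code{row}.  Extra columns (candidate covariates for backward
#' elimination) are kept verbatim.  Rows with a missing/unparseable
#' mandatory field are dropped; the dropped rows and their reasons are
#' attached as attribute \code{"dropped"} and a count is logged.
#'
#' @param path CSV path.
#' @return Data frame of typed phenotype records; attribute \code{"dropped"}
#'   holds the rejected rows with a \code{reason} column.
#' @export
read_phenotypes <- function(path) {
  base <- c("animal_id", "age_months", "birth_year", "genetic_group",
            "plate", "row")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  has_log <- "log_rltl" %in% names(d)
  has_raw <- "raw_rltl" %in% names(d)
  need <- c(base, if (!has_log && !has_raw) "log_rltl")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("phenotype file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))

  d$age_months <- num_or_na(d$age_months)
  if (has_log) d$log_rltl <- num_or_na(d$log_rltl)
  if (has_raw) d$raw_rltl <- num_or_na(d$raw_rltl)
  if (!has_log) {
    if (any(!is.na(d$raw_rltl) & d$raw_rltl <= 0))
      stop("raw_rltl must be > 0 to log-transform")
    d$log_rltl <- log(d$raw_rltl)
  }

  reason <- rep(NA_character_, nrow(d))
  flag <- function(cond, code) {
    reason[cond & is.na(reason)] <<- code
  }
  flag(is.na(d$age_months), "bad_age")
  flag(is.na(d$log_rltl), "bad_rltl")
  for (cc in c("animal_id", "birth_year", "genetic_group", "plate", "row"))
    flag(is.na(d[[cc]]) | d[[cc]] == "", paste0("missing_", cc))

  keep <- is.na(reason)
  dropped <- cbind(d[!keep, , drop = FALSE],
                   reason = reason[!keep])
  if (nrow(dropped))
    telo_log("warn", nrow(dropped), " phenotype row(s) dropped (",
             paste(unique(dropped$reason), collapse = ", "), ")")
  if (!any(keep)) telo_log("warn", "phenotype file has no usable rows")
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame as returned by \code{read_phenotypes}.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a qPCR plate table
#'
#' Columns: \code{sample_id, animal_id, plate_id, row_id, cq_tel, cq_b2m,
#' e_tel, e_b2m, is_calibrator} (calibrator flag as 0/1 or TRUE/FALSE).
#'
#' @param path CSV path.
#' @return Data frame of plate records.
#' @export
read_plates <- function(path) {
  d <- read_csv_checked(path, c("sample_id", "animal_id", "plate_id",
                                "row_id", "cq_tel", "cq_b2m", "e_tel",
                                "e_b2m", "is_calibrator"), "plate")
  for (cc in c("cq_tel", "cq_b2m", "e_tel", "e_b2m")) {
    d[[cc]] <- num_or_na(d[[cc]])
    if (anyNA(d[[cc]])) stop("non-numeric values in plate column ", cc)
  }
  d$is_calibrator <- d$is_calibrator %in% c("1", "TRUE", "true", "T")
  d
}

#' @rdname read_plates
#' @param plates Data frame of plate records.
#' @export
write_plates <- function(plates, path) {
  plates$is_calibrator <- as.integer(plates$is_calibrator)
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a survival table
#'
#' Columns: \code{animal_id, time_days, event} (1 = culling observed, 0 =
#' right-censored at the maximal known survival time) and optionally
#' \code{cluster}.
#'
#' @param path CSV path.
#' @return Data frame of survival records.
#' @export
read_survival <- function(path) {
  d <- read_csv_checked(path, c("animal_id", "time_days", "event"),
                        "survival")
  d$time_days <- num_or_na(d$time_days)
  if (anyNA(d$time_days)) stop("non-numeric time_days in ", path)
  d$event <- as.integer(d$event)
  if (anyDuplicated(d$animal_id))
    stop("survival table has duplicate animal_id(s)")
  if (any(d$time_days <= 0)) stop("survival times must be > 0")
  d
}

#' @rdname read_survival
#' @param survival_table Data frame of survival records.
#' @export
write_survival <- function(survival_table, path) {
  utils::write.csv(survival_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline.  Defaults follow the final model
#' of the underlying study design: quadratic Legendre polynomials for both
#' the fixed and the random (genetic) age regression, homogeneous residual
#' variance, five profile clusters.
#'
#' @param polynomial_order_fixed,polynomial_order_random Non-negative
#'   integers, at most 5.
#' @param age_bounds Numeric \code{c(t_min, t_max)} in months, or
#'   \code{"from-data"} to take the observed range.
#' @param residual_classes \code{"homogeneous"} or a numeric vector of cut
#'   points (months) splitting the age range into left-closed intervals,
#'   e.g. \code{c(24)} for young/old.
#' @param n_clusters Number of profile shape clusters (default 5).
#' @param n_animals Number of phenotyped animals the simulator generates.
#' @param seed Integer seed governing every stochastic stage.
#' @param reml_tol_loglik,reml_tol_param REML convergence tolerances
#'   (absolute restricted log-likelihood change; max relative parameter
#'   change).
#' @param max_iter Maximum REML iterations.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(polynomial_order_fixed = 2L,
                       polynomial_order_random = 2L,
                       age_bounds = "from-data",
                       residual_classes = "homogeneous",
                       n_clusters = 5L,
                       n_animals = 308L,
                       seed = 1L,
                       reml_tol_loglik = 1e-8,
                       reml_tol_param = 1e-6,
                       max_iter = 100L) {
  for (o in c(polynomial_order_fixed, polynomial_order_random)) {
    if (o < 0 || o > 5 || o != round(o))
      stop("polynomial orders must be integers in 0..5")
  }
  if (!identical(age_bounds, "from-data")) {
    stopifnot(is.numeric(age_bounds), length(age_bounds) == 2L,
              age_bounds[2] > age_bounds[1])
  }
  if (!identical(residual_classes, "homogeneous")) {
    stopifnot(is.numeric(residual_classes))
    if (is.unsorted(residual_classes, strictly = TRUE))
      stop("residual class cut points must be strictly increasing ",
           "(intervals must partition the age range without overlap)")
  }
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  structure(list(
    polynomial_order_fixed = as.integer(polynomial_order_fixed),
    polynomial_order_random = as.integer(polynomial_order_random),
    age_bounds = age_bounds,
    residual_classes = residual_classes,
    n_clusters = as.integer(n_clusters),
    n_animals = as.integer(n_animals),
    seed = as.integer(seed),
    reml_tol_loglik = reml_tol_loglik,
    reml_tol_param = reml_tol_param,
    max_iter = as.integer(max_iter)
  ), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Keys match the arguments of \code{\link{run_config}}; absent keys take
#' the defaults.
#'
#' @param path File path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return A \code{\link{run_config}}.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write the JSON run manifest
#'
#' Records the configuration, seed and package version alongside a named
#' list of free-form entries (file hashes, proportions, convergence info).
#'
#' @param config A \code{\link{run_config}}.
#' @param path Output path.
#' @param extra Named list merged into the manifest.
#' @export
write_manifest <- function(config, path, extra = list()) {
  m <- c(list(package = "telotraj",
              version = as.character(utils::packageVersion("telotraj")),
              config = unclass(config)),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
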