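## Pipeline stages and the command-line entry point.  Each stage reads its
## inputs from / writes its artifacts to a single output directory, so
## stages can be run one at a time (`simulate`, `rltl`, `fit`, `params`,
## `cluster`, `survival`) or chained (`all`).  Every stochastic stage is
## driven by the single configuration seed; rerunning with the same seed
## reproduces every output byte for byte.

out_path <- function(out_dir, name) file.path(out_dir, name)

truth_to_json <- function(truth, path) {
  jsonlite::write_json(list(
    K_true = truth$K_true,
    sigma2_e_true = as.vector(truth$sigma2_e_true),
    sigma2_pe_true = truth$sigma2_pe_true,
    fixed_regression = truth$fixed_regression,
    fixed_effect_values = lapply(truth$fixed_effect_values, as.list),
    basis = list(order = truth$basis$order, t_min = truth$basis$t_min,
                 t_max = truth$basis$t_max,
                 normalized = truth$basis$normalized),
    survival_log_hazard_by_cluster =
      as.list(truth$survival_log_hazard_by_cluster),
    baseline_hazard_per_day = truth$baseline_hazard_per_day),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run pipeline stages
#'
#' @param stage One of \code{"simulate"}, \code{"rltl"}, \code{"fit"},
#'   \code{"params"}, \code{"cluster"}, \code{"survival"}, \code{"all"}.
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed); later stages read
#'   the artifacts earlier stages wrote there.
#' @return Invisibly, a named list of the artifacts produced.
#' @export
run_pipeline <- function(stage, config = run_config(),
                         out_dir = "telotraj-out") {
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "rltl", "fit", "params", "cluster", "survival")
  stage <- match.arg(stage, c(stages, "all"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages else stage
  made <- list()

  for (st in todo) {
    made[[st]] <- switch(st,
      simulate = stage_simulate(config, out_dir),
      rltl = stage_rltl(config, out_dir),
      fit = stage_fit(config, out_dir),
      params = stage_params(config, out_dir),
      cluster = stage_cluster(config, out_dir),
      survival = stage_survival(config, out_dir))
  }
  write_manifest(config, out_path(out_dir, "run_manifest.json"),
                 extra = list(stages_run = todo))
  invisible(made)
}

stage_simulate <- function(config, out_dir) {
  basis <- if (identical(config$age_bounds, "from-data")) {
    legendre_basis(config$polynomial_order_random, 0, 60)
  } else {
    legendre_basis(config$polynomial_order_random, config$age_bounds[1],
                   config$age_bounds[2])
  }
  sim <- simulate_study(n_animals = config$n_animals,
                        truth = default_truth(basis), seed = config$seed)
  write_pedigree(sim$pedigree, out_path(out_dir, "pedigree.txt"))
  write_plates(sim$plates, out_path(out_dir, "plates.csv"))
  write_phenotypes(sim$phenotypes, out_path(out_dir, "phenotypes.csv"))
  write_survival(sim$survival, out_path(out_dir, "survival.csv"))
  truth_to_json(sim$truth, out_path(out_dir, "truth.json"))
  telo_log("info", "simulated ", nrow(sim$phenotypes), " records of ",
           config$n_animals, " animals")
  c("pedigree.txt", "plates.csv", "phenotypes.csv", "survival.csv",
    "truth.json")
}

stage_rltl <- function(config, out_dir) {
  plates <- read_plates(out_path(out_dir, "plates.csv"))
  rl <- rltl_table(plates)
  lt <- log_transform(rl$rltl, rl$sample_id)
  rl$log_rltl <- lt$log_rltl
  utils::write.csv(rl, out_path(out_dir, "rltl.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(lt$normality, out_path(out_dir, "normality.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  telo_log("info", "computed RLTL for ", nrow(rl), " samples")
  c("rltl.csv", "normality.json")
}

stage_fit <- function(config, out_dir) {
  phen <- read_phenotypes(out_path(out_dir, "phenotypes.csv"))
  ped <- read_pedigree(out_path(out_dir, "pedigree.txt"))
  model <- rrm_model(order_fixed = config$polynomial_order_fixed,
                     order_random = config$polynomial_order_random,
                     residual_cuts = if (identical(config$residual_classes,
                                                   "homogeneous")) NULL
                                     else config$residual_classes)
  basis <- if (identical(config$age_bounds, "from-data")) NULL else
    legendre_basis(config$polynomial_order_random, config$age_bounds[1],
                   config$age_bounds[2])
  fit <- fit_reml(phen, ped, model, basis = basis,
                  tol_loglik = config$reml_tol_loglik,
                  tol_param = config$reml_tol_param,
                  max_iter = config$max_iter,
                  solutions = TRUE, pev = TRUE)
  saveRDS(fit, out_path(out_dir, "fit.rds"))
  sol <- data.frame(
    effect = c(names(fit$beta),
               paste0(rep(rownames(fit$u), each = ncol(fit$u)), ":",
                      rep(colnames(fit$u), nrow(fit$u)))),
    estimate = c(unname(fit$beta), as.vector(t(fit$u))),
    se = c(if (is.null(fit$se_beta)) rep(NA_real_, length(fit$beta))
           else fit$se_beta,
           if (is.null(fit$pev)) rep(NA_real_, length(fit$u))
           else as.vector(t(vapply(rownames(fit$u), function(a)
             sqrt(pmax(diag(fit$pev[[a]]), 0)),
             numeric(ncol(fit$u)))))))
  utils::write.csv(sol, out_path(out_dir, "solutions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    converged = fit$converged, iterations = fit$iterations,
    loglik = fit$loglik, aic = fit$aic,
    basis = list(order = fit$basis$order, t_min = fit$basis$t_min,
                 t_max = fit$basis$t_max,
                 normalized = fit$basis$normalized),
    K = fit$varcomp$K, sigma2_e = as.vector(fit$varcomp$sigma2_e),
    sigma2_pe = fit$varcomp$sigma2_pe,
    theta = as.list(fit$theta), theta_cov = fit$theta_cov,
    loglik_trace = fit$trace$loglik),
    out_path(out_dir, "fit_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  telo_log("info", sprintf("REML converged in %d iterations, logL %.4f",
                           fit$iterations, fit$loglik))
  c("fit.rds", "solutions.csv", "fit_manifest.json")
}

stage_params <- function(config, out_dir) {
  fit <- readRDS(out_path(out_dir, "fit.rds"))
  trajs <- list(fixed_curve(fit), additive_variance(fit),
                heritability(fit), genetic_correlation(fit))
  write_trajectories(trajs, out_path(out_dir, "trajectories.csv"))
  write_trajectories(animal_profiles(fit),
                     out_path(out_dir, "profiles.csv"))
  ei <- eigen_analysis(fit)
  jsonlite::write_json(list(eigenvalues = ei$values,
                            percent = ei$percent),
                       out_path(out_dir, "eigen.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c("trajectories.csv", "profiles.csv", "eigen.json")
}

stage_cluster <- function(config, out_dir) {
  fit <- readRDS(out_path(out_dir, "fit.rds"))
  prof <- animal_profiles(fit)
  cl <- cluster_profiles(prof, k = config$n_clusters, seed = config$seed)
  write_clusters(cl, out_path(out_dir, "clusters.csv"),
                 out_path(out_dir, "cluster_curves.csv"))
  telo_log("info", "cluster proportions: ",
           paste(sprintf("%.1f%%", 100 * cl$proportions), collapse = " "))
  c("clusters.csv", "cluster_curves.csv")
}

stage_survival <- function(config, out_dir) {
  surv <- read_survival(out_path(out_dir, "survival.csv"))
  clu <- utils::read.csv(out_path(out_dir, "clusters.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  surv$cluster <- clu$cluster[match(surv$animal_id, clu$animal_id)]
  surv <- surv[!is.na(surv$cluster), , drop = FALSE]
  fit <- fit_cox(surv)
  write_cox_summary(fit, out_path(out_dir, "survival_fit.json"))
  telo_log("info", sprintf("cluster-lifespan Wald p = %.4f",
                           fit$wald$p_value))
  "survival_fit.json"
}

#' Command-line entry point
#'
#' Thin wrapper used by the \code{exec/telotraj} script:
#' \code{telotraj <stage> [--config <yaml/json>] [--seed <int>]
#' [--out-dir <dir>] [--log-level <debug|info|warn|error>]}.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
telotraj_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: telotraj <simulate|rltl|fit|params|cluster|survival|all>",
    "[--config FILE] [--seed INT] [--out-dir DIR] [--log-level LEVEL]")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  stage <- args[1L]
  args <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args))
      stop("malformed arguments; ", usage)
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config)) read_config(opts$config)
            else run_config()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts[["log-level"]]))
    options(telotraj.log_level = opts[["log-level"]])
  out_dir <- if (!is.null(opts[["out-dir"]])) opts[["out-dir"]]
             else "telotraj-out"
  run_pipeline(stage, config, out_dir)
  invisible(0L)
}
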