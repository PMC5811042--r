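## Association between profile cluster and productive lifespan: Cox
## proportional hazards on right-censored lifespan (days from birth to
## culling; animals alive at study end enter at their maximal known
## survival time), Breslow tie handling (daily recording produces ties),
## cluster as a factor with the largest cluster as reference, and a Wald
## test over the cluster coefficients.

#' Fit the cluster-lifespan Cox proportional-hazards model
#'
#' Maximises the Breslow partial likelihood (Newton-Raphson, via
#' \code{survival::coxph}) with cluster indicators as covariates.  The
#' reference cluster defaults to the largest one.  A monotone partial
#' likelihood (a cluster separating completely in event order) yields very
#' large coefficients; these are flagged with a warning.
#'
#' @param records Data frame with \code{animal_id}, \code{time_days},
#'   \code{event} (1 = culled, 0 = censored) and \code{cluster}.
#' @param reference_cluster Reference level (default: largest cluster).
#' @param ties Tie handling, \code{"breslow"} (default) or \code{"efron"}.
#' @return Object of class \code{cox_fit}: \code{coefficients} (log hazard
#'   ratios per non-reference cluster), \code{cov}, \code{wald}
#'   (statistic, df, p_value), \code{score_statistic}, \code{loglik},
#'   \code{n_events}, \code{n_censored}, \code{reference},
#'   \code{monotone} flag.
#' @export
fit_cox <- function(records, reference_cluster = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  need <- c("animal_id", "time_days", "event", "cluster")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("survival records lack column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(records$animal_id))
    stop("every animal must have exactly one survival record")
  if (any(records$time_days <= 0)) stop("survival times must be > 0")
  ev <- as.integer(records$event)
  if (sum(ev) < 1L) stop("at least one event is required")
  cl <- factor(records$cluster)
  if (nlevels(cl) < 2L)
    stop("at least two clusters must be present after filtering")
  if (is.null(reference_cluster))
    reference_cluster <- names(which.max(table(cl)))
  if (!reference_cluster %in% levels(cl))
    stop("reference cluster not present: ", reference_cluster)
  cl <- stats::relevel(cl, ref = reference_cluster)

  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$time_days, ev) ~ cl,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  names(beta) <- sub("^cl", "", names(beta))
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  if (monotone || any(abs(beta) > 15))
    warning("monotone partial likelihood: a cluster separates completely ",
            "in event order; coefficient(s) are at the optimiser cap and ",
            "their SEs are unreliable")
  structure(list(
    coefficients = beta, cov = V,
    wald = wald_stat(beta, V),
    score_statistic = unname(fit$score),
    loglik = fit$loglik[2L],
    n_events = sum(ev), n_censored = sum(1L - ev),
    reference = reference_cluster, ties = ties,
    monotone = monotone || any(abs(beta) > 15)),
    class = "cox_fit")
}

wald_stat <- function(beta, V) {
  ok <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ok)) stop("singular coefficient covariance; Wald test undefined")
  stat <- drop(crossprod(beta, chol2inv(ok) %*% beta))
  df <- length(beta)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test for the cluster factor
#'
#' \eqn{W = \beta' Cov(\beta)^{-1} \beta} over the non-reference cluster
#' coefficients, compared to a chi-square with (number of clusters - 1)
#' degrees of freedom.
#'
#' @param fit A \code{\link{fit_cox}} result.
#' @return List \code{statistic}, \code{df}, \code{p_value}.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  wald_stat(fit$coefficients, fit$cov)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (ties = %s): %d events, %d censored, reference cluster %s\n",
              x$ties, x$n_events, x$n_censored, x$reference))
  print(data.frame(log_hr = x$coefficients,
                   se = sqrt(diag(x$cov)),
                   hr = exp(x$coefficients)))
  cat(sprintf("Wald chi-square = %.4f on %d df, p = %.4g\n",
              x$wald$statistic, x$wald$df, x$wald$p_value))
  if (x$monotone) cat("  (monotone likelihood flagged)\n")
  invisible(x)
}

#' Write the Cox fit summary as JSON
#'
#' @param fit A \code{\link{fit_cox}} result.
#' @param path Output path.
#' @export
write_cox_summary <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  jsonlite::write_json(list(
    reference = fit$reference,
    coefficients = as.list(fit$coefficients),
    se = as.list(stats::setNames(sqrt(diag(fit$cov)),
                                 names(fit$coefficients))),
    wald_chisq = fit$wald$statistic, wald_df = fit$wald$df,
    wald_p = fit$wald$p_value,
    n_events = fit$n_events, n_censored = fit$n_censored,
    ties = fit$ties, monotone = fit$monotone),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
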