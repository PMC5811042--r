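## Transforms a fitted random regression model into the reported
## quantities: fixed population curve, per-animal deviation profiles with
## prediction-error SEs, additive genetic variance V_A(t) = phi(t) K
## phi(t)', heritability and genetic-correlation trajectories with
## delta-method SEs, and the eigen decomposition of K.

#' Age-indexed trajectory
#'
#' @param age Strictly increasing age grid (months).
#' @param value Values on the grid.
#' @param se Pointwise standard errors (\code{NA} where undefined).
#' @param kind One of \code{fixed_curve}, \code{additive_variance},
#'   \code{heritability}, \code{profile}, \code{correlation}.
#' @param animal_id Animal id for profiles, \code{NA} for population
#'   curves.
#' @return Data frame of class \code{trajectory} with columns
#'   \code{kind, animal_id, age_month, value, se}.
#' @export
trajectory <- function(age, value, se = NA_real_, kind, animal_id = NA) {
  stopifnot(length(value) == length(age))
  if (is.unsorted(age, strictly = TRUE))
    stop("trajectory age grid must be strictly increasing")
  se <- rep_len(as.numeric(se), length(age))
  if (any(!is.na(se) & se < 0)) stop("trajectory SEs must be >= 0")
  structure(data.frame(kind = kind, animal_id = as.character(animal_id),
                       age_month = age, value = as.numeric(value), se = se,
                       stringsAsFactors = FALSE),
            class = c("trajectory", "data.frame"))
}

## theta layout shared with the REML engine
theta_layout <- function(fit) {
  m <- if (is.null(fit$varcomp$K)) 0L else ncol(fit$varcomp$K)
  nk <- if (m) m * (m + 1L) / 2L else 0L
  npe <- as.integer(!is.null(fit$varcomp$sigma2_pe))
  ne <- length(fit$varcomp$sigma2_e)
  list(m = m, nk = nk, npe = npe, ne = ne)
}

theta_split <- function(theta, lay) {
  K <- if (lay$nk) vech_to_sym(theta[seq_len(lay$nk)], lay$m) else NULL
  s2pe <- if (lay$npe) theta[lay$nk + 1L] else 0
  s2e <- theta[(lay$nk + lay$npe + 1L):(lay$nk + lay$npe + lay$ne)]
  list(K = K, s2pe = s2pe, s2e = s2e)
}

## residual variance applying at age t (respects residual age classes)
sigma2_e_at <- function(s2e, cuts, t) {
  if (length(s2e) == 1L) return(rep(s2e, length(t)))
  s2e[findInterval(t, cuts) + 1L]
}

## delta-method SE of g(theta) with central finite differences
## (step 1e-6 * parameter scale)
delta_se <- function(g, theta, theta_cov) {
  q <- length(theta)
  g0 <- g(theta)
  J <- matrix(0, length(g0), q)
  for (i in seq_len(q)) {
    h <- 1e-6 * max(abs(theta[i]), 1e-8)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (g(tp) - g(tm)) / (2 * h)
  }
  v <- rowSums((J %*% theta_cov) * J)
  sqrt(pmax(v, 0))
}

#' Fixed population curve
#'
#' \eqn{\hat f(t) = \sum_k \hat b_k \phi_k(t)}: the Legendre regression
#' part of the fixed effects evaluated along the age grid, with SE from the
#' corresponding block of the fixed-effect covariance.
#'
#' @param fit An \code{rrm_fit}.
#' @param grid Age grid (months); default integer months over the basis
#'   bounds.
#' @return A \code{\link{trajectory}} of kind \code{fixed_curve}.
#' @export
fixed_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  basis_f <- legendre_basis(fit$model$order_fixed, fit$basis$t_min,
                            fit$basis$t_max, fit$basis$normalized)
  if (is.null(grid)) grid <- age_grid(basis_f)
  Phi <- basis_matrix(grid, basis_f)
  bn <- paste0("phi", 0:(fit$model$order_fixed))
  b <- fit$beta[bn]
  se <- if (!is.null(fit$beta_cov) && all(bn %in% rownames(fit$beta_cov))) {
    B <- fit$beta_cov[bn, bn, drop = FALSE]
    sqrt(pmax(rowSums((Phi %*% B) * Phi), 0))
  } else NA_real_
  trajectory(grid, drop(Phi %*% b), se, "fixed_curve")
}

#' Individual animal profiles (deviations from the fixed curve)
#'
#' \eqn{\hat g_j(t) = \sum_k \hat u_{jk} \phi_k(t)}, with pointwise SE
#' \eqn{\sqrt{\phi(t) PEV_j \phi(t)'}} from the animal's prediction-error
#' covariance (\code{se_mode = "full"}, default) or ignoring coefficient
#' covariances (\code{se_mode = "independent"}: \eqn{\sqrt{\sum_k
#' \phi_k(t)^2 PEV_{j,kk}}}).
#'
#' @param fit An \code{rrm_fit} fitted with \code{solutions = TRUE} (and
#'   \code{pev = TRUE} for SEs).
#' @param animal_ids Animals to evaluate (default: phenotyped animals).
#' @param grid Age grid.
#' @param se_mode \code{"full"} or \code{"independent"}.
#' @return List of \code{\link{trajectory}} objects of kind
#'   \code{profile}, named by animal.
#' @export
animal_profiles <- function(fit, animal_ids = NULL, grid = NULL,
                            se_mode = c("full", "independent")) {
  stopifnot(inherits(fit, "rrm_fit"))
  se_mode <- match.arg(se_mode)
  if (is.null(fit$u)) stop("fit carries no BLUP solutions; ",
                           "refit with solutions = TRUE")
  if (is.null(animal_ids)) animal_ids <- fit$phen_animals
  unknown <- setdiff(animal_ids, rownames(fit$u))
  if (length(unknown))
    stop("unknown animal id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  if (is.null(grid)) grid <- age_grid(fit$basis)
  Phi <- basis_matrix(grid, fit$basis)
  out <- lapply(animal_ids, function(a) {
    val <- drop(Phi %*% fit$u[a, ])
    se <- NA_real_
    if (!is.null(fit$pev)) {
      P <- fit$pev[[a]]
      se <- if (se_mode == "full") {
        sqrt(pmax(rowSums((Phi %*% P) * Phi), 0))
      } else {
        sqrt(pmax(drop(Phi^2 %*% diag(P)), 0))
      }
    }
    trajectory(grid, val, se, "profile", animal_id = a)
  })
  stats::setNames(out, animal_ids)
}

#' Additive genetic variance along the age trajectory
#'
#' \eqn{V_A(t) = \phi(t) K \phi(t)'}: the quadratic form of the basis row
#' with the coefficient covariance; non-negative whenever K is PSD.
#'
#' @param K Symmetric coefficient covariance (or an \code{rrm_fit}).
#' @param basis The matching \code{\link{legendre_basis}} (taken from the
#'   fit when one is supplied).
#' @param grid Age grid.
#' @return A \code{\link{trajectory}} of kind \code{additive_variance}.
#' @export
additive_variance <- function(K, basis = NULL, grid = NULL) {
  if (inherits(K, "rrm_fit")) {
    basis <- K$basis
    K <- K$varcomp$K
  }
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  if (is.null(basis)) stop("a basis is required")
  if (ncol(K) != basis$order + 1L)
    stop("K dimension does not match the basis order")
  if (is.null(grid)) grid <- age_grid(basis)
  Phi <- basis_matrix(grid, basis)
  trajectory(grid, rowSums((Phi %*% K) * Phi), NA_real_,
             "additive_variance")
}

#' Heritability trajectory with delta-method standard errors
#'
#' \eqn{h^2(t) = V_A(t) / (V_A(t) + \sigma^2_{PE} + \sigma^2_e(t))}; the
#' permanent-environment variance enters the denominator only when that
#' term is in the model.  SEs by the delta method: central finite
#' difference gradient of \eqn{h^2(t)} in the variance parameters,
#' sandwiched with their asymptotic (inverse average-information)
#' covariance.
#'
#' @param fit A converged \code{rrm_fit} with \code{theta_cov}.
#' @param grid Age grid.
#' @return A \code{\link{trajectory}} of kind \code{heritability}.
#' @export
heritability <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(fit$varcomp$K)) stop("fit has no genetic component")
  if (is.null(grid)) grid <- age_grid(fit$basis)
  Phi <- basis_matrix(grid, fit$basis)
  lay <- theta_layout(fit)
  cuts <- attr(fit$varcomp$sigma2_e, "cuts")
  h2_of <- function(theta) {
    th <- theta_split(theta, lay)
    va <- rowSums((Phi %*% th$K) * Phi)
    tot <- va + th$s2pe + sigma2_e_at(th$s2e, cuts, grid)
    if (any(tot <= 0)) stop("total variance <= 0 on the age grid")
    va / tot
  }
  val <- h2_of(fit$theta)
  se <- delta_se(h2_of, fit$theta, fit$theta_cov)
  trajectory(grid, val, se, "heritability")
}

#' Genetic correlation with a reference age
#'
#' \eqn{r(t_0, t) = \phi(t_0) K \phi(t)' / \sqrt{V_A(t_0) V_A(t)}}.  With
#' an \code{rrm_fit}, delta-method SEs are attached (finite-difference
#' gradient sandwiched with the variance-parameter covariance); with a bare
#' K matrix the SE is \code{NA}.
#'
#' @param K An \code{rrm_fit} or a symmetric coefficient covariance.
#' @param basis Basis (ignored when a fit is supplied).
#' @param reference_age Reference age \eqn{t_0} (months; default the basis
#'   lower bound, i.e. birth).
#' @param grid Age grid.
#' @return A \code{\link{trajectory}} of kind \code{correlation}.
#' @export
genetic_correlation <- function(K, basis = NULL, reference_age = NULL,
                                grid = NULL) {
  fit <- NULL
  if (inherits(K, "rrm_fit")) {
    fit <- K
    basis <- fit$basis
    K <- fit$varcomp$K
  }
  K <- as.matrix(K)
  if (is.null(basis)) stop("a basis is required")
  if (is.null(reference_age)) reference_age <- basis$t_min
  if (is.null(grid)) grid <- age_grid(basis)
  corr_from_K <- function(Km) {
    p0 <- basis_row(reference_age, basis)
    Phi <- basis_matrix(grid, basis)
    v0 <- drop(p0 %*% Km %*% p0)
    vt <- rowSums((Phi %*% Km) * Phi)
    if (v0 <= 0 || any(vt <= 0))
      stop("zero additive variance at the reference age or on the grid; ",
           "correlation undefined")
    drop(Phi %*% Km %*% p0) / sqrt(v0 * vt)
  }
  val <- corr_from_K(K)
  se <- NA_real_
  if (!is.null(fit) && !is.null(fit$theta_cov) &&
      all(is.finite(fit$theta_cov))) {
    lay <- theta_layout(fit)
    se <- delta_se(function(theta)
      corr_from_K(theta_split(theta, lay)$K), fit$theta, fit$theta_cov)
    se[grid == reference_age] <- 0   # r(t0, t0) = 1 identically
  }
  trajectory(grid, val, se, "correlation")
}

#' Eigen decomposition of the coefficient covariance
#'
#' Eigenvalues of K (descending) with their percentage of total coefficient
#' variance, and the eigenfunctions \eqn{\psi_i(t) = \sum_k v_{ik}
#' \phi_k(t)} on the age grid.  The leading eigenfunction of an
#' intercept-dominated K is approximately constant: variation in overall
#' level rather than in curve shape.
#'
#' @param K An \code{rrm_fit} or symmetric coefficient covariance.
#' @param basis Basis (ignored when a fit is supplied).
#' @param grid Age grid.
#' @return List of class \code{eigen_decomposition}: \code{values},
#'   \code{percent}, \code{vectors}, \code{functions} (grid x m matrix),
#'   \code{grid}.
#' @export
eigen_analysis <- function(K, basis = NULL, grid = NULL) {
  if (inherits(K, "rrm_fit")) {
    basis <- K$basis
    K <- K$varcomp$K
  }
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  if (is.null(basis)) stop("a basis is required")
  if (is.null(grid)) grid <- age_grid(basis)
  ev <- eigen(K, symmetric = TRUE)
  tot <- sum(ev$values)
  pct <- if (tot > 0) 100 * ev$values / tot else rep(NA_real_,
                                                     length(ev$values))
  Phi <- basis_matrix(grid, basis)
  structure(list(values = ev$values, percent = pct, vectors = ev$vectors,
                 functions = Phi %*% ev$vectors, grid = grid),
            class = "eigen_decomposition")
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat("Eigen decomposition of the coefficient covariance:\n")
  print(data.frame(eigenvalue = x$values, percent = round(x$percent, 2)))
  invisible(x)
}

#' Write trajectories to a tidy CSV
#'
#' @param trajectories A \code{\link{trajectory}} or list thereof.
#' @param path Output path (columns \code{kind, animal_id, age_month,
#'   value, se}).
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  df <- do.call(rbind, lapply(trajectories, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
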