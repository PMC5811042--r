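## Random regression animal model:
##   y_tij = BirthYear_j + GeneticGroup_j + plate_ij + row_ij
##           + sum_k phi_k(t) b_k + sum_k phi_k(t) u_jk + e_tij
## with var(vec u) = A (x) K (pedigree relationship matrix times the
## coefficient covariance), optional permanent-environment animal effect,
## and homogeneous or age-class residual variances.  Variance components by
## average-information REML on the dense V = Z G Z' + R formulation (cheap
## at a few thousand records); solutions/PEV from the sparse Henderson
## mixed-model equations whose random block carries A^-1 (x) K^-1.

#' Specify a random regression model
#'
#' @param order_fixed,order_random Legendre orders for the fixed population
#'   curve and the random (additive genetic) animal curves.
#' @param fixed_factors Class effects always kept in the model.
#' @param covariates Extra numeric covariate columns (candidates for
#'   \code{\link{backward_eliminate}}).
#' @param random Random animal structure: \code{"pedigree"} (coefficients
#'   correlated through the relationship matrix), \code{"identity"} (animal
#'   identity without pedigree, A = I), or \code{"none"} (fixed effects
#'   only).
#' @param permanent_env Add a scalar permanent-environment effect per
#'   phenotyped animal.
#' @param residual_cuts \code{NULL} for homogeneous residual variance, or
#'   increasing age cut points (months) defining left-closed residual
#'   variance classes.
#' @param likelihood \code{"reml"} (default) or \code{"ml"}.
#' @return Object of class \code{rrm_model}.
#' @export
rrm_model <- function(order_fixed = 2L, order_random = 2L,
                      fixed_factors = c("birth_year", "genetic_group",
                                        "plate", "row"),
                      covariates = character(),
                      random = c("pedigree", "identity", "none"),
                      permanent_env = FALSE,
                      residual_cuts = NULL,
                      likelihood = c("reml", "ml")) {
  random <- match.arg(random)
  likelihood <- match.arg(likelihood)
  if (order_fixed < 0 || order_fixed > 5 || order_random < 0 ||
      order_random > 5)
    stop("polynomial orders must lie in 0..5")
  if (!is.null(residual_cuts) &&
      is.unsorted(residual_cuts, strictly = TRUE))
    stop("residual_cuts must be strictly increasing")
  structure(list(order_fixed = as.integer(order_fixed),
                 order_random = as.integer(order_random),
                 fixed_factors = fixed_factors,
                 covariates = covariates,
                 random = random,
                 permanent_env = isTRUE(permanent_env),
                 residual_cuts = residual_cuts,
                 likelihood = likelihood),
            class = "rrm_model")
}

## vech index pairs (a <= b) for an m x m symmetric matrix
vech_pairs <- function(m) {
  out <- NULL
  for (a in seq_len(m)) for (b in a:m) out <- rbind(out, c(a, b))
  out
}

vech_to_sym <- function(v, m) {
  K <- matrix(0, m, m)
  K[upper.tri(K, diag = TRUE)] <- NA   # placeholder, filled below
  p <- vech_pairs(m)
  for (i in seq_len(nrow(p))) K[p[i, 1], p[i, 2]] <- K[p[i, 2], p[i, 1]] <- v[i]
  K
}

sym_to_vech <- function(K) {
  p <- vech_pairs(nrow(K))
  vapply(seq_len(nrow(p)), function(i) K[p[i, 1], p[i, 2]], numeric(1))
}

## eigenvalue flooring that keeps K inside the PSD cone
bend_psd <- function(K, rel_floor = 1e-8) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  floor_val <- rel_floor * max(sum(pmax(ev$values, 0)), 1e-12)
  if (all(ev$values >= floor_val)) return(list(K = (K + t(K)) / 2,
                                               bent = FALSE))
  vals <- pmax(ev$values, floor_val)
  list(K = ev$vectors %*% (vals * t(ev$vectors)), bent = TRUE)
}

## design preparation -------------------------------------------------------

## Builds the fixed design matrix (Legendre regression columns + treatment
## dummies + covariates), dropping aliased columns with a logged note, plus
## record-level indices used by the variance machinery.
build_design <- function(data, model, basis_f) {
  n <- nrow(data)
  y <- as.numeric(data$log_rltl)
  Phi_f <- basis_matrix(data$age_months, basis_f)
  X <- Phi_f
  for (fct in model$fixed_factors) {
    if (!fct %in% names(data))
      stop("fixed factor column missing from data: ", fct)
    v <- factor(data[[fct]])
    if (nlevels(v) > 1L) {
      mm <- stats::model.matrix(~ v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(fct, ":", levels(v)[-1L])
      X <- cbind(X, mm)
    }
  }
  for (cv in model$covariates) {
    if (!cv %in% names(data))
      stop("covariate column missing from data: ", cv)
    X <- cbind(X, stats::setNames(data.frame(as.numeric(data[[cv]])), cv))
  }
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[(qx$rank + 1L):ncol(X)]
    telo_log("warn", "dropping aliased fixed-effect column(s): ",
             paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  X
}

## residual class index per record, merging classes with < 10 records into
## their left neighbour
residual_classes <- function(age, cuts, min_records = 10L) {
  if (is.null(cuts)) return(list(class = rep(1L, length(age)), cuts = NULL))
  cls <- findInterval(age, cuts) + 1L
  repeat {
    tab <- tabulate(cls, nbins = length(cuts) + 1L)
    small <- which(tab > 0L & tab < min_records)
    empty <- which(tab == 0L)
    fix <- c(small, empty)
    if (!length(fix)) break
    k <- fix[1L]
    telo_log("warn", "residual age class ", k,
             " has fewer than ", min_records,
             " records; merging with neighbour")
    cuts <- cuts[-max(k - 1L, 1L)]
    if (!length(cuts)) return(list(class = rep(1L, length(age)),
                                   cuts = NULL))
    cls <- findInterval(age, cuts) + 1L
  }
  list(class = cls, cuts = cuts)
}

prepare_rrm <- function(data, ped, model, basis_f, basis_r) {
  need <- c("animal_id", "age_months", "log_rltl")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (model$random == "pedigree") {
    stopifnot(inherits(ped, "pedigree"))
    unknown <- setdiff(unique(data$animal_id), ped$id)
    if (length(unknown))
      stop("phenotyped animal(s) absent from pedigree: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  X <- build_design(data, model, basis_f)
  rc <- residual_classes(data$age_months, model$residual_cuts)
  phen_animals <- unique(data$animal_id)
  list(y = as.numeric(data$log_rltl), X = X,
       anim = match(data$animal_id, phen_animals),
       phen_animals = phen_animals,
       Phi_r = if (model$random != "none")
         basis_matrix(data$age_months, basis_r) else NULL,
       rclass = rc$class, rcuts = rc$cuts,
       n_rclass = max(rc$class))
}

## relationship submatrix among phenotyped animals, via sparse solves
## against A^-1 (never forms dense A for the whole pedigree)
relationship_submatrix <- function(ped, ids) {
  Ainv <- ainverse(ped)
  ix <- match(ids, ped$id)
  E <- Matrix::sparseMatrix(i = ix, j = seq_along(ix), x = 1,
                            dims = c(length(ped$id), length(ix)))
  AS <- as.matrix(Matrix::solve(Ainv, E))
  AS[ix, , drop = FALSE]
}

## restricted / profile log-likelihood machinery -----------------------------

## Builds closures over the prepared data; theta is
## (vech K, [sigma2_pe], sigma2_e by class).
make_lik_env <- function(prep, model, A_rec, S_rec) {
  n <- length(prep$y)
  m <- if (model$random != "none") ncol(prep$Phi_r) else 0L
  kp <- if (m > 0L) vech_pairs(m) else NULL
  nk <- if (m > 0L) nrow(kp) else 0L
  npe <- as.integer(model$permanent_env)
  ne <- prep$n_rclass
  theta_names <- c(
    if (nk) paste0("K", kp[, 1] - 1L, kp[, 2] - 1L),
    if (npe) "sigma2_pe",
    if (ne == 1L) "sigma2_e" else paste0("sigma2_e", seq_len(ne)))
  split_theta <- function(theta) {
    K <- if (nk) vech_to_sym(theta[seq_len(nk)], m) else NULL
    s2pe <- if (npe) theta[nk + 1L] else 0
    s2e <- theta[(nk + npe + 1L):(nk + npe + ne)]
    list(K = K, s2pe = s2pe, s2e = s2e)
  }
  build_V <- function(theta) {
    th <- split_theta(theta)
    V <- if (!is.null(th$K))
      A_rec * (prep$Phi_r %*% th$K %*% t(prep$Phi_r))
    else matrix(0, n, n)
    if (npe) V <- V + th$s2pe * S_rec
    diag(V) <- diag(V) + th$s2e[prep$rclass]
    V
  }
  list(n = n, m = m, kp = kp, nk = nk, npe = npe, ne = ne,
       theta_names = theta_names, split_theta = split_theta,
       build_V = build_V)
}

## One likelihood evaluation.  The factorisation internals are kept on the
## result so that lik_add_derivs() can attach the score and
## average-information matrix without refactorising V.
lik_eval <- function(theta, env, prep, model, A_rec, S_rec,
                     derivs = FALSE) {
  n <- env$n
  X <- prep$X; y <- prep$y; p <- ncol(X)
  V <- env$build_V(theta)
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(list(loglik = -Inf))
  ldV <- 2 * sum(log(diag(cv)))
  ## triangular solves only; the dense inverse of V is deferred to the
  ## derivative pass (lik_add_derivs) and so is never paid for rejected
  ## line-search candidates
  W <- backsolve(cv, forwardsolve(t(cv), cbind(X, y)))
  VX <- W[, seq_len(p), drop = FALSE]
  Viy <- W[, p + 1L]
  XtViX <- crossprod(X, VX)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(list(loglik = -Inf))
  ldX <- 2 * sum(log(diag(cx)))
  beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Viy)))
  Py <- drop(Viy - VX %*% beta)
  yPy <- sum(y * Py)
  ll <- if (model$likelihood == "reml") {
    -0.5 * ((n - p) * log(2 * pi) + ldV + ldX + yPy)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + yPy)
  }
  out <- list(loglik = ll, beta = drop(beta),
              beta_cov = chol2inv(cx), Py = Py, yPy = yPy,
              theta = theta, cv = cv, VX = VX, cx = cx)
  if (derivs) out <- lik_add_derivs(out, env, prep, model, A_rec, S_rec)
  out
}

lik_add_derivs <- function(out, env, prep, model, A_rec, S_rec) {
  if (!is.null(out$score)) return(out)
  n <- env$n
  Py <- out$Py
  Vi <- chol2inv(out$cv)
  P <- if (model$likelihood == "reml") {
    Vi - out$VX %*% backsolve(out$cx,
                              forwardsolve(t(out$cx), t(out$VX)))
  } else Vi
  q <- length(out$theta)
  Fm <- matrix(0, n, q)
  trv <- numeric(q)
  dP <- diag(P)
  for (i in seq_len(q)) {
    if (i <= env$nk) {
      a <- env$kp[i, 1]; b <- env$kp[i, 2]
      po <- tcrossprod(prep$Phi_r[, a], prep$Phi_r[, b])
      dV <- if (a == b) A_rec * po else A_rec * (po + t(po))
      trv[i] <- sum(P * dV)
      Fm[, i] <- dV %*% Py
    } else if (env$npe && i == env$nk + 1L) {
      trv[i] <- sum(P * S_rec)
      Fm[, i] <- S_rec %*% Py
    } else {
      cls <- i - env$nk - env$npe
      ind <- prep$rclass == cls
      trv[i] <- sum(dP[ind])
      Fm[ind, i] <- Py[ind]
    }
  }
  out$score <- -0.5 * (trv - colSums(Fm * Py))
  out$AI <- 0.5 * crossprod(Fm, P %*% Fm)
  out
}

## closed-form fixed-effects-only fit (V = sigma2 I)
fit_fixed_only <- function(prep, model) {
  X <- prep$X; y <- prep$y
  n <- length(y); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  if (model$likelihood == "reml") {
    s2 <- rss / (n - p)
    ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) +
                    as.numeric(ldXX) + (n - p))
    aic <- -2 * ll + 2 * 1
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + n)
    aic <- -2 * ll + 2 * (1 + p)
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  structure(list(
    beta = stats::setNames(fit$coefficients, colnames(X)),
    beta_cov = XtXi * s2,
    u = NULL, pe = NULL,
    varcomp = list(K = NULL, sigma2_pe = NULL, sigma2_e = s2),
    theta = c(sigma2_e = s2),
    theta_cov = matrix(2 * s2^2 / (n - p), 1, 1,
                       dimnames = list("sigma2_e", "sigma2_e")),
    loglik = ll, aic = aic, n_theta = 1L,
    converged = TRUE, iterations = 0L,
    trace = data.frame(iter = 0L, loglik = ll),
    model = model, n = n, p = p), class = "rrm_fit")
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse symmetric system \eqn{C s = r} for given variance
#' components: fixed block \eqn{X'R^{-1}X}, random regression block
#' \eqn{Z'R^{-1}Z + A^{-1} \otimes K^{-1}} (animal-major coefficient
#' ordering), optional permanent-environment block, and the right-hand
#' side.  Solving it yields BLUE fixed effects and BLUP coefficients for
#' every animal in the pedigree, phenotyped or not.
#'
#' @param data Phenotype data frame (see \code{\link{read_phenotypes}}).
#' @param model An \code{\link{rrm_model}} with \code{random != "none"}.
#' @param basis The random-regression \code{\link{legendre_basis}}.
#' @param a_inverse Sparse inverse relationship matrix with animal-id
#'   dimnames (\code{\link{ainverse}}), or \code{NULL} for
#'   \code{random = "identity"}.
#' @param K,sigma2_e,sigma2_pe Variance components (residual scalar or
#'   per-class vector matching \code{model$residual_cuts}).
#' @return List: \code{C} (sparse), \code{rhs}, \code{layout} (data frame
#'   naming every equation), \code{animals}.
#' @export
build_mme <- function(data, model, basis, a_inverse, K, sigma2_e,
                      sigma2_pe = 0) {
  stopifnot(inherits(model, "rrm_model"), model$random != "none")
  basis_f <- legendre_basis(model$order_fixed, basis$t_min, basis$t_max,
                            basis$normalized)
  prep <- prepare_rrm(data, NULL,
                      utils::modifyList(model, list(random = "identity")),
                      basis_f, basis)
  n <- length(prep$y)
  m <- basis$order + 1L
  if (!is.null(a_inverse)) {
    animals <- rownames(a_inverse)
    if (is.null(animals)) stop("a_inverse needs animal-id dimnames")
    miss <- setdiff(prep$phen_animals, animals)
    if (length(miss)) stop("animal(s) missing from a_inverse: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
  } else {
    animals <- prep$phen_animals
    a_inverse <- Matrix::Diagonal(length(animals))
    dimnames(a_inverse) <- list(animals, animals)
  }
  N <- length(animals)
  aix <- match(data$animal_id, animals)
  ri <- 1 / (if (length(sigma2_e) == 1L) rep(sigma2_e, n)
             else sigma2_e[prep$rclass])

  X <- prep$X
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = m),
    j = as.vector(t((aix - 1L) * m + matrix(seq_len(m), n, m, byrow = TRUE))),
    x = as.vector(t(prep$Phi_r)),
    dims = c(n, N * m))
  Kinv <- chol2inv(chol(K))
  Ginv <- Matrix::kronecker(a_inverse, Matrix::Matrix(Kinv, sparse = TRUE))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  XtRiX <- Matrix::crossprod(Xs, ri * Xs)
  XtRiZ <- Matrix::crossprod(Xs, ri * Z)
  ZtRiZ <- Matrix::crossprod(Z, ri * Z)
  blocks <- list(
    cbind(XtRiX, XtRiZ),
    cbind(Matrix::t(XtRiZ), ZtRiZ + Ginv))
  rhs <- c(as.vector(Matrix::crossprod(Xs, ri * prep$y)),
           as.vector(Matrix::crossprod(Z, ri * prep$y)))
  layout <- data.frame(
    block = c(rep("fixed", ncol(X)), rep("genetic", N * m)),
    label = c(colnames(X),
              paste0(rep(animals, each = m), ":phi", rep(0:(m - 1L), N))),
    stringsAsFactors = FALSE)
  if (model$permanent_env) {
    Np <- length(prep$phen_animals)
    Zp <- Matrix::sparseMatrix(i = seq_len(n), j = prep$anim,
                               x = 1, dims = c(n, Np))
    if (sigma2_pe <= 0) stop("sigma2_pe must be > 0 for the PE block")
    blocks[[1]] <- cbind(blocks[[1]], Matrix::crossprod(Xs, ri * Zp))
    blocks[[2]] <- cbind(blocks[[2]], Matrix::crossprod(Z, ri * Zp))
    blocks[[3]] <- cbind(Matrix::crossprod(Zp, ri * Xs),
                         Matrix::crossprod(Zp, ri * Z),
                         Matrix::crossprod(Zp, ri * Zp) +
                           Matrix::Diagonal(Np) / sigma2_pe)
    rhs <- c(rhs, as.vector(Matrix::crossprod(Zp, ri * prep$y)))
    layout <- rbind(layout,
                    data.frame(block = "pe", label = prep$phen_animals))
  }
  C <- do.call(rbind, blocks)
  list(C = Matrix::forceSymmetric(C), rhs = rhs, layout = layout,
       animals = animals)
}

#' Fit the random regression animal model by AI-REML
#'
#' Average-information REML with automatic bending (eigenvalue flooring at
#' 1e-8 of the trace) when a proposed K leaves the PSD cone and step
#' halving when a proposal would decrease the restricted log-likelihood;
#' convergence when the log-likelihood change and the maximum relative
#' parameter change fall below their tolerances.  Starting values are
#' scale-aware: half the OLS residual variance to the residual, the other
#' half spread over the K diagonal.
#'
#' @param data Phenotype data frame with \code{animal_id, age_months,
#'   log_rltl} and the model's factor/covariate columns.
#' @param ped A \code{\link{pedigree}} (required for
#'   \code{random = "pedigree"}).
#' @param model An \code{\link{rrm_model}}.
#' @param basis Optional \code{\link{legendre_basis}} for the random term;
#'   default bounds are the observed age range.
#' @param start Optional named list \code{K}, \code{sigma2_pe},
#'   \code{sigma2_e} of starting values.
#' @param tol_loglik,tol_param,max_iter Convergence controls.
#' @param solutions Solve the mixed-model equations at convergence for
#'   BLUE/BLUP solutions.
#' @param pev Also extract per-animal prediction-error covariance blocks
#'   and solution standard errors (requires \code{solutions}).
#' @param verbose Log iteration progress.
#' @return Object of class \code{rrm_fit}: variance components
#'   (\code{varcomp}), restricted log-likelihood, REML-AIC (2 x number of
#'   variance parameters penalty), asymptotic covariance of the variance
#'   parameters (inverse average information), solutions and their SEs,
#'   convergence trace.
#' @export
fit_reml <- function(data, ped = NULL, model = rrm_model(), basis = NULL,
                     start = NULL, tol_loglik = 1e-8, tol_param = 1e-6,
                     max_iter = 100L, solutions = TRUE, pev = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(model, "rrm_model"))
  ## `basis` supplies age bounds and convention; polynomial orders always
  ## come from the model (fixed and random orders may differ)
  if (is.null(basis)) {
    basis <- legendre_basis(model$order_random,
                            min(data$age_months), max(data$age_months))
  } else {
    basis <- legendre_basis(model$order_random, basis$t_min, basis$t_max,
                            basis$normalized)
  }
  basis_f <- legendre_basis(model$order_fixed, basis$t_min, basis$t_max,
                            basis$normalized)
  prep <- prepare_rrm(data, ped, model, basis_f, basis)

  if (model$random == "none") {
    fit <- fit_fixed_only(prep, model)
    fit$basis <- basis
    return(fit)
  }

  A_rec <- if (model$random == "pedigree") {
    AS <- relationship_submatrix(ped, prep$phen_animals)
    AS[prep$anim, prep$anim]
  } else {
    outer(prep$anim, prep$anim, "==") * 1
  }
  S_rec <- if (model$permanent_env) {
    if (model$random == "identity") A_rec
    else outer(prep$anim, prep$anim, "==") * 1
  } else NULL

  env <- make_lik_env(prep, model, A_rec, S_rec)
  m <- env$m
  vary <- stats::var(stats::lm.fit(prep$X, prep$y)$residuals)
  floor_e <- 1e-8 * vary
  theta <- if (is.null(start)) {
    c(if (env$nk) sym_to_vech(diag(0.5 * vary / m, m)),
      if (env$npe) 0.1 * vary,
      rep(0.5 * vary, env$ne))
  } else {
    c(if (env$nk) sym_to_vech(start$K),
      if (env$npe) start$sigma2_pe,
      rep_len(start$sigma2_e, env$ne))
  }
  names(theta) <- env$theta_names

  sanitize <- function(theta) {
    bent <- FALSE
    if (env$nk) {
      b <- bend_psd(vech_to_sym(theta[seq_len(env$nk)], m))
      if (b$bent) bent <- TRUE
      theta[seq_len(env$nk)] <- sym_to_vech(b$K)
    }
    if (env$npe) theta[env$nk + 1L] <- max(theta[env$nk + 1L], floor_e)
    ix <- (env$nk + env$npe + 1L):length(theta)
    theta[ix] <- pmax(theta[ix], floor_e)
    list(theta = theta, bent = bent)
  }
  theta <- sanitize(theta)$theta

  cur <- lik_eval(theta, env, prep, model, A_rec, S_rec, derivs = TRUE)
  if (!is.finite(cur$loglik))
    stop("starting values give a non-finite restricted likelihood")
  ## The Newton update is taken in Cholesky coordinates of K (K = LL',
  ## psi = lower-triangle of L): the PSD constraint disappears, so optima
  ## on or near the cone boundary (nearly singular K) are reached without
  ## bending or step collapse.  Score and average information transform by
  ## the Jacobian J = d vech(K) / d psi.
  lpairs <- if (env$nk) {
    out <- NULL
    for (b in seq_len(m)) for (a in b:m) out <- rbind(out, c(a, b))
    out
  } else NULL
  theta_to_psi <- function(theta) {
    if (!env$nk) return(theta)
    K <- vech_to_sym(theta[seq_len(env$nk)], m)
    L <- t(chol(bend_psd(K, 1e-10)$K + 1e-12 * mean(diag(K)) * diag(m)))
    c(vapply(seq_len(env$nk), function(i)
      L[lpairs[i, 1], lpairs[i, 2]], numeric(1)),
      theta[-seq_len(env$nk)])
  }
  psi_to_theta <- function(psi) {
    if (!env$nk) return(psi)
    L <- matrix(0, m, m)
    for (i in seq_len(env$nk)) L[lpairs[i, 1], lpairs[i, 2]] <- psi[i]
    stats::setNames(c(sym_to_vech(tcrossprod(L)),
                      psi[-seq_len(env$nk)]), env$theta_names)
  }
  psi_jacobian <- function(psi) {
    q <- length(psi)
    J <- diag(q)
    if (!env$nk) return(J)
    L <- matrix(0, m, m)
    for (i in seq_len(env$nk)) L[lpairs[i, 1], lpairs[i, 2]] <- psi[i]
    for (i in seq_len(env$nk)) {        # theta index: K[kp[i,1], kp[i,2]]
      a <- env$kp[i, 1]; b <- env$kp[i, 2]
      for (j in seq_len(env$nk)) {      # psi index: L[lpairs[j,]]
        r <- lpairs[j, 1]; cidx <- lpairs[j, 2]
        ## d (L L')_{ab} / d L_{r c} = delta_{ar} L_{bc} + delta_{br} L_{ac}
        J[i, j] <- (a == r) * L[b, cidx] + (b == r) * L[a, cidx]
      }
    }
    J
  }

  psi <- theta_to_psi(theta)
  theta <- psi_to_theta(psi)
  trace <- data.frame(iter = 0L, loglik = cur$loglik)
  converged <- FALSE
  iter <- 0L
  stalled <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- psi_jacobian(psi)
    score_psi <- drop(crossprod(J, cur$score))
    AI_psi <- crossprod(J, cur$AI %*% J)
    if (env$nk) {
      ## curvature of the K = LL' map: -Hess_psi = J' AI J - sum_i
      ## score_i d2K_i/dpsi2, with d2 K_{ab} / dL_{rc} dL_{sd} =
      ## delta_{cd} (delta_{ar} delta_{bs} + delta_{as} delta_{br});
      ## essential near the PSD boundary where the score is large
      Cmat <- matrix(0, length(psi), length(psi))
      for (i in seq_len(env$nk)) {
        a <- env$kp[i, 1]; b <- env$kp[i, 2]
        for (j in seq_len(env$nk)) {
          r <- lpairs[j, 1]; cj <- lpairs[j, 2]
          for (k in seq_len(env$nk)) {
            s2 <- lpairs[k, 1]; ck <- lpairs[k, 2]
            if (cj == ck) {
              Cmat[j, k] <- Cmat[j, k] + cur$score[i] *
                ((a == r) * (b == s2) + (a == s2) * (b == r))
            }
          }
        }
      }
      AI_psi <- AI_psi - Cmat
    }
    ## Candidate ascent directions, in order: exact-curvature Newton (only
    ## when that matrix is positive definite — it can be indefinite away
    ## from the optimum), the Gauss-Newton transform of the average
    ## information, its Levenberg-Marquardt damped versions, and finally
    ## the scaled gradient.  Line searches use cheap (derivative-free)
    ## likelihood evaluations; only genuinely improving steps are
    ## accepted, so the trace is strictly monotone.
    gain_tol <- max(0.1 * tol_loglik, 1e-13 * max(1, abs(cur$loglik)))
    GN <- crossprod(J, cur$AI %*% J)
    dscale <- pmax(abs(diag(GN)), 1e-8 * max(abs(diag(GN)), 1))
    dirs <- list()
    ch1 <- tryCatch(chol(AI_psi), error = function(e) NULL)
    if (!is.null(ch1))
      dirs <- c(dirs, list(backsolve(ch1, forwardsolve(t(ch1), score_psi))))
    for (lam in c(0, 1e-4, 1e-2, 1, 100)) {
      AIr <- GN + (lam + 1e-10) * diag(dscale, length(psi))
      d <- tryCatch(solve(AIr, score_psi), error = function(e) NULL)
      if (!is.null(d) && sum(d * score_psi) > 0)
        dirs <- c(dirs, list(d))
    }
    dirs <- c(dirs, list(score_psi / max(dscale)))
    improved <- FALSE
    full_step <- FALSE
    for (di in seq_along(dirs)) {
      delta <- dirs[[di]]
      step <- 1
      for (h in 1:8) {
        cand_psi <- psi + step * delta
        cand <- sanitize(psi_to_theta(cand_psi))
        new <- lik_eval(cand$theta, env, prep, model, A_rec, S_rec,
                        derivs = FALSE)
        if (is.finite(new$loglik) && new$loglik > cur$loglik + gain_tol) {
          improved <- TRUE
          full_step <- (di == 1L && step == 1)
          break
        }
        step <- step / 2
      }
      if (improved) break
    }
    if (!improved) {
      ## no candidate direction yields genuine ascent: stationary point
      converged <- TRUE
      break
    }
    new <- lik_add_derivs(new, env, prep, model, A_rec, S_rec)
    dll <- new$loglik - cur$loglik
    dpar <- max(abs(cand$theta - theta) / pmax(abs(theta), floor_e))
    psi <- theta_to_psi(cand$theta)
    theta <- psi_to_theta(psi)
    cur <- new
    trace <- rbind(trace, data.frame(iter = iter, loglik = cur$loglik))
    if (verbose)
      telo_log("info", sprintf("iter %d logL %.8f dll %.2e dpar %.2e",
                               iter, cur$loglik, dll, dpar))
    if (abs(dll) < tol_loglik && dpar < tol_param) {
      ## a damped/halved step can make tiny progress without being at the
      ## optimum; only full Newton steps (or a persistent stall) count
      stalled <- stalled + 1L
      if (full_step || stalled >= 3L) {
        converged <- TRUE
        break
      }
    } else {
      stalled <- 0L
    }
  }
  if (!converged) {
    tail_tr <- utils::tail(trace, 5L)
    stop("AI-REML did not converge in ", max_iter,
         " iterations; last restricted log-likelihoods: ",
         paste(sprintf("%.6f", tail_tr$loglik), collapse = ", "))
  }

  th <- env$split_theta(theta)
  s2e <- th$s2e
  if (!is.null(prep$rcuts)) attr(s2e, "cuts") <- prep$rcuts
  theta_cov <- tryCatch(solve(cur$AI), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  dimnames(theta_cov) <- list(env$theta_names, env$theta_names)
  n_theta <- length(theta)
  aic <- if (model$likelihood == "reml") {
    -2 * cur$loglik + 2 * n_theta
  } else {
    -2 * cur$loglik + 2 * (n_theta + ncol(prep$X))
  }

  fit <- structure(list(
    beta = stats::setNames(cur$beta, colnames(prep$X)),
    beta_cov = structure(cur$beta_cov,
                         dimnames = list(colnames(prep$X),
                                         colnames(prep$X))),
    u = NULL, pe = NULL, pev = NULL, se_beta = NULL,
    varcomp = list(K = th$K, sigma2_pe = if (env$npe) th$s2pe else NULL,
                   sigma2_e = s2e),
    theta = theta, theta_cov = theta_cov, theta_names = env$theta_names,
    loglik = cur$loglik, aic = aic, n_theta = n_theta,
    converged = converged, iterations = iter, trace = trace,
    basis = basis, model = model,
    phen_animals = prep$phen_animals, n = env$n, p = ncol(prep$X)),
    class = "rrm_fit")

  if (solutions) {
    a_inv <- if (model$random == "pedigree") ainverse(ped) else NULL
    mme <- build_mme(data, model, basis, a_inv, K = th$K,
                     sigma2_e = th$s2e,
                     sigma2_pe = if (env$npe) th$s2pe else 0)
    sol <- as.vector(Matrix::solve(mme$C, mme$rhs))
    pf <- sum(mme$layout$block == "fixed")
    N <- length(mme$animals)
    fit$beta <- stats::setNames(sol[seq_len(pf)],
                                mme$layout$label[seq_len(pf)])
    um <- matrix(sol[pf + seq_len(N * (m))], N, m, byrow = TRUE,
                 dimnames = list(mme$animals, paste0("phi", 0:(m - 1L))))
    fit$u <- um
    if (env$npe) {
      fit$pe <- stats::setNames(utils::tail(sol, length(prep$phen_animals)),
                                prep$phen_animals)
    }
    if (pev) {
      Ci <- as.matrix(Matrix::solve(mme$C))
      fit$se_beta <- sqrt(pmax(diag(Ci)[seq_len(pf)], 0))
      pevs <- vector("list", N)
      names(pevs) <- mme$animals
      for (j in seq_len(N)) {
        ix <- pf + (j - 1L) * m + seq_len(m)
        pevs[[j]] <- Ci[ix, ix, drop = FALSE]
      }
      fit$pev <- pevs
    }
  }
  fit
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat("Random regression animal model fit (", x$model$likelihood, ")\n",
      sep = "")
  cat(sprintf("  records: %d, fixed effects: %d, logL: %.4f, AIC: %.2f\n",
              x$n, x$p, x$loglik, x$aic))
  if (!is.null(x$varcomp$K)) {
    cat("  K (genetic coefficient covariance):\n")
    print(round(x$varcomp$K, 6))
  }
  if (!is.null(x$varcomp$sigma2_pe))
    cat(sprintf("  sigma2_pe: %.6f\n", x$varcomp$sigma2_pe))
  cat(sprintf("  sigma2_e: %s\n",
              paste(sprintf("%.6f", x$varcomp$sigma2_e), collapse = ", ")))
  invisible(x)
}

#' Backward elimination of candidate fixed effects
#'
#' Iteratively refits the model, each round removing the least significant
#' candidate whose conditional Wald F-test p-value is at or above
#' \code{alpha}; mandatory effects (the model's \code{fixed_factors} and
#' the age regression) are never removed.  Candidates aliased with the
#' retained design are flagged and removed first.
#'
#' @param data Phenotype data frame.
#' @param ped Pedigree (or \code{NULL} for non-pedigree models).
#' @param model An \code{\link{rrm_model}}; its \code{covariates} are the
#'   candidates.
#' @param alpha Retention threshold (default 0.05).
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return List: \code{model} (final \code{rrm_model}), \code{fit} (final
#'   fit), \code{trace} (data frame of removals with p-values).
#' @export
backward_eliminate <- function(data, ped = NULL, model = rrm_model(),
                               alpha = 0.05, ...) {
  cand <- model$covariates
  trace <- data.frame(removed = character(), p_value = numeric(),
                      reason = character(), stringsAsFactors = FALSE)
  repeat {
    ## aliased candidates go first
    if (length(cand)) {
      basis_probe <- legendre_basis(model$order_fixed,
                                    min(data$age_months),
                                    max(data$age_months))
      keep_model <- utils::modifyList(model, list(covariates = character()))
      X0 <- build_design(data, keep_model, basis_probe)
      aliased <- cand[vapply(cand, function(cv) {
        qr(cbind(X0, as.numeric(data[[cv]])))$rank == ncol(X0)
      }, logical(1))]
      if (length(aliased)) {
        telo_log("warn", "candidate aliased with retained design, removed: ",
                 aliased[1L])
        trace <- rbind(trace, data.frame(removed = aliased[1L],
                                         p_value = NA_real_,
                                         reason = "aliased"))
        cand <- setdiff(cand, aliased[1L])
        next
      }
    }
    model$covariates <- cand
    fit <- fit_reml(data, ped, model, solutions = FALSE, ...)
    if (!length(cand)) return(list(model = model, fit = fit, trace = trace))
    pvals <- vapply(cand, function(cv) {
      ix <- match(cv, names(fit$beta))
      w <- fit$beta[ix]^2 / fit$beta_cov[ix, ix]
      stats::pf(w, 1, fit$n - fit$p, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] < alpha)
      return(list(model = model, fit = fit, trace = trace))
    trace <- rbind(trace, data.frame(removed = cand[worst],
                                     p_value = unname(pvals[worst]),
                                     reason = "non-significant"))
    cand <- cand[-worst]
  }
}

#' Rank fitted models by AIC with the two-unit parsimony rule
#'
#' Models must share the same data and fixed-effect structure (REML
#' likelihoods are not comparable otherwise).  The preferred model is the
#' simplest (fewest variance parameters) within two AIC units of the
#' minimum.
#'
#' @param fits Named list of \code{rrm_fit} objects.
#' @return Data frame ranked by AIC with \code{delta_aic} and a logical
#'   \code{preferred} column (exactly one TRUE).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ref <- fits[[1L]]
  for (f in fits[-1L]) {
    if (f$n != ref$n)
      stop("models were fitted to different data; AIC not comparable")
    if (ref$model$likelihood == "reml" &&
        !identical(sort(names(f$beta)), sort(names(ref$beta))))
      stop("REML likelihoods are only comparable across models sharing ",
           "the fixed-effect structure; refit with likelihood = \"ml\" ",
           "to compare different fixed structures")
  }
  df <- data.frame(
    model = names(fits),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_varparams = vapply(fits, `[[`, numeric(1), "n_theta"),
    stringsAsFactors = FALSE)
  df$delta_aic <- df$aic - min(df$aic)
  within2 <- which(df$delta_aic <= 2)
  pref <- within2[order(df$n_varparams[within2], df$aic[within2])][1L]
  df$preferred <- seq_len(nrow(df)) == pref
  df <- df[order(df$aic), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Test residual variance heterogeneity across age classes
#'
#' Fits the model with homogeneous residual variance and with one residual
#' variance per age class, and reports the AIC difference and a
#' likelihood-ratio statistic with (number of classes - 1) degrees of
#' freedom.  Classes with fewer than 10 records are merged with their
#' neighbour (with a warning).
#'
#' @param data Phenotype data frame.
#' @param ped Pedigree (for pedigree models).
#' @param model Base \code{\link{rrm_model}} (its \code{residual_cuts} are
#'   ignored).
#' @param age_cuts Increasing cut points (months) defining the classes,
#'   e.g. \code{c(12, 24, 40)} for four groups.
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return List: \code{homogeneous}, \code{heterogeneous} (fits),
#'   \code{delta_aic} (homogeneous minus heterogeneous), \code{lrt}
#'   (statistic, df, p), \code{preferred}.
#' @export
test_residual_heterogeneity <- function(data, ped = NULL,
                                        model = rrm_model(), age_cuts,
                                        ...) {
  mh <- utils::modifyList(model, list(residual_cuts = NULL))
  class(mh) <- "rrm_model"
  fit_h <- fit_reml(data, ped, mh, solutions = FALSE, ...)
  mv <- utils::modifyList(model, list(residual_cuts = age_cuts))
  class(mv) <- "rrm_model"
  fit_v <- fit_reml(data, ped, mv, solutions = FALSE, ...)
  df <- fit_v$n_theta - fit_h$n_theta
  if (df == 0L) {
    lrt <- list(statistic = 0, df = 0L, p_value = 1)
  } else {
    stat <- max(0, 2 * (fit_v$loglik - fit_h$loglik))
    lrt <- list(statistic = stat, df = df,
                p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  delta <- fit_h$aic - fit_v$aic
  list(homogeneous = fit_h, heterogeneous = fit_v,
       delta_aic = delta, lrt = lrt,
       preferred = if (delta > 2) "heterogeneous" else "homogeneous")
}
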