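## Quieter logging during tests (warnings and errors still surface).
options(telotraj.log_level = "warn")

## Independent oracles shared across test files.  These deliberately avoid
## the package's own computational paths: dense textbook formulas, brute
## force enumeration, and generic optimisers.

## Direct restricted log-likelihood for a random regression animal model,
## computed from the dense V = A_rec * (Phi K Phi') + sigma2_e I formula.
oracle_reml_loglik <- function(K, s2e, y, X, Phi, Arec) {
  n <- length(y); p <- ncol(X)
  V <- Arec * (Phi %*% K %*% t(Phi))
  diag(V) <- diag(V) + s2e
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(-Inf)
  Vi <- chol2inv(cv)
  VX <- Vi %*% X
  XtViX <- crossprod(X, VX)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(-Inf)
  beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Vi %*% y)))
  Py <- Vi %*% y - VX %*% beta
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(cv))) +
            2 * sum(log(diag(cx))) + sum(y * Py))
}

## Derivative-free REML maximisation for an order-1 model via Nelder-Mead
## on a log-Cholesky parameterisation (independent of the AI-REML path).
oracle_reml_fit_order1 <- function(d, ped, basis, factors) {
  Phi <- basis_matrix(d$age_months, basis)
  X <- Phi
  for (f in factors) {
    mm <- stats::model.matrix(~ factor(d[[f]]))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  A <- amatrix(ped)
  ix <- match(d$animal_id, ped$id)
  Arec <- A[ix, ix]
  y <- d$log_rltl
  negll <- function(par) {
    L <- matrix(0, 2, 2)
    L[1, 1] <- exp(par[1]); L[2, 1] <- par[2]; L[2, 2] <- exp(par[3])
    K <- tcrossprod(L)
    ll <- oracle_reml_loglik(K, exp(par[4]), y, X, Phi, Arec)
    if (!is.finite(ll)) 1e10 else -ll
  }
  vy <- stats::var(stats::lm.fit(X, y)$residuals)
  start <- c(log(sqrt(0.5 * vy / 2)), 0, log(sqrt(0.5 * vy / 2)),
             log(0.5 * vy))
  o <- stats::optim(start, negll, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, negll, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  L <- matrix(0, 2, 2)
  L[1, 1] <- exp(o$par[1]); L[2, 1] <- o$par[2]; L[2, 2] <- exp(o$par[3])
  K <- tcrossprod(L)
  list(loglik = -o$value,
       theta = c(K[1, 1], K[1, 2], K[2, 2], exp(o$par[4])))
}

## Breslow partial log-likelihood for one binary covariate, maximised by
## a generic 1-D optimiser.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

oracle_cox_fit <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, x),
                  c(lower, upper), tol = 1e-10)$minimum
}

## Brute-force discrete Frechet distance: enumerate all monotone couplings
## (tiny grids only).
oracle_frechet <- function(ax, ay, bx, by) {
  n <- length(ax); m <- length(bx)
  d <- function(i, j) sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
  best <- Inf
  walk <- function(i, j, cur) {
    cur <- max(cur, d(i, j))
    if (cur >= best) return()
    if (i == n && j == m) { best <<- cur; return() }
    if (i < n) walk(i + 1L, j, cur)
    if (i < n && j < m) walk(i + 1L, j + 1L, cur)
    if (j < m) walk(i, j + 1L, cur)
  }
  walk(1L, 1L, 0)
  best
}

## Adjusted Rand index between two labelings (direct contingency formula).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

## Small phenotype simulation used by several REML tests.
tiny_rrm_data <- function(seed, n_animals = 30, order = 1,
                          K = matrix(c(0.03, 0.005, 0.005, 0.004), 2),
                          s2e = 0.015) {
  ped <- simulate_pedigree(10, 3, 3, seed = seed)
  basis <- legendre_basis(order, 0, 60)
  truth <- simulation_truth(
    K_true = K, sigma2_e_true = s2e, basis = basis,
    fixed_regression = c(0.1, -0.03, 0.01)[seq_len(order + 1)],
    fixed_effect_values = list(birth_year = c(a = 0.01, b = -0.01),
                               genetic_group = c(g1 = 0, g2 = 0.02)))
  ids <- ped$id[ped$generation > 0]
  ids <- ids[seq_len(min(n_animals, length(ids)))]
  sched <- default_schedule(ids, seed = seed + 1000L)
  sim <- simulate_rr_phenotypes(ped, truth, sched, seed = seed + 2000L)
  list(data = sim$phenotypes, ped = ped, basis = basis, truth = sim$truth)
}
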