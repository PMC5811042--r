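## Minimal hand-built fit object for the pure-algebra operations.
fake_fit <- function(K, s2e = 0.01, b = NULL, u = NULL, pev = NULL,
                     order_fixed = nrow(K) - 1L, t_max = 60) {
  m <- nrow(K)
  basis <- legendre_basis(m - 1L, 0, t_max)
  theta <- c(sym_to_vech_test(K), s2e)
  if (is.null(b)) b <- numeric(order_fixed + 1L)
  names(b) <- paste0("phi", 0:order_fixed)
  structure(list(
    beta = b,
    beta_cov = diag(0, length(b),
                    length(b)) |> `dimnames<-`(list(names(b), names(b))),
    u = u, pev = pev, phen_animals = rownames(u),
    varcomp = list(K = K, sigma2_pe = NULL, sigma2_e = s2e),
    theta = theta, theta_cov = diag(1e-12, length(theta)),
    basis = basis,
    model = list(order_fixed = order_fixed, order_random = m - 1L),
    n = 10L, p = length(b)), class = "rrm_fit")
}

sym_to_vech_test <- function(K) {
  out <- numeric(0)
  for (a in seq_len(nrow(K))) for (b in a:nrow(K)) out <- c(out, K[a, b])
  out
}

test_that("fixed curve reduces to its closed forms", {
  K <- diag(3) * 0.01
  f0 <- fake_fit(K, b = c(0, 0, 0))
  expect_equal(fixed_curve(f0)$value, rep(0, 61))
  f1 <- fake_fit(K, b = c(1, 0, 0))
  expect_equal(fixed_curve(f1)$value, rep(sqrt(1 / 2), 61))
  f2 <- fake_fit(K, b = c(0, 1, 0))
  fc <- fixed_curve(f2)
  expect_equal(fc$value[fc$age_month == 30], 0, tolerance = 1e-12)
  expect_equal(fc$value, -rev(fc$value), tolerance = 1e-12)  # odd in x
  expect_error(fixed_curve(f1, grid = c(-5, 70)), "out of basis bounds")
})

test_that("animal profiles follow their coefficients and PEV", {
  K <- diag(2) * 0.01
  u <- rbind(A1 = c(0, 0), A2 = c(0.3, 0))
  pev <- list(A1 = diag(2), A2 = diag(2))
  f <- fake_fit(K, u = u, pev = pev, order_fixed = 1)
  pr <- animal_profiles(f)
  expect_equal(pr$A1$value, rep(0, 61))
  expect_equal(pr$A2$value, rep(0.3 * sqrt(1 / 2), 61))
  ## PEV = I: SE(t) = sqrt(sum_k phi_k(t)^2)
  Phi <- basis_matrix(0:60, f$basis)
  expect_equal(pr$A1$se, sqrt(rowSums(Phi^2)), tolerance = 1e-12)
  expect_error(animal_profiles(f, animal_ids = "nope"), "unknown animal")
})

test_that("additive variance is the K quadratic form of the basis row", {
  basis <- legendre_basis(2, 0, 60)
  expect_equal(additive_variance(matrix(0, 3, 3), basis)$value,
               rep(0, 61))
  va_i <- additive_variance(diag(3), basis)
  Phi <- basis_matrix(0:60, basis)
  expect_equal(va_i$value, rowSums(Phi^2), tolerance = 1e-12)
  va_d <- additive_variance(diag(c(1, 0, 0)), basis)
  expect_equal(va_d$value, rep(0.5, 61), tolerance = 1e-12)
  expect_error(additive_variance(diag(2), basis), "dimension")
})

test_that("heritability hits its closed-form special cases", {
  ## V_A(t) = sigma2_e with no PE: h2 = 0.5 everywhere
  f <- fake_fit(diag(c(0.02, 0, 0)), s2e = 0.01)
  h <- heritability(f)
  expect_equal(h$value, rep(0.5, 61), tolerance = 1e-10)
  f0 <- fake_fit(matrix(0, 3, 3), s2e = 0.01)
  expect_equal(heritability(f0)$value, rep(0, 61))
  expect_true(all(h$value >= 0 & h$value <= 1))
})

test_that("genetic correlation satisfies its identities", {
  basis <- legendre_basis(2, 0, 60)
  ## flat curves (order-0 variance only) are perfectly correlated
  r <- genetic_correlation(diag(c(1, 0, 0)) + 1e-12 * diag(3), basis)
  expect_equal(r$value, rep(1, 61), tolerance = 1e-5)
  ## K = I: correlation is the cosine of the two basis rows
  rI <- genetic_correlation(diag(3), basis)
  p0 <- basis_row(0, basis)
  Phi <- basis_matrix(0:60, basis)
  cosine <- drop(Phi %*% p0) / sqrt(sum(p0^2) * rowSums(Phi^2))
  expect_equal(rI$value, cosine, tolerance = 1e-12)
  expect_equal(rI$value[1], 1)             # r(t0, t0) = 1
  expect_error(genetic_correlation(matrix(0, 3, 3), basis),
               "zero additive variance")
})

test_that("correlations are bounded and V_A reconstruction is exact", {
  basis <- legendre_basis(2, 0, 60)
  set.seed(7)
  grid <- seq(0, 60, by = 5)
  for (i in 1:50) {
    L <- matrix(rnorm(9), 3)
    K <- crossprod(L)
    r <- genetic_correlation(K, basis, grid = grid)
    expect_true(all(abs(r$value) <= 1 + 1e-12))
    ei <- eigen_analysis(K, basis, grid = grid)
    va <- additive_variance(K, basis, grid = grid)$value
    recon <- drop(ei$functions^2 %*% ei$values)
    expect_lt(max(abs(recon - va)), 1e-10)
    expect_equal(sum(ei$percent), 100, tolerance = 1e-9)
  }
})

test_that("eigen decomposition reports variance shares and shapes", {
  basis <- legendre_basis(1, 0, 60)
  ei <- eigen_analysis(diag(c(3, 1)), basis)
  expect_equal(ei$percent, c(75, 25))
  ei2 <- eigen_analysis(diag(2), basis)
  expect_equal(ei2$percent, c(50, 50))
  ## intercept-dominated K: leading eigenfunction approximately constant
  K <- diag(c(1, 1e-4))
  ei3 <- eigen_analysis(K, basis)
  lead <- ei3$functions[, 1]
  expect_lt(stats::sd(lead) / abs(mean(lead)), 1e-3)
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  ## moderate n so the variance parameters are in their asymptotic regime
  basis <- legendre_basis(1, 0, 60)
  ped <- simulate_herd_pedigree(180, n_sires = 18, n_dams = 72, seed = 81)
  truth <- simulation_truth(
    K_true = matrix(c(0.03, 0.005, 0.005, 0.006), 2),
    sigma2_e_true = 0.015, basis = basis,
    fixed_regression = c(0.1, -0.03),
    fixed_effect_values = list(birth_year = c(a = 0.01, b = -0.01),
                               genetic_group = c(g1 = 0, g2 = 0.02)))
  sched <- default_schedule(attr(ped, "phenotyped"), seed = 82)
  sim <- simulate_rr_phenotypes(ped, truth, sched, seed = 83)
  tl <- list(data = sim$phenotypes, ped = ped, basis = basis)
  model <- rrm_model(order_fixed = 1, order_random = 1,
                     fixed_factors = c("birth_year", "genetic_group"))
  fit <- fit_reml(tl$data, tl$ped, model, basis = tl$basis,
                  solutions = FALSE)
  grid <- c(0, 30, 60)
  h <- heritability(fit, grid = grid)
  ## bootstrap oracle: resample variance parameters from their asymptotic
  ## normal and recompute h2(t) directly
  set.seed(42)
  ch <- chol(fit$theta_cov + 1e-12 * diag(length(fit$theta)))
  Phi <- basis_matrix(grid, tl$basis)
  draws <- t(replicate(400, {
    th <- fit$theta + drop(rnorm(length(fit$theta)) %*% ch)
    K <- matrix(c(th[1], th[2], th[2], th[3]), 2)
    va <- rowSums((Phi %*% K) * Phi)
    va / (va + th[4])
  }))
  boot_se <- apply(draws, 2, stats::sd)
  expect_lt(max(abs(h$se - boot_se) / boot_se), 0.2)
})

test_that("trajectory constructor enforces its invariants", {
  expect_error(trajectory(c(0, 0, 1), 1:3, kind = "profile"),
               "strictly increasing")
  expect_error(trajectory(0:2, 1:3, se = -1, kind = "profile"), ">= 0")
  tr <- trajectory(0:2, c(1, 2, 3), kind = "fixed_curve")
  expect_s3_class(tr, "trajectory")
})
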