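test_that("mixed-model equations match the hand-assembled 2x2 system", {
  ## one animal, one record, order-0 fixed and random regressions
  d <- data.frame(animal_id = "A", age_months = 30, log_rltl = 0.4)
  model <- rrm_model(order_fixed = 0, order_random = 0,
                     fixed_factors = character(), random = "identity")
  basis <- legendre_basis(0, 0, 60)
  K <- matrix(0.2, 1, 1); s2e <- 0.5
  mme <- build_mme(d, model, basis, NULL, K = K, sigma2_e = s2e)
  z <- sqrt(1 / 2)                      # phi_0 under the normalised basis
  C <- as.matrix(mme$C)
  expect_equal(C, matrix(c(z^2 / s2e, z^2 / s2e,
                           z^2 / s2e, z^2 / s2e + 1 / 0.2), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(mme$rhs, c(z * 0.4 / s2e, z * 0.4 / s2e),
               tolerance = 1e-12)
})

test_that("duplicated records double the data part of the equations", {
  d1 <- data.frame(animal_id = "A", age_months = 30, log_rltl = 0.4)
  d2 <- rbind(d1, d1)
  model <- rrm_model(order_fixed = 0, order_random = 0,
                     fixed_factors = character(), random = "identity")
  basis <- legendre_basis(0, 0, 60)
  K <- matrix(0.2, 1, 1)
  m1 <- build_mme(d1, model, basis, NULL, K = K, sigma2_e = 0.5)
  m2 <- build_mme(d2, model, basis, NULL, K = K, sigma2_e = 0.5)
  Ginv <- matrix(0, 2, 2); Ginv[2, 2] <- 1 / 0.2
  expect_equal(as.matrix(m2$C) - Ginv, 2 * (as.matrix(m1$C) - Ginv),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$rhs, 2 * m1$rhs, tolerance = 1e-12)
})

test_that("animals without phenotypes enter through the pedigree only", {
  ped <- pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
  d <- data.frame(animal_id = c("S", "D"), age_months = c(10, 20),
                  log_rltl = c(0.1, 0.2))
  model <- rrm_model(order_fixed = 0, order_random = 0,
                     fixed_factors = character())
  basis <- legendre_basis(0, 0, 60)
  K <- matrix(0.3, 1, 1)
  mme <- build_mme(d, model, basis, ainverse(ped), K = K, sigma2_e = 0.4)
  expect_equal(mme$animals, ped$id)
  ## offspring O has no records: its row is pure A^-1 (x) K^-1
  C <- as.matrix(mme$C)
  o <- 1 + match("O", mme$animals)      # 1 fixed equation first
  Ainv <- as.matrix(ainverse(ped))
  expect_equal(C[o, 1], 0)
  expect_equal(C[o, 1 + seq_len(3)],
               Ainv["O", ] / 0.3, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fixed-effects-only fit reproduces ordinary least squares", {
  tl <- tiny_rrm_data(seed = 21)
  model <- rrm_model(order_fixed = 1, random = "none",
                     fixed_factors = c("birth_year", "genetic_group"))
  fit <- fit_reml(tl$data, model = model, basis = tl$basis)
  X <- cbind(basis_matrix(tl$data$age_months,
                          legendre_basis(1, 0, 60)),
             stats::model.matrix(~ factor(tl$data$birth_year) +
                                   factor(tl$data$genetic_group))[, -1])
  ls <- stats::lm.fit(X, tl$data$log_rltl)
  expect_equal(unname(fit$beta), unname(ls$coefficients),
               tolerance = 1e-10)
  n <- nrow(tl$data); p <- ncol(X)
  expect_equal(unname(fit$varcomp$sigma2_e),
               sum(ls$residuals^2) / (n - p), tolerance = 1e-10)
})

test_that("AI-REML matches the derivative-free restricted-likelihood oracle", {
  tl <- tiny_rrm_data(seed = 31)
  model <- rrm_model(order_fixed = 1, order_random = 1,
                     fixed_factors = c("birth_year", "genetic_group"))
  fit <- fit_reml(tl$data, tl$ped, model, basis = tl$basis,
                  tol_loglik = 1e-10, tol_param = 1e-8, solutions = FALSE)
  oracle <- oracle_reml_fit_order1(tl$data, tl$ped, tl$basis,
                                   c("birth_year", "genetic_group"))
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-6)
  expect_lt(max(abs(fit$theta - oracle$theta) /
                  pmax(abs(oracle$theta), 1e-8)), 1e-4)
  ## restricted logL never decreased across accepted iterations
  expect_true(all(diff(fit$trace$loglik) >= -1e-10))
})

test_that("pure-noise data drives the genetic fraction to the boundary", {
  set.seed(5)
  n <- 100
  d <- data.frame(animal_id = rep(paste0("A", 1:n), each = 3),
                  age_months = rep(c(0, 20, 40), n),
                  log_rltl = rnorm(3 * n, 0, 0.1))
  model <- rrm_model(order_fixed = 0, order_random = 0,
                     fixed_factors = character(), random = "identity")
  fit <- fit_reml(d, model = model, solutions = FALSE)
  frac <- fit$varcomp$K[1, 1] /
    (fit$varcomp$K[1, 1] + fit$varcomp$sigma2_e)
  expect_lt(frac, 0.05)
})

test_that("restricted likelihood is invariant to record ordering", {
  tl <- tiny_rrm_data(seed = 41, n_animals = 15)
  model <- rrm_model(order_fixed = 1, order_random = 1,
                     fixed_factors = c("birth_year", "genetic_group"))
  f1 <- fit_reml(tl$data, tl$ped, model, basis = tl$basis,
                 solutions = FALSE)
  set.seed(1)
  perm <- sample.int(nrow(tl$data))
  f2 <- fit_reml(tl$data[perm, ], tl$ped, model, basis = tl$basis,
                 solutions = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
})

test_that("BLUP solutions shrink to zero as residual variance dominates", {
  tl <- tiny_rrm_data(seed = 51, n_animals = 12)
  model <- rrm_model(order_fixed = 1, order_random = 1,
                     fixed_factors = character())
  basis <- tl$basis
  K <- matrix(c(0.03, 0, 0, 0.004), 2)
  solve_u <- function(s2e) {
    mme <- build_mme(tl$data, model, basis, ainverse(tl$ped), K = K,
                     sigma2_e = s2e)
    sol <- as.vector(Matrix::solve(mme$C, mme$rhs))
    sol[-seq_len(sum(mme$layout$block == "fixed"))]
  }
  expect_lt(max(abs(solve_u(1e6))), 1e-5)
  ## as sigma2_e -> 0 fitted values approach observations, provided each
  ## animal's curve can interpolate its records (2 records, 2 coefficients)
  set.seed(99)
  d2 <- do.call(rbind, lapply(tl$ped$id[1:8], function(a)
    data.frame(animal_id = a, age_months = c(5, 50),
               log_rltl = rnorm(2, 0.1, 0.2))))
  mme <- build_mme(d2, model, basis, ainverse(tl$ped), K = K,
                   sigma2_e = 1e-10)
  sol <- as.vector(Matrix::solve(mme$C, mme$rhs))
  p <- sum(mme$layout$block == "fixed")
  Phi <- basis_matrix(d2$age_months, basis)
  aix <- match(d2$animal_id, mme$animals)
  u <- matrix(sol[-seq_len(p)], ncol = 2, byrow = TRUE)
  fitted <- drop(basis_matrix(d2$age_months,
                              legendre_basis(1, 0, 60)) %*% sol[1:2]) +
    rowSums(Phi * u[aix, ])
  expect_lt(max(abs(fitted - d2$log_rltl)), 1e-4)
})

test_that("permanent environment is recovered when present, floored when absent", {
  basis <- legendre_basis(1, 0, 60)
  ped <- simulate_herd_pedigree(150, n_sires = 15, n_dams = 60, seed = 61)
  cows <- attr(ped, "phenotyped")
  truth <- simulation_truth(
    K_true = matrix(c(0.03, 0.004, 0.004, 0.005), 2),
    sigma2_e_true = 0.012, sigma2_pe_true = 0.02, basis = basis,
    fixed_regression = c(0.1, -0.03),
    fixed_effect_values = list(birth_year = c(a = 0.01, b = -0.01),
                               genetic_group = c(g1 = 0, g2 = 0.02)))
  sched <- default_schedule(cows, seed = 62)
  sim <- simulate_rr_phenotypes(ped, truth, sched, seed = 63)
  model <- rrm_model(order_fixed = 1, order_random = 1,
                     fixed_factors = c("birth_year", "genetic_group"),
                     permanent_env = TRUE)
  fit <- fit_reml(sim$phenotypes, ped, model, basis = basis,
                  solutions = FALSE)
  se_pe <- sqrt(fit$theta_cov["sigma2_pe", "sigma2_pe"])
  expect_lt(abs(fit$varcomp$sigma2_pe - 0.02), 3 * se_pe)

  truth0 <- truth; truth0$sigma2_pe_true <- 0
  sim0 <- simulate_rr_phenotypes(ped, truth0, sched, seed = 64)
  fit0 <- fit_reml(sim0$phenotypes, ped, model, basis = basis,
                   solutions = FALSE)
  vy <- stats::var(sim0$phenotypes$log_rltl)
  expect_lt(fit0$varcomp$sigma2_pe, 0.1 * vy)
})

test_that("backward elimination removes null candidates and honours aliasing", {
  gen_d <- function(seed) {
    set.seed(seed)
    n <- 500
    d <- data.frame(animal_id = paste0("A", seq_len(n)),
                    age_months = sample(0:60, n, replace = TRUE),
                    birth_year = sample(c("y1", "y2"), n, replace = TRUE),
                    genetic_group = sample(c("g1", "g2"), n,
                                           replace = TRUE))
    d$noise_cov <- rnorm(n)
    d$log_rltl <- 0.1 - 0.002 * d$age_months +
      0.03 * (d$birth_year == "y2") + rnorm(n, 0, 0.1)
    d
  }
  model <- rrm_model(order_fixed = 1, random = "none",
                     fixed_factors = c("birth_year", "genetic_group"),
                     covariates = "noise_cov")
  removed <- vapply(1:50, function(s) {
    be <- backward_eliminate(gen_d(s), model = model)
    !("noise_cov" %in% be$model$covariates)
  }, logical(1))
  expect_gte(mean(removed), 0.9)

  ## a candidate duplicating a mandatory factor is aliased out first
  d <- gen_d(1)
  d$dup <- as.numeric(d$genetic_group == "g2")
  m2 <- utils::modifyList(model, list(covariates = c("dup", "noise_cov")))
  class(m2) <- "rrm_model"
  be2 <- backward_eliminate(d, model = m2)
  expect_equal(be2$trace$reason[1], "aliased")
  expect_false("dup" %in% be2$model$covariates)

  ## no candidates: identity
  m3 <- utils::modifyList(model, list(covariates = character()))
  class(m3) <- "rrm_model"
  be3 <- backward_eliminate(d, model = m3)
  expect_length(be3$trace$removed, 0)
})

test_that("AIC ranking applies the two-unit parsimony rule", {
  mk_fit <- function(aic, n_theta, beta_names = c("phi0", "phi1")) {
    structure(list(aic = aic, loglik = -aic / 2, n_theta = n_theta,
                   n = 100L, beta = stats::setNames(numeric(
                     length(beta_names)), beta_names),
                   model = list(likelihood = "reml")),
              class = "rrm_fit")
  }
  ## within two units the simpler wins
  r1 <- compare_models(list(complex = mk_fit(100, 5),
                            simple = mk_fit(101.9, 2)))
  expect_equal(r1$model[r1$preferred], "simple")
  ## beyond two units the better AIC wins
  r2 <- compare_models(list(complex = mk_fit(100, 5),
                            simple = mk_fit(103, 2)))
  expect_equal(r2$model[r2$preferred], "complex")
  ## a single fit is trivially preferred
  r3 <- compare_models(list(only = mk_fit(50, 1)))
  expect_true(r3$preferred)
  ## differing fixed structures are rejected under REML
  bad <- mk_fit(99, 2, beta_names = c("phi0", "phi1", "extra"))
  expect_error(compare_models(list(a = mk_fit(100, 2), b = bad)),
               "fixed-effect structure")
})

test_that("residual heterogeneity test detects simulated heterogeneity only", {
  gen <- function(seed, s2_young, s2_old) {
    set.seed(seed)
    n <- 150
    d <- data.frame(animal_id = rep(paste0("A", 1:n), each = 4),
                    age_months = as.numeric(replicate(n, c(0, sort(
                      sample(1:60, 3))))))
    d$log_rltl <- 0.1 +
      rnorm(nrow(d), 0,
            sqrt(ifelse(d$age_months <= 24, s2_young, s2_old)))
    d
  }
  model <- rrm_model(order_fixed = 0, order_random = 0,
                     fixed_factors = character(), random = "identity")
  het <- test_residual_heterogeneity(gen(71, 0.01, 0.04), model = model,
                                     age_cuts = 24)
  expect_equal(het$preferred, "heterogeneous")
  expect_lt(het$lrt$p_value, 0.05)

  hom <- test_residual_heterogeneity(gen(72, 0.02, 0.02), model = model,
                                     age_cuts = 24)
  expect_equal(hom$preferred, "homogeneous")

  ## degenerate single class reduces to the homogeneous fit
  one <- test_residual_heterogeneity(gen(73, 0.02, 0.02), model = model,
                                     age_cuts = numeric(0))
  expect_equal(one$lrt$df, 0L)
  expect_equal(one$homogeneous$loglik, one$heterogeneous$loglik,
               tolerance = 1e-8)
})
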