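test_that("simulated pedigrees respect generations, seeds and A diagonals", {
  p <- simulate_pedigree(4, 1, 0, seed = 1)
  expect_length(p, 4)
  expect_true(all(is.na(p$sire)))

  p1 <- simulate_pedigree(4, 2, 2, seed = 1)
  p2 <- simulate_pedigree(4, 2, 2, seed = 1)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  expect_error(simulate_pedigree(4, 0, 2, seed = 1), ">= 1")
  expect_error(simulate_pedigree(1, 2, 2, seed = 1), ">= 2")

  big <- simulate_pedigree(100, 3, 2, seed = 7)
  expect_true(all(diag(amatrix(big)) >= 1))   # tabular-method oracle
})

test_that("zero variance components reproduce the fixed part exactly", {
  basis <- legendre_basis(1, 0, 60)
  truth <- simulation_truth(
    K_true = matrix(0, 2, 2), sigma2_e_true = 1e-300, basis = basis,
    fixed_regression = c(0.12, -0.05),
    fixed_effect_values = list(birth_year = c(y1 = 0.02),
                               genetic_group = c(g = -0.01)))
  ped <- pedigree(c("A", "B"), c("0", "0"), c("0", "0"))
  sim <- simulate_rr_phenotypes(ped, truth,
                                list(A = c(0, 10, 20), B = c(0, 30)),
                                seed = 1)
  d <- sim$phenotypes
  fe <- sim$truth$fixed_effect_values
  expected <- drop(basis_matrix(d$age_months, basis) %*% c(0.12, -0.05)) +
    0.02 - 0.01 + fe$plate[d$plate] + fe$row[d$row]
  expect_equal(d$log_rltl, unname(expected), tolerance = 1e-10)
})

test_that("breeding values of unrelated founders have covariance K", {
  n <- 10000
  ped <- pedigree(as.character(1:n), rep("0", n), rep("0", n))
  basis <- legendre_basis(1, 0, 60)
  truth <- simulation_truth(K_true = diag(2), sigma2_e_true = 1,
                            basis = basis)
  sched <- stats::setNames(rep(list(0), 2), c("1", "2"))
  sim <- simulate_rr_phenotypes(ped, truth, sched, seed = 3)
  u <- sim$truth$u_true
  cv <- crossprod(u) / n
  ## Monte-Carlo SE of a covariance entry of iid standard normals
  mc_se <- sqrt(2 / n)
  expect_lt(max(abs(diag(cv) - 1)), 3 * mc_se)
  expect_lt(abs(cv[1, 2]), 3 / sqrt(n))
})

test_that("parent-offspring coefficient covariance is one half", {
  n <- 3000
  id <- c(paste0("S", 1:n), paste0("D", 1:n), paste0("O", 1:n))
  ped <- pedigree(id, c(rep("0", 2 * n), paste0("S", 1:n)),
                  c(rep("0", 2 * n), paste0("D", 1:n)))
  basis <- legendre_basis(1, 0, 60)
  truth <- simulation_truth(K_true = diag(2), sigma2_e_true = 1,
                            basis = basis)
  sim <- simulate_rr_phenotypes(ped, truth,
                                stats::setNames(list(0), "O1"), seed = 9)
  u <- sim$truth$u_true
  for (ord in 1:2) {
    up <- u[paste0("S", 1:n), ord]
    uo <- u[paste0("O", 1:n), ord]
    cv <- mean(up * uo)
    mc_se <- stats::sd(up * uo) / sqrt(n)
    expect_lt(abs(cv - 0.5), 3 * mc_se)  # a(parent, offspring) = 0.5
  }
})

test_that("phenotypic variance decomposes as phi K phi' + sigma2_e", {
  basis <- legendre_basis(2, 0, 60)
  K <- diag(c(0.4, 0.1, 0.05))
  truth <- simulation_truth(K_true = K, sigma2_e_true = 0.3,
                            basis = basis)
  n <- 8000
  ped <- pedigree(as.character(1:n), rep("0", n), rep("0", n))
  sched <- stats::setNames(rep(list(24), n), as.character(1:n))
  sim <- simulate_rr_phenotypes(ped, truth, sched, seed = 11)
  phi <- basis_row(24, basis)
  expected <- drop(phi %*% K %*% phi) + 0.3
  v <- stats::var(sim$phenotypes$log_rltl)
  ## fixed plate/row effects add a little variance; allow MC + fixed slack
  expect_lt(abs(v - expected) / expected, 0.1)
})

test_that("non-PSD K is rejected before any draw", {
  basis <- legendre_basis(1, 0, 60)
  expect_error(simulation_truth(matrix(c(1, 2, 2, 1), 2), 1, basis),
               "positive semi-definite")
})

test_that("survival generator matches its null, effect and censoring laws", {
  truth <- default_truth()
  truth$survival_log_hazard_by_cluster <- c(A = 0, B = 0)
  labs <- stats::setNames(rep(c("A", "B"), each = 1500),
                          paste0("x", 1:3000))
  sv <- simulate_survival(labs, truth, censoring_rate = 0, seed = 2)
  fit <- fit_cox(sv, reference_cluster = "A")
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$coefficients[["B"]]), 3 * se)   # null: no separation

  truth$survival_log_hazard_by_cluster <- c(A = 0, B = 0.7)
  sv2 <- simulate_survival(labs[1:2000], truth, censoring_rate = 0,
                           seed = 3)
  fit2 <- fit_cox(sv2, reference_cluster = "A")
  expect_lt(abs(fit2$coefficients[["B"]] - 0.7),
            3 * sqrt(diag(fit2$cov)))

  labs3 <- stats::setNames(rep("A", 10000), paste0("y", 1:10000))
  truth$survival_log_hazard_by_cluster <- c(A = 0)
  sv3 <- simulate_survival(labs3, truth, censoring_rate = 0.2, seed = 4)
  frac <- mean(1 - sv3$event)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))

  expect_error(simulate_survival(labs, truth, censoring_rate = 1,
                                 seed = 1), "\\[0, 1\\)")
})

test_that("every generator is bit-identical under a fixed seed", {
  s1 <- simulate_study(n_animals = 15, seed = 6)
  s2 <- simulate_study(n_animals = 15, seed = 6)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$truth$u_true, s2$truth$u_true)

  sched1 <- default_schedule(paste0("A", 1:50), seed = 2)
  sched2 <- default_schedule(paste0("A", 1:50), seed = 2)
  expect_identical(sched1, sched2)
})

test_that("default schedule averages about 4.3 records per animal", {
  sched <- default_schedule(paste0("A", 1:2000), seed = 13)
  m <- mean(lengths(sched))
  expect_lt(abs(m - 4.3), 0.15)
  expect_true(all(vapply(sched, function(s) s[1] == 0, logical(1))))
  expect_true(all(unlist(sched) <= 60))
})
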