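test_that("Cox estimates match the grid-search partial-likelihood oracle", {
  ## two subjects, both events, covariate (1, 0): the partial likelihood
  ## beta - log(1 + e^beta) is monotone, so the maximiser sits at the
  ## boundary; both routes must agree on the likelihood itself and the
  ## fit must flag the monotone likelihood
  d2 <- data.frame(animal_id = c("a", "b"), time_days = c(1, 2),
                   event = 1L, cluster = c("B", "A"))
  expect_warning(fit2 <- fit_cox(d2, reference_cluster = "A"), "monotone")
  expect_true(fit2$monotone)
  x <- as.numeric(d2$cluster == "B")
  for (b in seq(-2, 2, by = 0.5)) {
    expect_equal(oracle_cox_loglik(b, d2$time_days, d2$event, x),
                 b - log(1 + exp(b)), tolerance = 1e-12)
  }
  ## four subjects, alternating clusters: finite interior maximiser
  d4 <- data.frame(animal_id = letters[1:4],
                   time_days = c(2, 4, 6, 8), event = 1L,
                   cluster = c("B", "A", "B", "A"))
  fit4 <- fit_cox(d4, reference_cluster = "A")
  oracle4 <- oracle_cox_fit(d4$time_days, d4$event,
                            as.numeric(d4$cluster == "B"))
  expect_lt(abs(fit4$coefficients[["B"]] - oracle4), 1e-6)

  ## five subjects with a censored record, no ties
  d5 <- data.frame(animal_id = letters[1:5],
                   time_days = c(3, 5, 7, 11, 13),
                   event = c(1L, 1L, 0L, 1L, 1L),
                   cluster = c("B", "A", "B", "A", "B"))
  fit5 <- fit_cox(d5, reference_cluster = "A")
  oracle5 <- oracle_cox_fit(d5$time_days, d5$event,
                            as.numeric(d5$cluster == "B"))
  expect_lt(abs(fit5$coefficients[["B"]] - oracle5), 1e-6)
})

test_that("Wald test follows its identities", {
  d <- data.frame(animal_id = paste0("x", 1:40),
                  time_days = c(1:40), event = 1L,
                  cluster = rep(c("A", "B"), 20))
  fit <- fit_cox(d, reference_cluster = "A")
  w <- wald_test(fit)
  ## single coefficient: W = (beta / se)^2
  expect_equal(w$statistic,
               (fit$coefficients[["B"]] / sqrt(fit$cov[1, 1]))^2,
               tolerance = 1e-10)
  expect_equal(w$df, 1L)
  ## beta = 0 gives statistic 0 and p = 1 (identical groups by symmetry)
  expect_equal(wald_stat(c(B = 0), matrix(1, 1, 1))$p_value, 1)
})

test_that("score test equals the log-rank statistic without ties", {
  set.seed(23)
  d <- data.frame(animal_id = paste0("x", 1:60),
                  time_days = sort(sample(1:10000, 60)),
                  event = 1L,
                  cluster = sample(c("A", "B"), 60, replace = TRUE))
  fit <- fit_cox(d, reference_cluster = "A")
  lr <- survival::survdiff(survival::Surv(time_days, event) ~ cluster,
                           data = d)
  expect_lt(abs(fit$score_statistic - lr$chisq), 1e-8)
})

test_that("likelihood is invariant to time rescaling and late censoring", {
  set.seed(31)
  d <- data.frame(animal_id = paste0("x", 1:50),
                  time_days = sort(sample(1:5000, 50)), event = 1L,
                  cluster = sample(c("A", "B"), 50, replace = TRUE))
  f1 <- fit_cox(d, reference_cluster = "A")
  d_years <- d; d_years$time_days <- d$time_days / 365.25
  f2 <- fit_cox(d_years, reference_cluster = "A")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)

  ## a subject censored before the first event joins no risk set and
  ## leaves the partial likelihood untouched; censored within the follow-up
  ## it enters exactly the risk sets of earlier events
  d3 <- rbind(d, data.frame(animal_id = "early",
                            time_days = min(d$time_days) - 0.5,
                            event = 0L, cluster = "A"))
  f3 <- fit_cox(d3, reference_cluster = "A")
  expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-10)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-10)
  d5 <- rbind(d, data.frame(animal_id = "mid",
                            time_days = stats::median(d$time_days),
                            event = 0L, cluster = "A"))
  f5 <- fit_cox(d5, reference_cluster = "A")
  x <- as.numeric(d5$cluster == "B")
  oracle5 <- oracle_cox_fit(d5$time_days, d5$event, x)
  expect_lt(abs(f5$coefficients[["B"]] - oracle5), 1e-6)
})

test_that("preconditions and degenerate designs are caught", {
  d <- data.frame(animal_id = c("a", "b"), time_days = c(1, 2),
                  event = c(0L, 0L), cluster = c("A", "B"))
  expect_error(fit_cox(d), "at least one event")
  d2 <- data.frame(animal_id = c("a", "b"), time_days = c(1, 2),
                   event = 1L, cluster = "A")
  expect_error(fit_cox(d2), "two clusters")
  d3 <- data.frame(animal_id = c("a", "a"), time_days = c(1, 2),
                   event = 1L, cluster = c("A", "B"))
  expect_error(fit_cox(d3), "exactly one")
  ## complete separation in event order triggers the monotone warning
  d4 <- data.frame(animal_id = paste0("x", 1:20),
                   time_days = c(1:10, 101:110), event = 1L,
                   cluster = rep(c("B", "A"), each = 10))
  expect_warning(fit_cox(d4, reference_cluster = "A"), "monotone")
})

test_that("the largest cluster is the default reference", {
  d <- data.frame(animal_id = paste0("x", 1:30),
                  time_days = sample(1:1000, 30), event = 1L,
                  cluster = c(rep("big", 20), rep("small", 10)))
  fit <- fit_cox(d)
  expect_equal(fit$reference, "big")
  expect_equal(names(fit$coefficients), "small")
})
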