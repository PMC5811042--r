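## Synthetic-data generator: pedigrees, breeding-value gene dropping,
## Legendre-curve phenotypes, qPCR plates and censored survival times, all
## with stored ground truth and full determinism under a seed.

is_psd <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

#' Ground truth for a simulation
#'
#' Holds every generative parameter: the genetic coefficient covariance
#' \code{K_true} on the normalised Legendre basis, the residual variance
#' (scalar, or one per age class), an optional permanent-environment
#' variance, the fixed regression coefficients and factor-level effects,
#' cluster curve templates and per-cluster log-hazards for survival.
#' Together with a seed this is sufficient to regenerate every simulated
#' phenotype exactly.
#'
#' @param K_true Symmetric PSD matrix, \code{(order+1) x (order+1)}.
#' @param sigma2_e_true Positive residual variance (scalar or per-class
#'   vector).
#' @param sigma2_pe_true Permanent-environment variance (scalar, >= 0).
#' @param fixed_regression Numeric vector \code{b} of fixed Legendre
#'   coefficients (same length as \code{ncol(K_true)} by default).
#' @param fixed_effect_values Named list of named numeric vectors:
#'   effects for \code{birth_year}, \code{genetic_group} (and optionally
#'   \code{plate}, \code{row}; when absent these are drawn at simulation
#'   time and recorded back into the returned truth).
#' @param basis The \code{\link{legendre_basis}} the coefficients refer to.
#' @param cluster_templates Optional list of template curve functions or
#'   matrices for profile-clustering simulations.
#' @param survival_log_hazard_by_cluster Named numeric vector of log hazard
#'   ratios (0 = baseline).
#' @param baseline_hazard_per_day Baseline event rate per day.
#' @return Object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(K_true, sigma2_e_true, basis,
                             sigma2_pe_true = 0,
                             fixed_regression = NULL,
                             fixed_effect_values = list(),
                             cluster_templates = NULL,
                             survival_log_hazard_by_cluster = NULL,
                             baseline_hazard_per_day = 1 / 1477) {
  K_true <- as.matrix(K_true)
  if (!is_psd(K_true))
    stop("K_true must be symmetric positive semi-definite")
  if (any(sigma2_e_true <= 0)) stop("sigma2_e_true must be > 0")
  if (sigma2_pe_true < 0) stop("sigma2_pe_true must be >= 0")
  if (is.null(fixed_regression)) fixed_regression <- numeric(ncol(K_true))
  structure(list(
    K_true = K_true,
    sigma2_e_true = sigma2_e_true,
    sigma2_pe_true = sigma2_pe_true,
    fixed_regression = fixed_regression,
    fixed_effect_values = fixed_effect_values,
    basis = basis,
    cluster_templates = cluster_templates,
    survival_log_hazard_by_cluster = survival_log_hazard_by_cluster,
    baseline_hazard_per_day = baseline_hazard_per_day
  ), class = "simulation_truth")
}

#' Default simulation truth emulating the dairy-herd study conditions
#'
#' Quadratic genetic curves with \code{K = diag(0.022, 0.0013, 0.0004)} and
#' residual variance 0.016 on the natural-log RLTL scale.  These values
#' place the phenotypic variance near 0.026 (a raw-scale coefficient of
#' variation around 0.16), heritability between roughly 0.41 and 0.47
#' across ages, a genetic correlation between birth and 60 months around
#' 0.72, and ~93% of coefficient variance on the leading eigenvalue.  The
#' fixed curve declines over early life and flattens with a slight late
#' rise.  Birth-year (5 levels) and genetic-group (2 levels) effects are
#' small fixed shifts; plate and row effects are drawn at simulation time.
#'
#' @param basis A \code{\link{legendre_basis}} (order 2 for the defaults;
#'   other orders get a zero-padded/truncated K diagonal).
#' @return A \code{\link{simulation_truth}}.
#' @export
default_truth <- function(basis = legendre_basis(2, 0, 60)) {
  m <- basis$order + 1L
  kdiag <- c(0.022, 0.0013, 0.0004, 0.0002, 0.0001, 5e-05)[seq_len(m)]
  K <- diag(kdiag, m)
  ## fixed curve: convex parabola in standardized age, high at birth,
  ## minimum ~2/3 through life, mild late rise; least-squares projection
  ## onto the basis
  g <- seq(basis$t_min, basis$t_max, length.out = 101)
  x <- standardize_age(g, basis)
  target <- 0.05 + 0.08 * (x - 0.2)^2
  Phi <- basis_matrix(g, basis)
  b <- drop(solve(crossprod(Phi), crossprod(Phi, target)))
  simulation_truth(
    K_true = K, sigma2_e_true = 0.016, basis = basis,
    fixed_regression = b,
    fixed_effect_values = list(
      birth_year = stats::setNames(seq(-0.02, 0.02, length.out = 5),
                                   as.character(2008:2012)),
      genetic_group = c(select = 0.01, control = 0)
    ),
    survival_log_hazard_by_cluster =
      stats::setNames(numeric(5), paste0("C", 1:5))
  )
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 1; each later generation is produced by random
#' sire x dam matings among all earlier-generation animals (so matings
#' between relatives, and hence inbreeding, arise naturally from the third
#' generation on).  Sexes are assigned alternately and recorded in
#' attribute \code{"sex"}.
#'
#' @param n_founders Number of founders (>= 2).
#' @param n_generations Total number of generations including founders
#'   (>= 1); 1 means founders only.
#' @param offspring_per_mating Offspring per mating.
#' @param seed Integer seed.
#' @param n_matings Matings per generation (default
#'   \code{floor(n_founders / 2)}).
#' @return A \code{\link{pedigree}} with attribute \code{"sex"} (named
#'   "M"/"F" vector).
#' @export
simulate_pedigree <- function(n_founders, n_generations, offspring_per_mating,
                              seed, n_matings = NULL) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_generations < 1) stop("n_generations must be >= 1")
  set.seed(seed)
  if (is.null(n_matings)) n_matings <- max(1L, n_founders %/% 2L)
  id <- as.character(seq_len(n_founders))
  sire <- rep("0", n_founders)
  dam <- rep("0", n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  nxt <- n_founders + 1L
  if (n_generations >= 2L && offspring_per_mating >= 1L) {
    for (g in 2:n_generations) {
      males <- id[sex == "M"]
      females <- id[sex == "F"]
      if (!length(males) || !length(females)) break
      for (mt in seq_len(n_matings)) {
        s <- sample(males, 1L)
        d <- sample(females, 1L)
        for (o in seq_len(offspring_per_mating)) {
          id <- c(id, as.character(nxt))
          sire <- c(sire, s)
          dam <- c(dam, d)
          sex <- c(sex, sample(c("M", "F"), 1L))
          nxt <- nxt + 1L
        }
      }
    }
  }
  ped <- pedigree(id, sire, dam)
  attr(ped, "sex") <- stats::setNames(sex, id)[ped$id]
  ped
}

#' Simulate a study herd pedigree
#'
#' Emulates the structure of a recorded dairy herd: a founder layer, a
#' parent layer of \code{n_sires} sires and \code{n_dams} dams, and
#' \code{n_animals} phenotyped cows whose parents are drawn from that
#' layer.
#'
#' @param n_animals Number of phenotyped cows.
#' @param n_sires,n_dams Parent-layer sizes.
#' @param seed Integer seed.
#' @return A \code{\link{pedigree}} with attribute \code{"phenotyped"}: the
#'   ids of the cow layer.
#' @export
simulate_herd_pedigree <- function(n_animals = 308, n_sires = 40,
                                   n_dams = 241, seed = 1) {
  set.seed(seed)
  n_gs <- max(4L, n_sires %/% 2L)   # grandsires
  n_gd <- max(4L, n_dams %/% 2L)    # granddams
  gs <- paste0("GS", seq_len(n_gs))
  gd <- paste0("GD", seq_len(n_gd))
  sires <- paste0("S", seq_len(n_sires))
  dams <- paste0("D", seq_len(n_dams))
  cows <- paste0("A", seq_len(n_animals))
  id <- c(gs, gd, sires, dams, cows)
  sire <- c(rep("0", n_gs + n_gd),
            sample(gs, n_sires, replace = TRUE),
            sample(gs, n_dams, replace = TRUE),
            sample(sires, n_animals, replace = TRUE))
  dam <- c(rep("0", n_gs + n_gd),
           sample(gd, n_sires, replace = TRUE),
           sample(gd, n_dams, replace = TRUE),
           sample(dams, n_animals, replace = TRUE))
  ped <- pedigree(id, sire, dam)
  attr(ped, "phenotyped") <- cows
  ped
}

## Breeding-value gene dropping: founders drawn from N(0, K); descendants as
## mid-parent average plus a Mendelian-sampling deviation with covariance
## (0.5 - 0.25 (F_s + F_d)) K (F = -1 for an unknown parent, whose
## contribution is dropped).  Exact Cholesky recursion: var(vec u) = A (x) K.
draw_breeding_values <- function(ped, K) {
  n <- length(ped$id)
  m <- ncol(K)
  f <- inbreeding(ped)
  ev <- eigen(K, symmetric = TRUE)
  Lk <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
  u <- matrix(0, n, m, dimnames = list(ped$id, NULL))
  Fpar <- function(p) if (is.na(p)) -1 else f[p]
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    mid <- numeric(m)
    if (!is.na(s)) mid <- mid + 0.5 * u[s, ]
    if (!is.na(d)) mid <- mid + 0.5 * u[d, ]
    w <- 0.5 - 0.25 * (Fpar(s) + Fpar(d))
    u[i, ] <- mid + sqrt(w) * drop(Lk %*% stats::rnorm(m))
  }
  u
}

#' Default longitudinal sampling schedule
#'
#' One record at birth (age 0) plus 1-7 further records at distinct random
#' integer ages up to the basis upper bound, with on average 3.3 later
#' records, i.e. ~4.3 records per animal overall.
#'
#' @param animal_ids Character vector of animals to schedule.
#' @param seed Integer seed.
#' @param t_max Maximum sampling age in months.
#' @return Named list of sorted age vectors.
#' @export
default_schedule <- function(animal_ids, seed, t_max = 60) {
  set.seed(seed)
  out <- lapply(animal_ids, function(a) {
    n_later <- 1L + stats::rbinom(1L, 6L, 2.3 / 6)
    sort(c(0, sample(seq_len(t_max), n_later)))
  })
  stats::setNames(out, animal_ids)
}

#' Simulate random-regression phenotypes over a pedigree
#'
#' Per-animal genetic coefficient vectors are drawn from a zero-mean
#' multivariate normal with covariance \code{A (x) K_true} via gene
#' dropping; each scheduled record is fixed part + genetic curve +
#' permanent-environment effect (if any) + i.i.d. residual.  Plate and row
#' are assigned by filling plates sequentially (\code{samples_per_plate}
#' samples, 8 rows); their effects are taken from the truth when present,
#' otherwise drawn N(0, 0.01^2)/N(0, 0.005^2) and recorded back.
#'
#' @param ped A \code{\link{pedigree}}.
#' @param truth A \code{\link{simulation_truth}}.
#' @param schedule Named list of age vectors (see
#'   \code{\link{default_schedule}}); names select phenotyped animals.
#' @param seed Integer seed.
#' @param samples_per_plate Plate capacity (excluding the calibrator).
#' @return List: \code{phenotypes} (data frame with columns
#'   \code{animal_id, age_months, log_rltl, birth_year, genetic_group,
#'   plate, row}), \code{truth} (augmented with realised plate/row effects
#'   and the matrix \code{u_true}).
#' @export
simulate_rr_phenotypes <- function(ped, truth, schedule, seed,
                                   samples_per_plate = 53L) {
  stopifnot(inherits(ped, "pedigree"), inherits(truth, "simulation_truth"))
  if (!is_psd(truth$K_true)) stop("K_true must be PSD")
  basis <- truth$basis
  if (ncol(truth$K_true) != basis$order + 1L)
    stop("K_true dimension does not match the basis order")
  unknown <- setdiff(names(schedule), ped$id)
  if (length(unknown))
    stop("scheduled animal(s) not in pedigree: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  set.seed(seed)
  u <- draw_breeding_values(ped, truth$K_true)

  anims <- names(schedule)
  nrec <- vapply(schedule, length, 1L)
  animal_id <- rep(anims, nrec)
  age <- unlist(schedule, use.names = FALSE)
  n <- length(age)

  fe <- truth$fixed_effect_values
  by_lev <- names(fe$birth_year)
  gg_lev <- names(fe$genetic_group)
  if (is.null(by_lev)) { fe$birth_year <- c(y1 = 0); by_lev <- "y1" }
  if (is.null(gg_lev)) { fe$genetic_group <- c(g1 = 0); gg_lev <- "g1" }
  a_by <- stats::setNames(sample(by_lev, length(anims), replace = TRUE), anims)
  a_gg <- stats::setNames(sample(gg_lev, length(anims), replace = TRUE), anims)

  n_plates <- ceiling(n / samples_per_plate)
  plate <- paste0("P", rep(seq_len(n_plates), each = samples_per_plate)[seq_len(n)])
  row <- paste0("R", (seq_len(n) - 1L) %% 8L + 1L)
  if (is.null(fe$plate)) {
    fe$plate <- stats::setNames(stats::rnorm(n_plates, 0, 0.01),
                                paste0("P", seq_len(n_plates)))
  }
  if (is.null(fe$row)) {
    fe$row <- stats::setNames(stats::rnorm(8L, 0, 0.005), paste0("R", 1:8))
  }

  Phi <- basis_matrix(age, basis)
  genetic <- rowSums(Phi * u[animal_id, , drop = FALSE])
  fixed <- drop(Phi %*% truth$fixed_regression) +
    fe$birth_year[a_by[animal_id]] +
    fe$genetic_group[a_gg[animal_id]] +
    fe$plate[plate] + fe$row[row]

  pe_eff <- if (truth$sigma2_pe_true > 0) {
    stats::setNames(stats::rnorm(length(anims), 0,
                                 sqrt(truth$sigma2_pe_true)), anims)
  } else stats::setNames(numeric(length(anims)), anims)

  s2e <- residual_variance_at(truth, age)
  y <- fixed + genetic + pe_eff[animal_id] +
    stats::rnorm(n, 0, sqrt(s2e))

  phen <- data.frame(
    animal_id = animal_id, age_months = age, log_rltl = unname(y),
    birth_year = unname(a_by[animal_id]),
    genetic_group = unname(a_gg[animal_id]),
    plate = plate, row = row, stringsAsFactors = FALSE)
  truth$fixed_effect_values <- fe
  truth$u_true <- u
  truth$animal_birth_year <- a_by
  truth$animal_genetic_group <- a_gg
  list(phenotypes = phen, truth = truth)
}

## residual variance per record, honouring per-class vectors
## (classes = left-closed intervals between stored cut points)
residual_variance_at <- function(truth, age) {
  s2 <- truth$sigma2_e_true
  if (length(s2) == 1L) return(rep(s2, length(age)))
  cuts <- attr(s2, "cuts")
  if (is.null(cuts) || length(cuts) != length(s2) - 1L)
    stop("per-class sigma2_e_true needs attr 'cuts' with one fewer cut ",
         "points than classes")
  cls <- findInterval(age, cuts) + 1L
  unname(s2[cls])
}

#' Simulate qPCR plates realising given target RLTL values
#'
#' Each plate carries one calibrator record (fixed Cq 15/20, the same
#' "golden" DNA on every plate).  Sample Cq values are constructed so that
#' the efficiency-corrected calibrator ratio returns the target exactly;
#' Gaussian noise with \code{noise_sd} cycles is then added independently to
#' the two sample reactions (the calibrator is left exact), making measured
#' log RLTL normal around the log target with variance
#' \code{noise_sd^2 (log^2 E_TEL + log^2 E_B2M)}.
#'
#' @param targets Data frame \code{sample_id, animal_id, target_rltl}
#'   (targets > 0).
#' @param efficiencies Length-2 numeric \code{c(E_TEL, E_B2M)}, each in
#'   (1, 2].
#' @param samples_per_plate Samples per plate (excluding the calibrator).
#' @param noise_sd Cq noise standard deviation in cycles (>= 0).
#' @param seed Integer seed.
#' @return Plate record data frame (schema of \code{\link{read_plates}}).
#' @export
simulate_cq_plates <- function(targets, efficiencies = c(2, 2),
                               samples_per_plate = 53L, noise_sd = 0,
                               seed = 1) {
  stopifnot(is.data.frame(targets),
            all(c("sample_id", "animal_id", "target_rltl") %in%
                  names(targets)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  e_tel <- efficiencies[1]; e_b2m <- efficiencies[2]
  if (any(efficiencies <= 1 | efficiencies > 2))
    stop("efficiencies must lie in (1, 2]")
  if (any(targets$target_rltl <= 0)) stop("target RLTL must be > 0")
  set.seed(seed)
  n <- nrow(targets)
  plate <- paste0("P", rep(seq_len(ceiling(n / samples_per_plate)),
                           each = samples_per_plate)[seq_len(n)])
  row <- paste0("R", (seq_len(n) - 1L) %% 8L + 1L)
  cq_tel_cal <- 15; cq_b2m_cal <- 20
  ## spread B2M Cqs around the calibrator, solve TEL Cq for the target
  cq_b2m <- cq_b2m_cal + stats::runif(n, -1, 1)
  cq_tel <- cq_tel_cal -
    (log(targets$target_rltl) + (cq_b2m_cal - cq_b2m) * log(e_b2m)) /
    log(e_tel)
  cq_tel <- cq_tel + stats::rnorm(n, 0, noise_sd)
  cq_b2m <- cq_b2m + stats::rnorm(n, 0, noise_sd)
  smp <- data.frame(
    sample_id = targets$sample_id, animal_id = targets$animal_id,
    plate_id = plate, row_id = row,
    cq_tel = cq_tel, cq_b2m = cq_b2m,
    e_tel = e_tel, e_b2m = e_b2m,
    is_calibrator = FALSE, stringsAsFactors = FALSE)
  cal <- data.frame(
    sample_id = paste0("CAL_", unique(plate)), animal_id = "calibrator",
    plate_id = unique(plate), row_id = "R1",
    cq_tel = cq_tel_cal, cq_b2m = cq_b2m_cal,
    e_tel = e_tel, e_b2m = e_b2m,
    is_calibrator = TRUE, stringsAsFactors = FALSE)
  out <- rbind(smp, cal)
  out <- out[order(out$plate_id, !out$is_calibrator, out$sample_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate right-censored productive lifespan
#'
#' Exponential event times with cluster-specific log hazards
#' (\code{truth$survival_log_hazard_by_cluster}) around the baseline rate;
#' independent exponential censoring with rate chosen so each animal is
#' censored with probability \code{censoring_rate}.  Times are rounded up
#' to whole days (culling is recorded daily, producing ties).
#'
#' @param cluster_assignment Named character vector animal -> cluster label.
#' @param truth A \code{\link{simulation_truth}}.
#' @param censoring_rate Fraction in [0, 1).
#' @param seed Integer seed.
#' @return Data frame \code{animal_id, time_days, event, cluster}.
#' @export
simulate_survival <- function(cluster_assignment, truth, censoring_rate,
                              seed) {
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  lh <- truth$survival_log_hazard_by_cluster
  if (is.null(lh)) stop("truth carries no survival log-hazards")
  cl <- as.character(cluster_assignment)
  miss <- setdiff(unique(cl), names(lh))
  if (length(miss))
    stop("no log-hazard for cluster(s): ", paste(miss, collapse = ", "))
  rate <- truth$baseline_hazard_per_day * exp(unname(lh[cl]))
  if (any(rate <= 0)) stop("hazards must be positive")
  set.seed(seed)
  n <- length(cl)
  tev <- stats::rexp(n, rate)
  if (censoring_rate > 0) {
    cens <- stats::rexp(n, rate * censoring_rate / (1 - censoring_rate))
    event <- as.integer(tev <= cens)
    tt <- pmin(tev, cens)
  } else {
    event <- rep(1L, n)
    tt <- tev
  }
  data.frame(animal_id = names(cluster_assignment),
             time_days = ceiling(tt), event = event, cluster = cl,
             stringsAsFactors = FALSE)
}

#' Simulate noisy curves from shape templates
#'
#' Draws each curve from one of \code{k} template shapes plus i.i.d.
#' Gaussian noise at every grid point; used to exercise and test profile
#' clustering against labelled ground truth.  The default five templates
#' mirror the qualitative profile families of interest: flat, mild decline,
#' mild rise, steep decline, steep rise (early-life change flattening out).
#'
#' @param n Number of curves.
#' @param grid Age grid (months).
#' @param templates List of functions of age, or a k x length(grid) matrix.
#' @param noise_sd Noise SD at each grid point; the default is 20% of the
#'   0.1 separation between adjacent default templates.
#' @param seed Integer seed.
#' @param proportions Optional template probabilities.
#' @return List: \code{curves} (n x length(grid) matrix), \code{labels}
#'   (integer template index), \code{grid}, \code{templates} (matrix).
#' @export
simulate_template_profiles <- function(n, grid = 0:60, templates = NULL,
                                       noise_sd = 0.02, seed = 1,
                                       proportions = NULL) {
  if (is.null(templates)) {
    ramp <- function(a) pmin(a, 20) / 20   # change happens in early life
    templates <- rbind(
      flat = rep(0, length(grid)),
      mild_down = -0.1 * ramp(grid),
      mild_up = 0.1 * ramp(grid),
      steep_down = -0.2 * ramp(grid),
      steep_up = 0.2 * ramp(grid))
  } else if (is.list(templates)) {
    templates <- do.call(rbind, lapply(templates, function(f) f(grid)))
  }
  k <- nrow(templates)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  set.seed(seed)
  labels <- sample.int(k, n, replace = TRUE, prob = proportions)
  curves <- templates[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * length(grid), 0, noise_sd), n)
  rownames(curves) <- paste0("A", seq_len(n))
  list(curves = curves, labels = labels, grid = grid, templates = templates)
}

#' Simulate a complete study dataset
#'
#' Chains the generators into the full input set the pipeline consumes: a
#' herd pedigree; a longitudinal sampling schedule; genetic curve + fixed
#' effect target RLTL values; qPCR plates whose Cq noise realises the
#' residual variance (noise SD per reaction derived from
#' \code{sigma2_e_true}); and censored survival times.  The returned truth
#' is sufficient to regenerate everything.
#'
#' @param n_animals Number of phenotyped cows.
#' @param truth A \code{\link{simulation_truth}} (default
#'   \code{\link{default_truth}}).
#' @param censoring_rate Fraction of animals alive at study end.
#' @param seed Integer seed.
#' @return List: \code{pedigree}, \code{plates}, \code{phenotypes},
#'   \code{survival}, \code{truth}.
#' @export
simulate_study <- function(n_animals = 308, truth = default_truth(),
                           censoring_rate = 64 / 308, seed = 1) {
  ped <- simulate_herd_pedigree(n_animals, seed = seed)
  cows <- attr(ped, "phenotyped")
  sched <- default_schedule(cows, seed = seed + 1L,
                            t_max = truth$basis$t_max)
  ## phenotype means (no residual): the residual enters via Cq noise
  s2e <- truth$sigma2_e_true[1]
  noiseless <- truth
  noiseless$sigma2_e_true <- .Machine$double.eps
  sim <- simulate_rr_phenotypes(ped, noiseless, sched, seed = seed + 2L)
  phen <- sim$phenotypes
  truth <- sim$truth
  truth$sigma2_e_true <- s2e
  ## per-reaction Cq noise implying residual variance s2e on log RLTL
  e <- c(2, 2)
  noise_sd <- sqrt(s2e / (log(e[1])^2 + log(e[2])^2))
  targets <- data.frame(sample_id = sprintf("S%04d", seq_len(nrow(phen))),
                        animal_id = phen$animal_id,
                        target_rltl = exp(phen$log_rltl))
  plates <- simulate_cq_plates(targets, efficiencies = e,
                               noise_sd = noise_sd, seed = seed + 3L)
  ## measured phenotypes: run the plates back through the qPCR stage
  rl <- rltl_table(plates)
  phen$log_rltl <- log(rl$rltl[match(targets$sample_id, rl$sample_id)])
  phen$plate <- rl$plate_id[match(targets$sample_id, rl$sample_id)]
  phen$row <- rl$row_id[match(targets$sample_id, rl$sample_id)]

  ## true cluster labels: quintiles of the genetic intercept coefficient
  u0 <- truth$u_true[cows, 1L]
  qs <- stats::quantile(u0, probs = seq(0.2, 0.8, 0.2))
  clu <- stats::setNames(paste0("C", findInterval(u0, qs) + 1L), cows)
  surv <- simulate_survival(clu, truth, censoring_rate, seed = seed + 4L)

  list(pedigree = ped, plates = plates, phenotypes = phen,
       survival = surv, truth = truth)
}
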