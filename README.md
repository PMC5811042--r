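# telotraj

Longitudinal telomere-length analysis with random regression animal models.

Telomeres shorten with age in many species, and repeated relative leukocyte
telomere length (RLTL) measurements over an animal's life make it possible
to ask not just how long telomeres are, but how they *change* — and how much
of that change is heritable.  `telotraj` is an R implementation of the full
analysis path used for pedigreed longitudinal qPCR studies (the motivating
system is a dairy-cattle herd sampled from birth to ~60 months):

1. **qPCR → phenotype**: efficiency-corrected, calibrator-normalised
   relative quantification
   `RLTL = E_TEL^(ΔCq_TEL) / E_B2M^(ΔCq_B2M)`, DNA quality-control gating,
   and natural-log transformation with a normality check.
2. **Pedigree algebra**: the numerator relationship matrix A by the tabular
   method, and its sparse inverse by Henderson's rules with Meuwissen–Luo
   inbreeding — A itself is never formed by the solver.
3. **Random regression animal model** fitted by average-information REML:
   `y = BirthYear + GeneticGroup + plate + row + Σ φ_k(t) b_k + Σ φ_k(t) u_jk + e`,
   with normalised Legendre polynomials `φ_k`, animal coefficient vectors
   `u_j` with `var(u) = A ⊗ K`, optional permanent-environment effect and
   age-class residual variances; backward elimination of candidate fixed
   effects, REML-AIC model ladders with the two-unit parsimony rule, and
   residual-heterogeneity tests.
4. **Genetic parameter trajectories**: `V_A(t) = φ(t) K φ(t)'`,
   heritability `h²(t) = V_A / (V_A + V_PE + σ²_e)` and genetic
   correlations with birth, with delta-method SEs from the inverse
   average-information matrix; eigenvalues/eigenfunctions of K; per-animal
   profiles with prediction-error SEs.
5. **Profile clustering** under the discrete Fréchet distance (k-means++
   seeding, pointwise-median centers, provably non-increasing objective).
6. **Survival association**: Cox proportional hazards of profile cluster on
   right-censored productive lifespan with a Wald test.

A first-class synthetic-data generator (pedigrees, gene-dropped breeding
values, qPCR plates whose Cq noise realises the residual variance, censored
survival times) provides known ground truth for every stage.

## A worked example

```r
library(telotraj)

sim <- simulate_study(n_animals = 120, seed = 1)   # herd + plates + survival
fit <- fit_reml(sim$phenotypes, sim$pedigree, rrm_model(),
                basis = legendre_basis(2, 0, 60))
fit
#> Random regression animal model fit (reml)
#>   records: 518, fixed effects: 24, logL: 169.7714, AIC: -325.54
#>   K (genetic coefficient covariance):
#>           [,1]      [,2]      [,3]
#> [1,]  0.029542  0.001965 -0.000589
#> [2,]  0.001965  0.000139 -0.000080
#> [3,] -0.000589 -0.000080  0.000206
#>   sigma2_e: 0.017874

heritability(fit, grid = c(0, 30, 60))
#>           kind animal_id age_month     value         se
#> 1 heritability      <NA>         0 0.3827464 0.08344744
#> 2 heritability      <NA>        30 0.4653698 0.07204670
#> 3 heritability      <NA>        60 0.4914482 0.14453398

eigen_analysis(fit)
#> Eigen decomposition of the coefficient covariance:
#>     eigenvalue percent
#> 1 2.968495e-02   99.32
#> 2 2.024053e-04    0.68
#> 3 2.988835e-10    0.00

cl <- cluster_profiles(animal_profiles(fit), k = 5, seed = 1)
surv <- sim$survival
surv$cluster <- paste0("C", cl$cluster[surv$animal_id])
wald_test(fit_cox(surv))   # no simulated association: p is uniform
#> $statistic
#> [1] 0.6811777
#> $df
#> [1] 4
#> $p_value
#> [1] 0.9536297
```

At this deliberately small n (120 cows) the K estimate is noisy — the
level variance K[1,1] lands near 0.03 against a generating 0.022 and the
small shape variances are only loosely resolved — but heritability sits in
the 0.37–0.48 band implied by the generator, most coefficient variance
loads on the leading (level) eigenvalue, and the cluster–lifespan Wald
test is null as simulated.  The 500-animal replicates in the test suite
show the estimator unbiased at herd scale.

The same pipeline runs file-based from the shell, byte-reproducible under a
seed:

```sh
telotraj all --seed 1 --out-dir out/
# or stage by stage: simulate, rltl, fit, params, cluster, survival
```

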