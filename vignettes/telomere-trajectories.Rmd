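---
title: "Modelling longitudinal telomere length with random regression animal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal telomere length with random regression animal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotraj)
options(telotraj.log_level = "warn")
```

## The problem

Relative leukocyte telomere length (RLTL) is measured repeatedly over the
lives of pedigreed animals — here the motivating system is a dairy-cattle
herd sampled from birth to about 60 months of age, roughly 4.3 qPCR samples
per cow.  Three questions drive the analysis: how does RLTL change with age
at the population level; how much of the variation among individual
trajectories is additive-genetic, and does that share change with age; and
are individual trajectory shapes associated with how long a cow stays in
the herd (productive lifespan, right-censored for animals alive at study
end).

`telotraj` implements the full path from raw quantification cycles to those
answers, plus a synthetic-data generator with known ground truth so that
every stage can be verified without access to any particular herd's data.

## From quantification cycles to phenotypes

Each qPCR plate carries the study samples and one *calibrator* (the same
"golden" DNA on every plate).  With reaction efficiencies $E_{TEL}$ and
$E_{B2M}$ (fold amplification per cycle, estimated upstream from the raw
fluorescence curves and taken as inputs here),

$$RLTL = \frac{E_{TEL}^{\,Cq_{TEL}(cal) - Cq_{TEL}(s)}}
              {E_{B2M}^{\,Cq_{B2M}(cal) - Cq_{B2M}(s)}},$$

so the calibrator absorbs plate-level shifts: any additive change applied to
both sample and calibrator Cq values cancels exactly, and the calibrator's
own ratio is identically 1.  DNA extracts pass a quality gate first
(yield > 20 ng/µl, 260/280 > 1.7, 260/230 > 1.8, all strict, and an
integrity gel score in [1, 2], inclusive — the source protocol leaves the
boundary conventions open; we fix them this way and report every violated
rule rather than throwing).  RLTL ratios are natural-log transformed
(`log_transform`), which also reports a Shapiro–Wilk normality check; the
log base is a pure scale choice absorbed by the variance components, so
only its documentation matters.

## The random regression animal model

Ages $t$ in months are mapped to $x \in [-1,1]$ and expanded in Legendre
polynomials $\phi_k$, scaled by $\sqrt{(2k+1)/2}$ so the basis is
orthonormal — the convention standard in random-regression quantitative
genetics, which makes coefficient covariances comparable across studies.
The observation model for record $i$ of animal $j$ at age $t$ is

$$y_{tij} = \mathrm{BY}_j + \mathrm{GG}_j + \mathrm{plate}_{ij} +
  \mathrm{row}_{ij} + \sum_{k=0}^{n} \phi_k(t)\, b_k +
  \sum_{k=0}^{n} \phi_k(t)\, u_{jk} + e_{tij},$$

with birth year, genetic group, plate and row as class effects, a fixed
population regression $b$, and animal-specific random coefficient vectors
$u_j$.  Stacked across animals, $\mathrm{var}(u) = A \otimes K$: $A$ is the
pedigree numerator relationship matrix and $K$ the $(n{+}1)\times(n{+}1)$
coefficient covariance.  Residuals are i.i.d. with variance $\sigma^2_e$,
optionally one variance per age class; an optional scalar
permanent-environment effect per animal captures non-genetic repeatability.
Both polynomial orders default to 2 (quadratic), the final configuration of
the motivating analysis.

$A$ is never formed by the solver: `ainverse` assembles its sparse inverse
directly from the pedigree by Henderson's rules with Meuwissen–Luo
inbreeding coefficients (at most 9 contributions per animal), and
inbreeding is always accounted for — multi-generation closed herds have
$F \neq 0$.  Unknown parents are treated as unrelated founders; no
unknown-parent groups are fitted because no grouping structure is assumed.

### Estimation

Variance components are estimated by average-information REML.  The
likelihood and its derivatives are evaluated on the dense
$V = Z(A \otimes K)Z' + \sigma^2_{PE} S + R$ representation, which is cheap
at a few thousand records because every derivative
$\partial V / \partial K_{ab}$ is the Hadamard product of the record-level
relationship matrix with a rank-2 basis outer product.  Updates are
Newton steps on the average-information matrix, taken in Cholesky
coordinates of $K$ ($K = LL'$, with the score and curvature transformed
exactly, including the second-derivative term of the map): this removes
the PSD constraint, so optima on or near the cone boundary — nearly
singular $K$, common in small datasets — are reached cleanly instead of
being crawled toward under repeated bending.  Steps that would decrease
the restricted log-likelihood trigger Levenberg–Marquardt damping and
halving, only genuinely improving steps are ever accepted (the trace is
strictly monotone), and any $K$ supplied as a starting value is floored
into the PSD cone at $10^{-8}$ of its trace.  Convergence requires both
$|\Delta \log L_R| < 10^{-8}$ and a maximum relative parameter change
below $10^{-6}$ (both configurable), accepted only on an undamped full
Newton step or after a persistent stall.
Starting values are scale-aware: half the OLS residual variance to
$\sigma^2_e$, the other half spread over the diagonal of $K$.  The inverse
of the final average-information matrix is the asymptotic covariance of the
variance parameters used by all delta-method standard errors.

Solutions (BLUE fixed effects, BLUP coefficients for every pedigree animal,
prediction-error covariances) come from the sparse Henderson mixed-model
equations, whose random block carries $A^{-1} \otimes K^{-1}$; the two
routes agree because they maximise the same restricted likelihood.

### Model selection

Fixed-effect candidates (birth season, weights, condition scores, …) are
backward-eliminated by conditional Wald F-tests at $\alpha = 0.05$;
mandatory effects (birth year, genetic group, plate, row, and the age
regression) are never dropped, and candidates aliased with the retained
design are flagged and removed first.  Random structures are compared by
REML-AIC with the penalty counting only variance parameters, and a
two-unit parsimony rule: the preferred model is the simplest within two
AIC units of the minimum.  All models on the comparison ladder
(fixed-only → +animal identity → +pedigree → +random curves) share one
fixed structure, so their REML likelihoods are comparable; an ML mode
(`likelihood = "ml"`) is provided for comparisons across fixed structures,
where REML likelihoods would be invalid.  Residual heterogeneity across
age classes is assessed by refitting with per-class variances and
reporting both the AIC difference and a likelihood-ratio test; classes
with fewer than 10 records are merged with a neighbour.

## Genetic parameter trajectories

With $p = \phi(t)$ the basis row at age $t$:

* additive genetic variance $V_A(t) = p K p'$, non-negative whenever $K$
  is PSD;
* heritability $h^2(t) = V_A(t) / (V_A(t) + \sigma^2_{PE} + \sigma^2_e(t))$,
  with the permanent-environment term included only when it is in the
  model;
* genetic correlation
  $r(t_0, t) = p_0 K p' / \sqrt{(p_0 K p_0')(p K p')}$ against a reference
  age (birth by default);
* eigenvalues of $K$ with their percentage of total coefficient variance,
  and eigenfunctions $\psi_i(t) = \sum_k v_{ik}\phi_k(t)$ — the leading
  eigenfunction of an intercept-dominated $K$ is flat, i.e. variance in
  overall level rather than curve shape.

Standard errors for $h^2(t)$ and $r(t_0,t)$ use the delta method with
central finite-difference gradients (step $10^{-6}$ of each parameter's
scale) sandwiched with the asymptotic covariance; the tests validate this
against a parametric bootstrap of the variance parameters.  Individual
profiles $\sum_k u_{jk}\phi_k(t)$ are reported as deviations from the
fixed curve with $SE(t) = \sqrt{\phi(t)\,PEV_j\,\phi(t)'}$ from the full
prediction-error covariance; a mode that ignores coefficient covariances
(`se_mode = "independent"`) is provided for comparison because summing
per-order standard errors, as trajectory reports sometimes do, omits those
covariances.  Trajectories are evaluated on integer months across the
observed age range; the bounds are recorded in the fit so curves can be
re-evaluated later.

## Profile clustering and lifespan

Profiles are clustered as shapes, not vectors: the discrete Fréchet
distance (smallest achievable maximum pointwise gap over monotone
couplings of the two curves in the age–value plane) respects the ordering
of points along the trajectory.  Centers are seeded k-means++-style and
updated as pointwise medians, accepting an update only if it does not
increase the total within-cluster distance — so the objective is
non-increasing by construction — with five restarts keeping the best
objective; everything is deterministic given the seed.  This is a
deliberate, simpler stand-in for Fréchet-mean shape averaging with the
same intent (grouping by shape); it is not a re-implementation of any
specific package's algorithm.  The default of five clusters targets the
biologically interesting contrast: no change, mild/marked early-life
decline, mild/marked early-life rise.

Cluster–lifespan association uses Cox proportional hazards on days from
birth to culling, right-censoring animals alive at study end, with Breslow
tie handling (daily recording produces ties), the largest cluster as the
reference level (a stability choice), and a Wald chi-square over the
cluster coefficients.  The proportional-hazards fit itself is delegated to
the `survival` package — it is exactly Newton–Raphson on the Breslow
partial likelihood — while the surrounding contract (reference choice,
Wald test, monotone-likelihood flagging) is this package's.

## The synthetic-data generator

The generator emulates the motivating study design and provides the ground
truth that every test is scored against:

* **Pedigree**: a founder layer, a parent layer (default 40 sires, 241
  dams), and the phenotyped cow layer (default 308); the generic
  `simulate_pedigree` also produces deeper pedigrees where matings between
  relatives, and hence inbreeding, arise naturally.
* **Breeding values** by gene dropping: founders drawn from $N(0, K)$,
  descendants as the mid-parent average plus a Mendelian-sampling
  deviation with covariance $(0.5 - 0.25(F_s + F_d))K$ — exact and $O(N)$,
  never forming $A$.
* **Sampling schedule**: one record at birth plus 1–7 more at distinct
  random integer ages up to 60 months, mean 4.3 records per animal.  The
  post-birth age distribution is a stand-in choice, not an inference about
  any particular study's design.
* **Default truth**: $K = \mathrm{diag}(0.022, 0.0013, 0.0004)$ on the
  normalised quadratic basis and $\sigma^2_e = 0.016$ on the log scale.
  Chosen once to land in the reported ballpark of the motivating system:
  phenotypic variance ≈ 0.026 (raw-scale CV ≈ 0.16), $h^2$ ≈ 0.41–0.47
  across ages, birth–60-month genetic correlation ≈ 0.72, ≈ 93% of
  coefficient variance on the leading eigenvalue.  The fixed curve
  declines through early life with a mild late rise.
* **qPCR plates**: Cq values constructed so the noise-free calibrator
  ratio returns each target exactly; i.i.d. Gaussian noise (in cycles) on
  the two sample reactions then makes measured log RLTL normal around the
  log target with variance $\sigma^2_{Cq}(\log^2 E_{TEL} + \log^2
  E_{B2M})$.  In the end-to-end simulation the Cq noise SD is derived from
  $\sigma^2_e$, so the model's residual variance is physically realised in
  the plates.
* **Survival**: exponential event times with cluster-specific log hazards
  (all zero by default — no association, matching the motivating
  finding); censoring is an independent exponential with rate chosen so
  each animal is censored with exactly the nominal probability, rounded up
  to whole days.

What the generator does *not* emulate — selection of parents, genotype
data, assay batch drift beyond plate/row shifts, pulsatile within-animal
telomere dynamics — bounds what passing tests show: they demonstrate
correctness of the estimation machinery under the stated model, not that
the model captures every feature of real herd data.

## Numerical choices and limitations

* Problem sizes in the test-suite simulation studies (tiny 30-animal fits
  for oracle agreement, 20 replicates of 500-animal herds for recovery,
  200-animal herds for the AIC ladder) were chosen as the smallest designs
  at which the corresponding statistical property is identifiable with
  comfortable power.
* The 2-subject Cox configuration with one covariate has a monotone
  partial likelihood (no finite MLE); the package flags such fits rather
  than reporting a spuriously precise coefficient.
* Heritability SEs assume the variance parameters are in their asymptotic
  normal regime; at very small n the delta method and the bootstrap can
  disagree noticeably.
* Dense-V REML evaluation scales as the cube of the record count; beyond
  roughly $10^4$ records a sparse-factorisation update path would be the
  natural extension.
* Eigenvalue bending keeps $K$ estimable at the PSD boundary but means a
  truly zero genetic variance is reported as a tiny positive floor.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_study(n_animals = 120, seed = 1)
fit <- fit_reml(sim$phenotypes, sim$pedigree, rrm_model(),
                basis = legendre_basis(2, 0, 60))
heritability(fit, grid = c(0, 30, 60))
cl <- cluster_profiles(animal_profiles(fit), k = 5, seed = 1)
surv <- sim$survival
surv$cluster <- paste0("C", cl$cluster[surv$animal_id])
wald_test(fit_cox(surv))
```

The same flow, file-based, is available from the shell:

```sh
telotraj all --seed 1 --out-dir out/
```

which writes the simulated inputs, the RLTL table, fit solutions and
manifest, the trajectory and profile CSVs, cluster labels and curves, and
the Cox summary, all byte-reproducible under the same seed.
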