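---
title: "Transmission-based association for longitudinal quantitative traits: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-based association for longitudinal quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The retrospective transmission model

`qltdt` tests association between a biallelic SNP and a quantitative,
possibly multivariate phenotype in nuclear families by modelling
*allelic transmission conditional on phenotype*.  For each offspring $j$
with phenotype vector $Y_j \in \mathbb{R}^k$, two indicators are encoded
at every SNP with at least one heterozygous parent: $Z_j$, whether the
designated heterozygous parent (the father, when both are heterozygous)
transmitted the minor allele, and $W_j$, whether the other parent did.
Their conditional means are logistic,

$$\lambda_{Z,j} = \mathrm{expit}(\alpha_1 + \gamma^\top Y_j), \qquad
  \lambda_{W,j} = \mathrm{expit}(\alpha_2 + \gamma^\top Y_j),$$

with a shared slope vector $\gamma$ and separate intercepts.  Estimation
solves the quasi-score equations
$\sum_j D_j^\top V_j^{-1}(X_j - \lambda_j) = 0$ with the diagonal
Bernoulli working covariance $\lambda(1-\lambda)$, i.e. a generalized
estimating equation with working independence across transmissions.  The
test of association is the Wald statistic
$\hat\gamma^\top [\widehat{\mathrm{var}}(\hat\gamma)]^{-1} \hat\gamma$
referred to $\chi^2_k$, with a sandwich covariance.

Because the model is retrospective — transmissions given phenotypes — it
makes *no* assumption about the marginal or joint distribution of the
phenotype across time points.  Its validity rests on Mendelian
transmission probabilities and on the working assumption that
transmissions to different offspring are exchangeable given the parents.
The test is valid in the presence of linkage only insofar as
transmissions to siblings are treated as uncorrelated, which is the
model's stated working assumption.

### Why two intercepts

The designated parent is always heterozygous, so $Z_j$ is a fair coin
under the null and $\alpha_1$ estimates $\mathrm{logit}(1/2) = 0$.  The
other parent may be heterozygous or homozygous; the marginal frequency of
$W_j = 1$ depends on the population allele frequency, so forcing a
common intercept would push allele-frequency information into $\gamma$.
Separate intercepts keep the $k$-df test on $\gamma$ clean while
preserving the asymmetry between the two parental roles.

### Degenerate, deterministic, and ambiguous transmissions

The three non-obvious encodings, fixed by gamete enumeration:

* **Other parent homozygous** (dosage 0 or 2): $W_j$ is deterministic
  (0 or 1).  These components are *retained* by default, with the same
  logistic working model.  They carry between-family information — a
  homozygous-minor parent both guarantees $W_j = 1$ and raises the
  offspring's expected dosage — and are precisely where the method gains
  power over heterozygous-parent-only testing.  The same mechanism makes
  the test susceptible to population stratification (see the simulator's
  confounded scenario below); `include_deterministic = FALSE` restores
  the classical robustness at the cost of that power.
* **Both parents heterozygous, child heterozygous**: exactly one parent
  transmitted the minor allele but which one is unidentifiable.  The
  offspring contributes through the observable total $S_j = Z_j + W_j$,
  with mean $\lambda_{Z,j} + \lambda_{W,j}$ and variance the sum of the
  two Bernoulli variances.  This uses all observed information without
  fabricating an assignment.
* **Heterozygous-parent-only mode** (`mode = "het_only"`): only
  unambiguous $Z$ components enter and the model has a single intercept.
  With the canonical link and Bernoulli working variance the quasi-score
  is then *identical* to the logistic-regression score, so the fit equals
  ordinary logistic maximum likelihood — the test suite verifies this
  equivalence against `stats::glm` on random fixtures.

### The sandwich is clustered by family

Deterministic $W$ components are identical for all offspring of the same
family (they equal the homozygous parent's dosage/2), and offspring
phenotypes are correlated through shared family effects, so score
contributions are *not* independent across siblings once noninformative
parents are used.  The sandwich meat is therefore accumulated per family
by default (`clustered = TRUE`), which reduces to per-offspring
accumulation when families have one offspring and is never
anti-conservative.  The standard small-sample multiplier $G/(G-1)$ over
the $G$ independent units is applied.  Per-offspring accumulation
remains available for the strict working-independence reading, but is
inappropriate when deterministic components are included.

### Numerical choices

Fisher scoring from $\theta = 0$ with step-halving on the score norm;
convergence at max-abs quasi-score below `tol = 1e-8`, at most 100
iterations.  Intercept drift beyond $\pm 15$ on the logit scale flags
complete separation (`degenerate` status; the scan records it and moves
on).  Constant phenotype columns are rejected outright — with a constant
column, $\gamma$ is confounded with the intercepts.  A singular
information or $\gamma$-covariance block likewise yields a flagged,
skipped variant rather than an error: a genome scan must never stop on
one SNP.

## Phenotype preparation

The intended phenotypes are two correlated, right-skewed longitudinal
traits at four visits (a primary lipid trait and a covariate trait),
with a treatment administered between visits 2 and 3.

1. **Log transform** (natural log).  Advisory Kolmogorov–Smirnov checks
   against a normal with plug-in mean and SD are reported per column on
   the raw and log scales; with estimated parameters the classical KS
   p-value is anti-conservative (Lilliefors situation), so the check is
   a logged report, never a gate.
2. **EM imputation.**  Mean and covariance of the joint 8-column
   (trait × 4 visits, covariate × 4 visits) multivariate normal are
   estimated by EM on *founders only* — founders are the independent
   draws from the population, and using the joint covariance lets each
   trait borrow strength from the other at correlated visits.  Missing
   cells for **all** individuals (founders included) are then completed
   by the plug-in conditional expectation
   $\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(y_o - \mu_o)$.  EM numerical
   choices: available-case initial moments projected to the nearest PSD
   matrix; ML ($1/n$) covariance denominators throughout for
   EM-consistency; convergence at observed-data log-likelihood change
   below `1e-8`; at most 2000 iterations (heavy visit-level missingness
   with founder-sized samples legitimately needs several hundred);
   singular observed blocks fall back to an SVD pseudo-inverse with a
   warning; all-missing rows are dropped from the fit and imputed at the
   mean.
3. **Covariate adjustment** (the `*Adj` definitions): each trait visit
   is regressed, with intercept, on all four covariate visits — the
   adjustment is one equation in the four covariate measurements, not a
   per-visit pairing — by OLS *fitted on founders only*; residuals are
   then formed for every individual with the founder coefficients.
   Fitting on founders keeps within-family correlation out of the
   adjustment; applying it to everyone keeps residuals comparable.
4. **Principal-component construction.**  `TBATPre` is the first
   principal component of visits 1–2 (pre-treatment), `TBATPost` of
   visits 3–4 (post-treatment), `MTBAT` the bivariate pair — the
   treatment boundary motivates the 2+2 split.  Scores are projections
   of column-centered data on the leading eigenvector of the
   2×2 sample covariance; the eigenvector sign is fixed so its component
   sum is positive (ties: first component positive), preventing sign
   flips across runs and platforms.  Scores are computed over all
   individuals; the test uses the offspring rows.

The whole preparation is deterministic given its inputs.

## Filters and bookkeeping

* Minor-allele orientation and MAF use founders only; if the ALT
  frequency among genotyped founders exceeds 0.5 the counted allele
  switches to REF (ties keep ALT).  Orientation, MAF, and all downstream
  encodings are invariant to swapping the REF/ALT labels in the input.
* Variants that are monomorphic or have founder MAF < 0.05 are excluded,
  with a per-variant reason log.  The boundary is strict: MAF 0.05 is
  retained.
* A family enters a SNP's analysis only with both parents genotyped and
  at least one heterozygous; a variant is testable only with **more than
  20** informative families (≥ 21).
* Mendelian-inconsistent offspring are dropped from that variant's unit
  (not the whole family) with a warning; missing-genotype offspring are
  dropped silently.
* Benjamini–Hochberg FDR control is applied separately within each
  phenotype definition, over the variants with a valid test
  (untested/degenerate variants contribute no p-value and do not enter
  $m$); per-definition significant counts are the natural summary of
  such a scan.  Autosomal dosage data only; no X/Y/MT logic.

## The synthetic-family generator

The generator emulates the structure of a lipid-lowering-drug family
study: nuclear families with genotyped parents and offspring, two
correlated log-normal traits at four visits, treatment after visit 2,
visit-dependent missingness, and optional two-subpopulation
stratification.  Defaults (all overridable in `sim_config()`):

| parameter | default | rationale |
|---|---|---|
| families | 200 | study-scale pedigree count |
| offspring per family | uniform 2–8 | expectation 5/family, ≈ 1000 offspring; matches a ~990-offspring cohort |
| MAF | 0.30 | common variant, mid-range informativeness |
| trait mean (log scale) | 4.7 per visit | ≈ 110 raw units, lipid-like |
| residual SD (log) | 0.5, exchangeable ρ = 0.5 | right-skewed raw trait, correlated visits |
| family intercept SD | 0.3 | sibling phenotype correlation ≈ 0.25 |
| treatment effect | −0.3 on visits 3–4 | a lowering drug |
| covariate coupling | −0.4 per centered log-covariate | negatively related traits |
| covariate trait | mean 3.9, SD 0.25, ρ = 0.5 | ≈ 50 raw units |
| missingness | trait 0.27/0.002/0.44/0.26; covariate 0.27/0.001/0.28/0.22 | heaviest at visit 3, mirroring the motivating study's availability pattern |
| genetic effect `a` | 0 | log-units per minor allele carried, all visits, all individuals |
| stratification | off; when on: MAF 0.1 vs 0.4, trait shift δ = 0.6, equal mixture | MAF difference coupled to a ≈ 1-SD mean shift so naive association is confounded |

Parents are drawn under Hardy–Weinberg at the configured MAF (per
subpopulation when stratified); each parent transmits its minor-allele
count/2 as a Bernoulli gamete, independently per offspring.  A single
master seed spawns named substreams (structure, genotypes, phenotypes,
missingness), so changing one scenario dimension does not perturb the
draws of another, and identical seeds yield byte-identical output files.
The truth record (JSON, 17 significant digits) stores the configuration,
dosages, latent log-scale values and missingness masks, from which every
phenotype cell is recomputable exactly.

What the generator does **not** emulate: linkage disequilibrium between
variants (variants are independent), genotyping error, real allele
frequency spectra, correlated transmissions to siblings (transmissions
are exactly Mendelian given parents), informative missingness, and any
particular real-data locus.  Passing calibration and power checks on
these synthetic conditions therefore demonstrates the statistical
machinery under the model's own assumptions — not robustness to LD
structure or non-MCAR missingness in real cohorts.

### Calibration and power harnesses

`simulate_null_statistics()` and `simulate_power_curve()` run the
in-memory pipeline (simulate → log → principal components → encode →
fit → Wald) on one variant per replicate.  They default to complete
phenotypes via `calibration_config()`: the harness targets the sampling
distribution of the test statistic; EM/imputation correctness is
established by its own closed-form and simulation oracles, and running
founder EM inside thousands of replicates would add cost, not
information.  Replicate seeds are substreams of the master seed and are
shared across effect sizes and modes, so mode comparisons are paired.
The power study uses a genetic effect of 0.09 log-units per allele,
chosen once to put the both-parents test in the mid-power range at the
default study conditions.  Problem sizes used by the test suite and the
acceptance script — 2,000 null replicates, 1,000 paired power
replicates, 1,000 stratified replicates, 200 EM replicates of 117
founders — were chosen to make Monte-Carlo error small relative to the
effects being demonstrated.

## Known limitations

* The within-family independence of transmissions makes the test valid
  under linkage only in the trio-equivalent sense; no linear-mixed-model
  alternative is provided.
* Treatment enters only through the pre/post phenotype split, not as an
  interaction covariate inside the test.
* Phenotype imputation is single plug-in conditional expectation, not
  multiple imputation and not a joint genotype–phenotype likelihood;
  imputation uncertainty is not propagated into the test.  The
  retrospective formulation limits (but does not remove) the resulting
  optimism.
* No genotype imputation, no phasing, no parent-of-origin effects, no
  multi-generation decomposition beyond nuclear families.
* With noninformative-parent information included (the default), the
  test is *not* stratification-robust; the simulator's confounded
  scenario exists to make that visible, and `include_deterministic =
  FALSE` restores robustness at a power cost.
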