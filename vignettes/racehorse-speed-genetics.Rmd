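---
title: "Quantitative genetics of racehorse speed: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of racehorse speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`equigen` estimates quantitative-genetic parameters of racehorse speed
from two tables: a pedigree (`id`, `sire`, `dam`, `birth_year`, `sex`)
and a race-performance table (one row per horse per race).  This vignette
is the package's account of the science: the models, their assumptions,
the synthetic-data generator, and every numerical decision a maintainer
would want written down.

## 1. Data preparation

Finish times are converted to average speed in yards per second by
dividing the known race distance by the time (`time_to_speed()`); this
assumes all runners cover the same distance, i.e. identical running
lines.  Races are grouped into distance categories in furlongs (1 furlong
= 220 yards): sprint 5–7, middle 8–12, long 14–20, windows inclusive at
both ends, so a 13-furlong race belongs to no category.  Horse age is
fitted as a factor to avoid assuming a functional age–speed form; because
very few horses race beyond eleven, ages collapse to a 10-level factor
2, 3, …, 10, 11+ (`collapse_age()`).  Records with any missing required
covariate are dropped with a reported count; the package takes the going
(ground softness) score as already numeric.

Pedigrees are validated (acyclicity, unique ids, no individual used as
both sire and dam), topologically sorted parents-first with stable
tie-breaking by input order, and trimmed to informative individuals:
horses with records plus all of their ancestors (`trim_pedigree()`).
Unknown parents — empty, `0` or `NA` fields — are treated as founders
drawn from the base population, the standard animal-model convention.
Generation depth counts founders as generation 1.

## 2. The animal model

Speed is modelled as

$$ y = Xb + Z_a a + Z_{pe} p + Z_t t + e $$

with $a \sim N(0, A\,V_A)$ (A the numerator relationship matrix),
$p \sim N(0, I\,V_{PE})$, $t \sim N(0, I\,V_T)$,
$e \sim N(0, I\,V_R)$.  Variance is partitioned conditional on fixed
effects; $V_P$ is the sum of the four components,
$h^2 = V_A / V_P$ and the repeatability $R = (V_A + V_{PE}) / V_P$.
The trainer term matters scientifically: offspring of well-bred horses
tend to go to good trainers, and omitting the term pushes that common
environment variance into $V_A$ (the package's confounding test
demonstrates the inflation directly).

Two fixed structures are provided.  **Model A**: race identity, age and
sex factors.  **Model B** replaces race identity with race-level
covariates — a year factor (detrending against environmentally driven
linear change), timing method, racecourse, quadratics in distance, field
size and going, interactions of distance with continuous year, going and
field size, and of distance² with continuous year — plus the same age and
sex factors.  Continuous covariates are centred and scaled to unit
variance *before* polynomials and interactions are formed, which keeps
the quadratic columns well conditioned; the scaling constants are stored
with the design.  Factors use treatment coding with the alphabetically
first level as reference.  Continuous year enters Model B only through
its interactions with distance; its main effect would be collinear with
the year factor and is excluded.  Single-level factors and rank-deficient
columns are dropped with warnings, never silently.

### Relationship algebra

`relationship_matrix()` implements the tabular method
($a_{ii} = 1 + a_{sd}/2$, $a_{ij} = (a_{js} + a_{jd})/2$), dense, which
is comfortable to a few thousand individuals; inbreeding is
$F_i = a_{ii} - 1$.  Model fitting never inverts that dense matrix:
`ainverse()` uses the factorisation $A = TDT'$ implied by Mendelian
transmission, so $A^{-1} = (I - P/2)' D^{-1} (I - P/2)$ with $P$ the
parent incidence matrix and $D$ the diagonal of Mendelian sampling
variances $d_i$ ($1/2 - (F_s + F_d)/4$ with both parents known,
$3/4 - F_p/4$ with one, 1 for founders).  $A^{-1}$ is extremely sparse
and carries $\log|A| = \sum \log d_i$; the tests verify it against the
dense inverse and the tabular matrix against an independent recursive
kinship oracle.

### REML

The restricted likelihood is evaluated through the mixed-model equations
with one sparse Cholesky factorisation per evaluation
($-2\ell_R = (n-p)\log 2\pi + \log|R| + \log|G| + \log|C| + y'Py$), and
maximised over log-variances with Nelder–Mead (relative tolerance
1e-10, i.e. well inside a 1e-8 change in the log-likelihood).  Direct
maximisation on the log scale was chosen over EM iterations for boundary
robustness: components are free to run to (effectively) zero, a
component below $10^{-8} V_P$ is flagged as pinned, and failed
factorisations on the boundary are retried with a lifted floor.  The
optimum — not the iteration path — is the contract, and it is verified
three ways: against `lme4` on a relationship-free pedigree (agreement to
~1e-5 including the likelihood constant), against a dense-matrix
evaluation of the same restricted likelihood, and against the balanced
half-sib ANOVA estimator ($h^2 = 4\,t_{sire}$).  Standard errors come
from the inverse numerical Hessian of the restricted log-likelihood on
the variance scale (observed information), with a delta-method SE for
$h^2$; they are labelled as such since information-matrix SEs from other
software will differ slightly.  BLUP breeding values at the optimum are
defined for every pedigree individual, phenotyped or not.

Significance of $V_A$ uses the boundary likelihood-ratio test: twice the
log-likelihood difference against the model without the additive term,
referred to a 50:50 mixture of $\chi^2_1$ and a point mass at zero
(`mixture_lrt()`; the 5% critical value is 2.706).

### Gibbs sampling

`fit_gibbs()` implements a blocked Gibbs sampler: the entire location
vector (fixed plus all random effects) is drawn jointly from its
Gaussian full conditional using a sparse Cholesky factorisation whose
symbolic analysis is reused across iterations, and each variance is
drawn from its scaled inverse chi-squared full conditional
$(S + \nu V)/\chi^2_{q+\nu}$.  Priors are the conventional weakly
informative inverse-Wishart in univariate parameterisation,
$\nu = 0.002$, $V = 1$.  Chains are planned with `chain_plan()`; the
retained sample count is $\lfloor (n_{iter} - burn)/thin \rfloor$ (the
production-scale plan 2,000,000 / 800,000 / 1,200 retains exactly 1,000
draws).  One root seed drives each chain; identical seeds give
bitwise-identical draws.

Convergence checks (`diagnostics()`): a Heidelberger–Welch stationarity
test per component — Cramér–von Mises statistic on the standardised
cumulative sums, long-run variance from an AIC-selected AR fit to the
second half of the chain, iteratively discarding the initial 10% up to
50% — plus the lag-1 autocorrelation of retained draws, with pass flags
at $p > 0.05$ and $|\rho_1| < 0.1$.  A constant chain passes stationarity
with autocorrelation reported as undefined.

## 3. Cohort trends and the drift test

`beta_g_posterior()` computes, per retained draw, the arithmetic mean
breeding value of each birth cohort (phenotyped horses by default) and
the unweighted OLS slope on birth year, giving a posterior for the rate
of genetic change $\beta_G$.  Unweighted regression follows the
convention of reporting the cohort series as-is; weighting by cohort
size is available as an option.  The point estimate is the
kernel-density mode (Gaussian kernel, Silverman's rule-of-thumb
bandwidth); intervals are 95% highest-density intervals; a "significant"
trend is conventionally declared when $P(\beta_G > 0) > 0.95$.  When a
phenotypic trend $\beta_P$ is supplied the ratio $\beta_G/\beta_P$ is
reported.

Because mean breeding values drift even under neutrality, a significant
$P(\beta_G > 0)$ is not evidence of selection.  `run_drift_test()`
therefore simulates neutral breeding values down the *actual* pedigree:
founders (and unknown-parent contributions) from $N(0, V_A)$, offspring
the mean of known parents plus a Mendelian deviation of variance
$d_i V_A$ — the same inbreeding-corrected $d_i$ as the relationship
factorisation, so simulated values have covariance exactly $A V_A$.
Each of $n_{sim}$ replicates draws its $V_A$ from the posterior (with
replacement), gene-drops, and computes the cohort-mean slope over the
same individuals and window as the observed trend, keeping the null
comparable.  The default pairing rule compares each drift slope with an
independent with-replacement resample of the $\beta_G$ posterior;
comparing every $\beta_G$ draw against the whole drift distribution is
available as `mode = "distribution"` (the two agree in expectation).
Selection is declared when $P(\beta_G > \text{drift}) > 0.95$.

A note on identifiability that the package's own simulations make vivid:
with race (or year) and age factors in the model, a linear cohort trend
in breeding values is exactly collinear with the fixed effects
(cohort = year − age), so the trend direction is identified only through
the pedigree prior — offspring means are tied to parental means.  With
hundreds of thousands of records that channel is strong; at the scale of
the package's test simulations it attenuates estimated trends
substantially.  This is why the drift-test power checks run on a
high-information configuration (heritability 0.6–0.65, seven records per
horse, a 16-year breeding horizon, truncation selection keeping the top
10% of sires and 40% of dams), chosen so the generator's realised trend
exceeds five drift-slope standard deviations; at the study's published
scale the same test has power at realistic heritabilities, but no method
could detect a 0.009 yards/s/year trend from a few hundred horses at
$h^2 = 0.124$.

## 4. Genetic correlations across distance categories

`fit_bivariate_gibbs()` fits a two-trait animal model with an
unstructured 2×2 additive covariance $\Sigma_A \otimes A$ (inverse-
Wishart full conditional, $\nu = 0.004$, scale $I$), reporting the
genetic correlation $r_G = \Sigma_{12}/\sqrt{\Sigma_{11}\Sigma_{22}}$ as
a kernel-density posterior mode with a 95% HPD interval.  Residual
covariance between traits is fixed at zero: records for different
distance categories come from different races, which are distinct
events.  Trainer effects are independent across traits.

Permanent-environment effects carry an unstructured 2×2 covariance by
default.  This was a deliberate design change after a failed diagonal
default: when the additive/permanent-environment split is weakly
identified (few sire families, few records), a diagonal PE structure
forces *all* cross-trait covariance of repeatedly measured horses
through $\Sigma_A$, and the $r_G$ posterior piles up at +1 regardless of
the simulated truth — a pathology we reproduced with an independent
minimal sampler, so it is structural, not an implementation artefact.
With the unstructured default the truth (independent PE) is inside the
model space and the bias disappears when the pedigree is informative.

**Known limitation.**  At desk scale (pedigrees of a few hundred, a
handful of sire families) $r_G$ remains weakly identified, and roughly
one chain in six wanders to the $|r_G| = 1$ boundary and mixes too
slowly to escape within affordable chain lengths; parameter-expanded
samplers are the established cure and are out of scope here.  The test
suite therefore checks what desk scale honestly supports — exact
recovery of self-correlation, an unidentifiability error for disjoint
unrelated trait sets, null coverage at $r_G = 0$, and majority coverage
plus sign detection at $r_G = 0.5$ over pre-registered seeds — and does
not claim calibrated 95% coverage near the boundary.  Estimates from
data at the published scale (tens of thousands of horses per trait,
thousands of sires) do not sit in this regime.

## 5. Selection intensity

For a trait under truncation selection with repeated records,

$$ i = \frac{\beta_G L}{h\,\sigma_A\,\sqrt{n / (1 + (n-1)R)}} $$

with $L$ the generation interval (mean parental age at offspring birth,
sire and dam pairs pooled — `generation_interval()`), $n$ the mean
record count per horse (a scalar; per-horse weighting is out of scope)
and $R$ the repeatability.  `intensity_to_proportion()` inverts the
standard-normal truncation identity $i(p) = \phi(\Phi^{-1}(1-p))/p$ by
bracketed root-finding on $(10^{-8}, 1 - 10^{-8})$ with tolerance
$10^{-10}$ in $p$ (the attainable maximum is $i \approx 5.85$ at the
lower bracket; larger intensities raise an error naming the bound).
Reference points: $i(0.5) = 2\phi(0) \approx 0.798$; $i = 1.202$, 0.905
and 0.317 invert to about 28%, 43% and 82% of the population selected.

## 6. The synthetic-data generator

`simulate_horse_data()` produces the structure the analyses assume, with
ground truth for every stage.  The pedigree grows year by year with
overlapping generations: parental ages are drawn from a distribution on
4–15 years with mean 9.5 (matching typical thoroughbred generation
intervals); matings concentrate on a small sire pool —
`sire_pool_fraction` of eligible males, the top fraction ranked by true
breeding value under selection (`true_genetic_trend > 0`), a random
fraction of the same size otherwise, so family structure does not change
between selected and neutral populations; dams produce at most one foal
per year.  True breeding values follow exactly the gene-drop
transmission rule (founders $N(0, V_A)$, inbreeding-corrected Mendelian
sampling), so their covariance is $A V_A$ by construction; the generator
maintains the relationship matrix incrementally to do this exactly.

Records: each racing horse gets $1 + \text{Poisson}(\bar{n} - 1)$ starts
at ages drawn from a front-loaded career distribution over 2–11; records
group into races within years (about ten runners per race); races carry
distance (uniform in the category window), going, racecourse and timing
method; observed speed is the fixed part (age, sex, covariate
polynomials, racecourse, timing) plus breeding value, permanent
environment, trainer effect and residual, and finish time is
back-computed from speed.  Trainer assignment can optionally follow sire
breeding-value rank with sorted trainer effects, reproducing the
"better-bred horses go to better trainers" confounding; the package's
tests use it to demonstrate the heritability inflation from omitting the
trainer term.

Default parameters describe a sprint-like population: mean speed 18
yards/s, phenotypic variance 0.16 (SD 0.4), partitioned as $h^2 = 0.124$,
$R = 0.35$ and a 10% trainer fraction, with 5.96 records per horse —
the conditions under which the variance-component recovery checks run.
What the generator does *not* emulate: race tactics and drafting,
heterogeneous residual variances, dead-heats and disqualifications,
surface changes, maternal effects.  Passing tests therefore validate the
statistical machinery under the model's own assumptions, not robustness
to these violations.

Problem sizes used by the test suite (the package's choice of desk
scale): recovery runs on ~1,500 phenotyped horses with ~6 records each;
drift calibration and power use 20 replicates per arm of a ~640-horse
pedigree; oracle comparisons use pedigrees of 40–200.  Reproducibility
contract: every stochastic function takes a seed; pipeline stages derive
child seeds deterministically from one root seed, and each run writes a
manifest naming the seed and a hash of the configuration.

## 7. Numerical choices, collected

* Topological sort: layered Kahn sweep, stable within rounds; cycles
  reported with a member id.
* Unknown parents: founders; both `0`, `NA` and empty accepted in files.
* Category windows inclusive at both ends; overlap is a configuration
  error.
* Design: treatment coding, first level reference; covariates
  standardised before polynomials; rank deficiency resolved by pivoted
  QR with a 1e-7 tolerance.
* REML: Nelder–Mead on log-variances, reltol 1e-10, max 2000
  evaluations; component floor $10^{-10} V_P$ during the final solve,
  lifted in factors of 100 if the boundary factorisation fails; SEs
  from `pracma::hessian` on the variance scale.
* Gibbs: symbolic Cholesky reused; variance full conditionals
  $(S + \nu V)/\chi^2_{q+\nu}$; divergence (non-finite draw) aborts with
  the offending iteration.
* KDE mode: `density(bw = "nrd0")`; HPD: shortest sorted-sample
  interval.
* Root-finding: `uniroot` on $(10^{-8}, 1-10^{-8})$, tol $10^{-10}$.
* Drift pairing: independent resampling of both posteriors (default),
  whole-distribution comparison as an option.
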