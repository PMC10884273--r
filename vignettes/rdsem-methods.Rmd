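---
title: "Two-level residual DSEM for longitudinal substance-use cohorts: model, sampler and synthetic-cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level residual DSEM: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

`rdsem` analyses panel data from substance-use-disorder (SUD) recovery
cohorts in which three continuous outcomes are followed over several years
on an unequally spaced schedule: the DUDIT-C drug-consumption score (0–8),
the Satisfaction With Life Scale sum score (SWLS, 5–35) and the SCL-90-R
Global Severity Index (GSI, 0–4). The scientific questions are dynamic:
does a person who is *above their own typical level* of psychological
distress at one occasion tend to use more drugs three months later? Do
substance use and life satisfaction move together around their long-term
trends? Answering these requires separating three sources of variation that
ordinary regression conflates: stable person-level differences, slow
person-specific time trends, and occasion-to-occasion fluctuation around
those trends.

## The model

For outcomes $v \in \{\mathrm{DUDIT}, \mathrm{SWLS}, \mathrm{SCL90R}\}$,
person $i$ and occasion $t$ (time $t$ in years since baseline):

$$y_{vit} = \alpha_{vi} + \beta_{vi}\, t + \varepsilon_{vit},$$

with a lag-1 vector autoregression on the *detrended residuals*

$$\boldsymbol\varepsilon_{it} = \Phi\, \boldsymbol\varepsilon_{i,t-1} +
\mathbf u_{it}, \qquad \mathbf u_{it} \sim N(\mathbf 0, \Sigma_u),$$

and a between-person level

$$(\boldsymbol\alpha_i, \boldsymbol\beta_i) = \Delta' \mathbf x_i +
\mathbf b_i, \qquad \mathbf b_i \sim
N\!\big(\mathbf 0,\ \mathrm{blockdiag}(\Sigma_b,
\mathrm{diag}(\sigma^2_{\beta}))\big),$$

where $\mathbf x_i$ holds an intercept, gender (male = 1) and standardized
baseline age. Modelling the autoregression on residuals rather than on the
outcomes themselves (the "r" in rDSEM) keeps the lagged effects from being
confounded with growth: a person recovering steadily would otherwise show
spurious positive autocorrelation. Latent centring — estimating
$\alpha_{vi}, \beta_{vi}$ jointly with everything else rather than plugging
in observed person means — avoids the bias that observed-mean centring
incurs with few occasions.

Assumptions worth stating explicitly:

* $\Phi$ is a **fixed effect** (shared across persons). Eleven observed
  occasions per person are too few to support random AR slopes.
* The sparsity of $\Phi$ follows the substantive model: the substance-use
  residual is predicted by all three lagged residuals; life satisfaction
  and distress carry only their own lags (five free lagged paths).
  `build_model_spec("full")` frees all nine for sensitivity work.
* $\boldsymbol\varepsilon_{i1}$ is drawn from the stationary distribution
  $N(\mathbf 0, \Sigma_\varepsilon)$ with
  $\mathrm{vec}(\Sigma_\varepsilon) = (I - \Phi \otimes \Phi)^{-1}
  \mathrm{vec}(\Sigma_u)$, so early occasions are exchangeable with later
  ones; a diffuse start is available by flag in the generator.
* Outcomes are treated as continuous Gaussians on a downscaled metric
  (DUDIT-C divided by 5, SWLS by 10), which puts the three instruments on
  comparable ranges and materially helps MCMC conditioning.

## Unequal spacing and missingness

The cohort schedule is quarterly for the first two years and annual
thereafter (preset `"stayer11"`: months 0, 3, …, 24, 36, 48). A lag-1
coefficient only has a constant meaning on a constant grid, so
`expand_time_lattice()` inserts *phantom occasions* at every 3-month
multiple between the schedule end points; phantom cells and genuinely
missing cells are treated identically — as latent values to be integrated
over, never imputed into the data file. `missingness_patterns()`,
`icc1()` and `distribution_by_missingness()` provide the descriptive side:
cluster sizes (attended occasions per person, where attendance means any
recorded response at the occasion), the $2^3$ outcome-missingness patterns,
intraclass correlations, and a rank-based check (Wilcoxon plus Cliff's
delta) of whether an outcome's observed distribution depends on another
outcome's missingness.

## Priors

Two regimes, both fully conjugate for the Gibbs sampler:

| block | reference | admissible range |
|---|---|---|
| lagged coefficients | $N(0, 10^2)$ | $N(0, 0.5^2)$ truncated to $(-1, 1)$, non-stationary $\Phi$ rejected |
| location parameters | $N(0, 10^2)$ | $N(0, 1)$ |
| $\Sigma_u$, $\Sigma_b$ | inverse-Wishart$(5, 0.01 I)$ | same |
| trend variances | inverse-gamma$(2, 0.01)$ | same |

The covariance scale matrices are $0.01 I$, not $I$: on the downscaled
metric the innovation variances are $\sim 0.1$–$0.25$ and between-level
variances smaller still, so a unit scale would be strongly informative
rather than weak. The admissible-range regime concentrates mass on the
theoretically meaningful region; in practice it shifts lagged estimates
slightly towards zero (`prior_sensitivity()` quantifies this), which we
read as a gain in precision, and it is the default reporting regime.

## The sampler

`fit_mcmc()` runs a blocked Gibbs sampler with data augmentation, written
in C++ (RcppArmadillo) with all randomness drawn from R's RNG so that runs
are exactly reproducible from a seed:

1. **Missing and phantom cells** are drawn *jointly per person* by forward
   filtering / backward sampling on the 3-dimensional residual state,
   conditioning exactly on the observed components of each occasion. A
   single-cell sweep would mix like a random walk across the seven
   consecutive phantom occasions between the annual waves; the joint draw
   removes that bottleneck.
2. **Person effects** $(\boldsymbol\alpha_i, \boldsymbol\beta_i)$: 6-dim
   conjugate normal, one shared precision Cholesky per scan.
3. **$\Phi$ and $\Sigma_u$**: Metropolis-within-Gibbs. The conjugate
   conditional based on the transition terms alone is used as an
   independence proposal; the stationary initial-occasion densities enter
   the acceptance ratio. The chain therefore targets the *exact* posterior
   implied by `complete_data_log_density()` times the priors, stationary
   initial term included. Acceptance rates are around 0.9 ($\Phi$) and
   0.65 ($\Sigma_u$) on cohort-sized data.
4. **Between-level coefficients and covariances**: conjugate
   (matrix-)normal, inverse-Wishart and inverse-gamma updates.

Because roughly half of all residual cells are latent (phantom occasions
plus item missingness), the augmented within-level state and
$(\Phi, \Sigma_u)$ are strongly coupled. Each scan therefore visits the
within-level blocks (steps 1–3) twice (`within_updates = 2`); every scan
is stored — there is no thinning — and effective sample sizes are reported
as measured. Defaults: 2 chains, 5,000 iterations with the first half as
warmup, convergence declared at split-chain rank-normalized
$\widehat R < 1.05$ with a target effective sample size above 400 per
reported parameter; a fit failing the $\widehat R$ threshold is returned
*flagged*, with a warning, never silently. Starting values are
data-derived (person means; zero slopes and lags), and warmup of half the
run is conservative — chains reach the typical set within a few hundred
scans.

## STDYX standardization and R²

Coefficients are standardized draw by draw with model-implied standard
deviations at the appropriate level, then summarized (posterior mean, SD,
equal-tailed 95% credible interval, and a credibility flag set exactly when
the interval excludes zero).

Within level, the total within-person variance of outcome $v$ in cluster
$i$ is

$$V_{vi} = \beta_{vi}^2\, \mathrm{Var}(t) + \Sigma_{\varepsilon, vv},$$

the trend contribution plus the stationary variance of the residual
autoregression, with $\mathrm{Var}(t)$ taken over the nominal schedule.
Lagged paths are scaled by the stationary residual SD of the predictor and
the cluster-averaged reciprocal of $\sqrt{V_{vi}}$; the trend effect of
cluster $i$ is $\beta_{vi}\sqrt{\mathrm{Var}(t) / V_{vi}}$, averaged over
clusters (the cluster-average convention; a pooled alternative would
weight clusters by their variances instead). Within-level covariances are
reported as innovation correlations. The within-level $R^2$ is **defined**
by the identity

$$R^2_{v,\mathrm{within}} = 1 - \Sigma_{u,vv}\,
\overline{V_{vi}^{-1}},$$

i.e. one minus the standardized innovation variance; the identity holds
per draw by construction and the test suite asserts it to machine
precision. (With this definition the three within-level $R^2$ values are
forced consistent with the standardized residual variances; published
tables that report both can disagree in their labelling, and the identity
is the arbiter here.) Between level, totals are covariate-explained plus
residual variance; between-level $R^2$ is the explained share.

## The synthetic-cohort generator

No raw cohort data are distributable, so the package carries a first-class
generator whose defaults *are* the study conditions: $N = 164$ persons,
the 11-occasion schedule, 62.2% male, baseline age with mean 27.1 and SD
7.1 years truncated at the inclusion minimum of 16 (the location parameter
is solved so the *truncated* mean is 27.1), the printed cluster-size
(attrition) distribution with 75% of persons attending all 11 occasions,
and item missingness at attended occasions with rates (DUDIT 0.27, SWLS
0.05, GSI 0.35) chosen to reproduce the published complete-occasion count
to within a few percent — the published pattern counts overlap ambiguously,
so these rates are deliberately approximate. Life-satisfaction missingness
odds are multiplied by 3 at occasions where the observed drug-use score
exceeds its occasion-specific expectation: missing-at-random by
construction (the mechanism conditions only on observed values), and
strong enough that the dependence diagnostic detects it at cohort size.

### Calibration to the standardized table

`calibrate_to_stdyx()` solves for unstandardized generating parameters
such that the *model-implied* STDYX quantities — computed with exactly the
standardization above, with cluster averages replaced by Gauss–Hermite
(41-node) expectations over the population distribution of trend slopes —
reproduce a target table of standardized values. A fixed-point iteration
alternates between unstandardizing the lagged paths and innovation
variances given the current stationary covariance, and a one-dimensional
root solve per outcome for the split of trend-slope mean versus SD; it
converges in ~30 iterations to residuals around $10^{-10}$, far inside the
0.005 reporting tolerance, and fails loudly (with diagnostics) when the
targets are non-stationary or jointly infeasible.

Two scales are genuinely free in a standardized table and are set as
design choices:

* **Within scale** (`within_scale`): the average within-cluster total
  variance per outcome on the analysis metric (defaults 0.16 / 0.21 /
  0.25), picked so raw-scale values resemble the cohort's baseline
  distributions.
* **Between scale**: set from the target intraclass correlations read as
  the *latent-level* share $\mathrm{Var}(\alpha_v) /
  (\mathrm{Var}(\alpha_v) + V_v)$. The random trends additionally disperse
  raw person means, so the generator's raw-data ANOVA ICC exceeds these
  latent shares for outcomes with large trend variance. We accept that
  mismatch deliberately: tying the scale to the raw ANOVA quantity instead
  would drive the substance-use intercept variance below the $N = 164$
  estimation noise floor and make the between-level covariance block
  unidentifiable — contradicting the precision with which the published
  analysis reports that block.

One genuine incompatibility in the target table deserves note. Matching
the standardized residual variances (0.766 / 0.738 / 0.702) together with
the cluster-averaged standardized trends ($-0.135$ / $0.191$ / $-0.036$)
forces the random trend slopes to carry roughly 20–40% of within-person
variance, with slope SDs much larger than slope means. The between-level
standardized *trend intercepts* (mean/SD ratios around $-0.07$ to $-0.26$)
are then arithmetically incompatible with the within-level trend rows —
no parameter configuration satisfies both. The calibration targets the
within-level rows (the quantities the recovery experiment is anchored on)
and ignores the between-level trend-intercept rows.

### What the generator does and does not emulate

It emulates: the two-level dynamics, the demographic mix, attrition via
the cluster-size distribution (rather than a hazard model — the
distribution is the only attrition information available), item
missingness with a realistic MAR dependence, and the unequal schedule. It
does **not** emulate: discreteness/skewness of the instruments (outcomes
are Gaussian on the rescaled metric; range clipping exists but is off by
default because it biases recovery), floor effects in DUDIT-C among
abstinent participants, or informative (MNAR) dropout. Passing recovery
tests therefore demonstrate that the estimator inverts the *assumed* data
generating process at the study's size and missingness — not that the
Gaussian assumption is harmless for real instrument data.

## Numerical choices

* Stationary covariances solve the discrete Lyapunov equation by a dense
  $9 \times 9$ linear solve; proposals with spectral radius $\ge 0.995$
  are rejected in both prior regimes (the stationary density degenerates
  at the boundary).
* Gaussian draws use precision Cholesky factors; the backward-sampling
  covariance gets a $10^{-12}$ diagonal jitter before factorization.
* Age is sampled by rejection at the truncation bound (acceptance
  $\approx 0.94$).
* Fixed-point calibration tolerance $10^{-10}$; Gauss–Hermite with 41
  nodes (exact for polynomial degree 81, ample for the smooth integrands
  involved).

## Validation problem sizes

The test suite validates the pipeline end to end at sizes chosen to keep
the experiments sharp: one recovery experiment at the study conditions
($N = 164$, 2 × 5,000 iterations) checked against the published
standardized estimates at twice their reported posterior SDs; a
20-replicate null-coverage study ($\Phi = 0$, $N = 80$, 2 × 2,000
iterations) requiring 95% intervals to cover zero in at least 18 of 20
replicates per lagged path; brute-force joint-Gaussian oracles for the
complete-data density on 2-person instances; and 10,000-person draws for
the demographic and attrition calibration checks. Monte-Carlo tolerances
in tests are set a priori at roughly three standard errors of the checked
quantity.

## Known limitations

* **Finite-sample tilt of own-lag estimates under heavy missingness.** With
  the study's missingness (~60% of drug-use cells latent once item
  missingness, attrition and phantom occasions are counted), the marginal
  posterior of an own-lag coefficient sits on a likelihood ridge against
  that outcome's person-level variance (posterior draw correlations around
  $-0.5$); because the variance is bounded at zero, integrating along the
  ridge tilts the marginal posterior mean positive — about $+0.09$ at
  $N = 80$ and $+0.02$–$0.05$ at $N = 164$ for the most-missing outcome,
  vanishing by $N = 1000$. Consequences: 95% credible intervals for a truly
  null own-lag cover zero at roughly 70–90% rather than the nominal rate in
  small cohorts (the package's own null-coverage experiment documents
  this), and own-lag recovery estimates sit slightly above their generating
  values. This is posterior geometry, not a sampler artifact: the sampler's
  conditionals are verified against brute-force Gaussian oracles, and the
  bias scales inversely with the observed information. Interpret weakly
  identified own-lag persistence in small, sparsely observed cohorts with
  corresponding caution.
* Gaussian outcome families only; no ordinal measurement model.
* AR effects are fixed, trends linear; no random AR slopes or splines.
* The between-level covariance of trend slopes is diagonal (the published
  analysis reports none), so trend–trend coupling across outcomes is not
  recoverable.
* Model comparison (DIC/WAIC) and variational approximations are out of
  scope.
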