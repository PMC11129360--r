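---
title: "Estimating and forecasting small-area mortality under incomplete death registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and forecasting small-area mortality under incomplete death registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Small-area mortality estimation faces two compounding problems. With few
person-years of exposure, observed age-specific death rates are dominated
by Poisson noise; and where vital registration is incomplete, the counts
that are observed systematically understate mortality, by amounts that
differ by age, sex and region. `samort` implements a nine-stage pipeline
that addresses both, plus a probabilistic forecast of the resulting
schedules, with a synthetic-data module so that every stage can be checked
by parameter recovery. This vignette records the models, the parameters
that matter, the numerical choices, and the places where the design was
genuinely open.

## The TOPALS relational model

A relational model borrows strength from a reference pattern. The area's
log-mortality schedule over single ages 0–99 is

$$\lambda(\alpha) = \lambda^* + B\,\alpha,$$

where $\lambda^*$ is a standard log-rate schedule (here, the pooled
national schedule computed from the data being fit, configurable),
$B$ is a $100\times 7$ matrix whose columns are linear B-spline hat
functions with knots at exact ages 0, 1, 10, 20, 40, 70, 100, and
$\alpha$ holds the offsets at the knots. Offsets vary linearly between
knots, so seven parameters describe any smooth departure from the
standard.

Deaths are modelled as independent Poisson counts, giving the
log-likelihood $\sum_x [D_x \lambda_x(\alpha) - N_x e^{\lambda_x(\alpha)}]$.
`fit_topals()` maximizes this minus two quadratic penalties:

* a smoothness penalty $w \sum_{j\ge 2} (\alpha_j - \alpha_{j-1})^2$
  (default weight $w = 1$) that keeps the offset function from oscillating
  implausibly, the construction used in the original TOPALS fitting
  literature; and
* a small ridge $r \sum_j \alpha_j^2$ (default $r = 10^{-4}$) whose only
  role is to bound the maximizer for degenerate inputs such as zero deaths
  at every age.

The penalized objective is strictly concave (Poisson log-likelihood
concave in $\lambda$, $\lambda$ linear in $\alpha$, penalties quadratic),
so the damped Newton iteration with analytic gradient and Hessian
converges monotonically; the implementation halves the step until the
objective increases and stops when the gradient max-norm falls below
$10^{-8}$ (cap of 50 iterations; non-convergence is flagged, not hidden).
Scale matters: with penalties fixed, multiplying deaths and exposures by a
common factor slightly re-balances data against smoothness, so only the
unpenalized fit is exactly scale-invariant.

## The Bayesian completeness model

Registered deaths $R_x$ are a binomial thinning of true deaths with
age-block coverage $\pi$, hence marginally Poisson:
$R_x \sim \mathrm{Poisson}(N_x\, \pi_{b(x)}\, e^{\lambda_x(\alpha)})$.
Only the product $\pi e^\lambda$ is identified — high mortality with low
registration is observationally equivalent to low mortality with high
registration — so prior information must carry the identification:

* **Coverage prior** $f_\pi$: independent Beta priors per sex and age
  block. The default blocks are child (0–4) and adult (5+), reflecting
  the child/adult distinction under which registration-coverage estimates
  are usually published; block boundaries are configurable. A Beta whose
  shape parameters sum to $10^7$ or more is treated as a point mass (used
  for the complete-registration scenario, under which the model collapses
  exactly to the penalized TOPALS fit).
* **Schedule prior** $f_\alpha$: independent normals on the consecutive
  offset differences with sd $1/\sqrt{2}$ — the Bayesian counterpart of the
  TOPALS penalty at weight 1 — plus a weak normal (sd 2) on the first
  offset so the prior is proper.

`sample_posterior()` targets the joint posterior of $(\alpha, \log \pi)$.
The sampler design matters here: the likelihood ridge
$\alpha_{\text{level}} + \log\pi \approx \text{const}$ is exactly linear
in $\log\pi$ (not in $\mathrm{logit}\,\pi$), so the chain parameterizes
coverage on the log scale, starts at the posterior mode (quasi-Newton)
with the mode's inverse Hessian as initial proposal covariance, re-learns
the covariance from its own burn-in history, and after burn-in alternates
random-walk steps with independence draws from a heavy-tailed
multivariate-$t$ (df 4) fitted at the adapted moments. The $\pi \le 1$
boundary is handled by rejection. This was validated two ways:
against deterministic grid quadrature on a two-parameter reduction
(posterior means and sds agree to Monte-Carlo error), and by
credible-interval calibration over 200 replicates with truth drawn from
the priors (empirical 95% coverage ≈ 0.95). Acceptance rate outside
[0.1, 0.6] triggers a diagnostic warning; multi-chain runs report
split-Rhat.

**Completeness and municipal adjustment.** Age-specific completeness is
the ratio of the unadjusted TOPALS rate to the coverage-adjusted rate,
$c_x = \exp(\lambda^{\text{unadj}}_x - \lambda^{\text{adj}}_x)$, using the
posterior median for the adjusted schedule (the median is the point
summary used throughout; the spread of the posterior is reported as
quantiles). Values above 1 are stochastic noise and are clipped to 1 (the
count of clipped ages is recorded). Municipal schedules — for which no
reliable coverage priors exist — are adjusted by their microregion's
completeness, $\lambda^{\text{adj}}_{\text{muni}} = \lambda_{\text{muni}}
- \log c_x$, under the assumption that under-registration is homogeneous
across the municipalities of a microregion. Because $c_x \le 1$, adjusted
rates never fall below unadjusted ones, and adjusted life expectancy can
only fall.

## Spatial smoothing and the outlier rule

Municipal rates, even adjusted, remain noisy. Marshall's local
empirical-Bayes estimator shrinks each area's rate toward its
neighbourhood mean with a data-estimated factor: with exposure-weighted
neighbourhood mean $m_i$ and variance $s_i^2$, the between-area variance
estimate is $A_i = s_i^2 - m_i/\bar n_i$ and the shrinkage weight
$C_i = A_i/(A_i + m_i/n_i)$ when $A_i > 0$, else 0 (full shrinkage under
apparent under-dispersion, Marshall's truncation). Design choices, both
configurable at the call site:

* **Neighbourhood**: municipalities sharing a microregion (self-inclusive).
  This needs no contiguity data and is consistent with the homogeneity
  assumption already made for the completeness adjustment; any
  self-inclusive named list (e.g. queen contiguity) can be passed instead.
* **Scale**: smoothing is applied per sex and single age on the *rate*
  scale, where the Marshall moment identities are exact; log-scale
  smoothing would break them.

After smoothing, life expectancies above the boxplot upper fence
$Q_3 + 1.5\,(Q_3 - Q_1)$ (type-7 quartiles, the interpolation convention R
uses by default; multiplier configurable) are deemed implausible — in
under-registered settings spuriously *high* e0 is the typical artifact —
and the municipality's full schedule is replaced by its microregion's
adjusted schedule, with counts logged per macroregion.

## Life tables

`lifetable_from_mx()` builds single-year tables with radix 1 using
$q_x = m_x / (1 + (1-a_x) m_x)$. Conventions the literature leaves open,
with our defaults:

* $a_x = 0.5$ at ages 1+ (mid-interval deaths);
* $a_0 = 0.07 + 1.7\,m_0$ capped into $[0.05, 0.35]$, a Coale–Demeny-style
  infant separation factor (`a0_rule = "midpoint"` gives $a_0 = 0.5$ for
  closed-form checks, and an explicit `a0` can be supplied);
* the open interval beyond age 99 is closed with a constant hazard equal
  to $m_{99}$, i.e. $T_{100} = l_{100}/m_{99}$.

Summary measures: $e_0$ and conditional $e_{65}$; the median age at death
and the interquartile range of the age at death, both read off the
survivor function by linear interpolation of $l_x$ between integer ages
(IQR = age where $l$ crosses $0.25\,l_0$ minus age where it crosses
$0.75\,l_0$); and the coefficient of variation of $e_0$ across areas,
using the population (divide-by-$n$) standard deviation.

## Lee–Carter forecasting adapted to small areas

Regional historical surfaces $\log m_{x,t}$ are decomposed as
$a_x + b_x k_t + \varepsilon_{x,t}$ by SVD of the column-centered surface,
with the conventional normalization $\sum_x b_x = 1$, $\sum_t k_t = 0$
(sign fixed so $\sum b_x > 0$; the recentering of $k$ folds into $a_x$;
residuals are kept for diagnostics and never forecast). A constant
surface leaves $b_x$ undefined; the fit then returns uniform $b_x$ with a
warning. The index follows a random walk with drift — the original
Lee–Carter time-series choice — estimated as
$\hat d = (k_T - k_1)/(T-1)$ with innovation sd from the first differences
about the drift (divisor $T-2$).

Municipalities have only one estimation year, so the municipal forecast
substitutes the municipality's adjusted jump-off schedule for $a_x$ and
borrows $b_x$ and the simulated $k$ paths from the enveloping region:

$$\log m_{x,T+h} = \log m^{\text{muni}}_{x,T} + b_x\,(k_{T+h} - k_T).$$

Subtracting $k_T$ anchors the forecast exactly at the municipal schedule
at $h = 0$. Two municipalities of one region keep a constant log-rate gap
along every path — the convergence-in-relative-risk assumption made
literal — and all municipalities of a region share the same simulated
index paths, so forecast uncertainty propagates from the regional level
rather than from municipal sample size. The classic second-stage
re-estimation of $k_t$ against observed death totals is deliberately
omitted, and forecast uncertainty includes the $k$-process only (the
jump-off schedule is treated as known).

## The synthetic world

`synthetic_world()` generates the study conditions with known ground
truth:

* **Standard schedules**: a three-component hazard — infant decline
  $0.015\,e^{-1.1x}$, a young-adult hump (Gaussian in age, centred at 22,
  sd 8, amplitude $9\times10^{-4}$ for males and $2.5\times10^{-4}$ for
  females), and Gompertz senescence ($5\times10^{-5} e^{0.095x}$ males,
  $3.2\times10^{-5}$ females). These levels give e0 in the low/mid 70s
  and a visible male excess at young adult ages.
* **True schedules**: standard + spline offsets, macroregion offsets
  $N(0, 0.3^2)$ and municipal offsets $N(0, 0.1^2)$ per component.
* **Exposures**: municipal totals log-normal (median `exposure_scale`,
  log-sd 1 — a heterogeneity of area sizes spanning roughly two orders of
  magnitude), spread over ages by a fixed pyramid $w_x \propto e^{-0.03x}$
  split evenly between sexes. The pyramid is fixed, not modelled:
  mortality, not population dynamics, is the target.
* **Counts**: complete deaths Poisson; registered deaths a binomial
  thinning with the microregion's completeness (child 0.75 / adult 0.85
  base, logit-normal microregion variation sd 0.3; optional
  municipal-level variation violates the homogeneity assumption on
  purpose). Coverage priors can be emitted centred on the truth
  (well-specified), logit-shifted (misspecified) or degenerate at 1.
* **Histories**: exact rank-one surfaces $a_x + b_x k_t$ over 61 years
  (1950–2010) with $b_x \propto e^{-x/40}$ normalized (decline fastest at
  young ages), $k_t$ a random walk with configurable drift — scalar, per
  region, or per region × sex — re-centred to $\sum k_t = 0$, and $a_x$
  anchored so the final-year surface equals the region's mean true
  schedule (which makes the degenerate zero-drift world internally
  consistent with the 2010 cross-section). The default drift of $-1.5$
  per year corresponds, under $\sum b_x = 1$, to an average log-rate
  decline of 1.5% per year — life-expectancy gains of a few years per
  decade. Optional Gaussian disturbances (`noise_sd`) break exact
  rank-one structure for recovery experiments.

What the synthetic world does **not** emulate: real age misreporting and
heaping, migration, cause-of-death structure, spatial correlation beyond
the hierarchy, or calibration to any particular country's numbers.
Passing tests therefore demonstrate internal statistical correctness of
the estimators under their own assumptions — recovery, calibration,
invariances — not field accuracy on real registries.

## Problem sizes and numerical tolerances

The test-suite and acceptance-script experiments use desk-scale worlds
chosen to keep the full run in minutes while leaving the statistical
checks well-powered: a 2×5×8 hierarchy (80 municipalities), median
municipal exposure 2–3×10⁴, sampler runs of 300–2500 kept draws per
microregion, 100–200 simulated index paths, and 20–200 replicate
recovery/calibration experiments. Machine-precision identities (life-table
columns, Lee–Carter reconstruction, Marshall moment formulas) are asserted
at $10^{-10}$–$10^{-12}$; Monte-Carlo comparisons use standard errors
estimated from integrated autocorrelation times. The TOPALS recovery
experiments run on a deliberately high-mortality standard (infant rate
0.05, floor 0.01): the recovery tolerance tracks observed-information
standard errors, which are dominated by the sparse-death child knots
otherwise.

## Known limitations

* The within-microregion homogeneity assumption for completeness is
  exactly true in the default synthetic world; the generator can violate
  it (`by_municipality = TRUE`), and in that regime municipal adjustment
  inherits the microregion average bias.
* Coverage is piecewise-constant in two age blocks; finer age patterns of
  under-registration are absorbed partly into the schedule offsets.
* $b_x$ fixed in time (inherent to Lee–Carter) makes long horizons
  optimistic at young ages where decline rates saturate.
* Forecast intervals condition on the jump-off schedule and on $b_x$;
  they quantify index uncertainty only.
* Reported municipal point estimates after smoothing and substitution no
  longer carry coherent posterior intervals — the pipeline reports the
  Bayesian spread at the microregion stage and index-driven spread at the
  forecast stage, but not a joint municipal posterior.
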