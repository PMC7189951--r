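---
title: "Birth spacing and parity progression: models, estimators, and design choices"
author: "birthgap"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birthgap)
```

## The problem

Fertility surveys often record, for each ever-married woman, the timing of
all her births relative to marriage, the date of the interview, and a set of
socio-demographic covariates. Two questions drive the analysis this package
supports:

1. **What accelerates or delays successive births?** Childbirth is a
   recurrent event: the clock restarts at marriage and again at every birth,
   and a woman is only at risk of a third birth after her second. The
   natural model is the Prentice–Williams–Peterson *gap-time* (PWP-GT)
   conditional model.
2. **What fraction of women at parity $i$ ever go on to an $(i+1)$-th
   birth?** These parity progression ratios (PPRs) summarise family-size
   dynamics and can be estimated from the *open* and *closed* birth
   intervals observed at a single cross-sectional interview, without
   follow-up.

All analysis times are months since marriage internally; years appear only
in the reporting layer (conversion by 12).

## The PWP gap-time model

For stratum $s$ (the birth order being waited for) the hazard of woman $i$
at gap time $u = t - t_{s-1}$ is

$$h_s(u \mid x_i) = h_{0s}(u)\, \exp(b_s' x_i),$$

with a separate, unspecified baseline hazard $h_{0s}$ per stratum. The
coefficients maximise the stratified Cox partial likelihood

$$L(b) = \prod_{s}\prod_{j=1}^{d_s}
  \frac{\exp(b_s' x_{(j)})}{\sum_{l \in R(u_{(j)},\, s)} \exp(b_s' x_l)},$$

where $R(u, s)$ contains every record of stratum $s$ with gap time at least
$u$ — the *conditional* risk-set structure: a woman contributes to stratum
$s$ only after an event in every stratum below $s$. `expand_gaps()` builds
exactly this long format; `pwp_gt()` maximises the likelihood.

Design choices a user should know:

* **Per-stratum coefficients by default.** Reports in this literature show
  one column of hazard ratios per delivery, which corresponds to a separate
  maximisation per stratum. A shared-coefficient variant
  (`per_stratum = FALSE`) is available and cross-checked against a
  stratified Cox fit.
* **Ties.** Gap times recorded in whole months tie frequently. Breslow is
  the default (it is also what the literal enumeration of the likelihood
  above gives); Efron is available and tested against an independent
  implementation of its formula.
* **Optimisation.** Newton–Raphson with analytic gradient and observed
  information, step-halving when a step would decrease the likelihood,
  convergence when the score max-norm falls below `tol` (default `1e-8`),
  at most 50 iterations. Constant or collinear design columns are dropped
  with a warning rather than producing a singular information matrix.
* **Separation.** With few events per stratum a binary covariate can
  perfectly order events, sending its coefficient to infinity while the
  score decays to zero. The fit is flagged (`monotone`) whenever the
  coefficient magnitude exceeds 10 — hazard ratios beyond $e^{10}$ have no
  demographic interpretation — and `converged` is set to `FALSE`.
* **Inference.** Standard errors come from the inverse observed
  information; p-values are two-sided Wald tests on the normal
  approximation, with no multiplicity correction (matching standard
  reporting practice in this literature). Reference levels appear in
  `wald_table()` with hazard ratio 1.00 and blank SE/p.

## The parity progression ratio estimator

Let $p_i(0, C_1)$ be the proportion of women at parity $i$ whose open
interval (time since the $i$-th birth, or since marriage for $i = 0$) is at
most $C_1$ months, and let

$$E_C(T^*) = \int_0^C [1 - F_i(t)]\, dt$$

be the mean closed interval truncated at $C$, computed from the empirical
distribution of observed closed intervals — equivalently
`mean(pmin(closed, C))`. The package estimates the progression ratio as

$$\hat a_i = \frac{C_1 - p\, C}{p\,(E_C - C)},
  \qquad p = p_i(0, C_1),$$

with $C_1 = 12$ months and $C$ on a grid from 60 to 120 months; the
per-transition median over the grid is the reported summary.

**Why this form.** A woman entering parity $i$ occupies it, within a window
of $C$ months, for $E_C(T^*)$ months if she will progress (probability
$a_i$) and for all $C$ months otherwise; expected window occupancy is
therefore $a_i E_C + (1 - a_i) C$. Essentially no birth interval is shorter
than $C_1 = 12$ months, so every woman occupies the first $C_1$ months of
the window, and under a stationary flow of entries the cross-sectional
proportion with open interval below $C_1$ is
$p \approx C_1 / \{a_i E_C + (1 - a_i) C\}$. Solving for $a_i$ gives the
estimator. It returns exactly 0 when $p = C_1/C$ (nobody leaves the window
early) and exactly 1 when $p = C_1/E_C$; both limits are verified exactly in
the tests, with a relative snapping tolerance of $10^{-9}$ absorbing
floating-point rounding of the inputs.

**The denominator of $p$.** The occupancy argument concerns women *inside
the window*, i.e. at parity $i$ with an open interval of at most $C$
months. That is the package default (`open_denominator = "within_C"`).
Counting instead *all* women currently at parity $i$ makes the estimator
degenerate whenever the survey includes long-married women: their open
intervals all exceed $C$, $p$ collapses towards zero and the ratio
diverges. We verified this numerically — under the post-reproductive
interview law the all-women variant returns values such as $-3.8$ where the
generating probability is $0.55$ — and therefore ship `"all"` only as a
comparison option.

**What the estimator needs from the survey design.** The stationary-flow
argument requires women to enter parity $i$ at an approximately constant
rate right up to the interview — a cross-section of women at *all* marriage
durations, including the recently married. A survey restricted to
post-reproductive women (every marriage decades old) is the estimator's
degenerate regime: no woman is inside any window. Recovery simulations
therefore use an interview law spanning essentially all durations
(`interview_window = c(0.01, 420)`), while the generator's default window
(260–420 months) mimics the post-reproductive cohorts on which the
descriptive statistics and the gap-time model are computed.

**Censoring.** $F_i$ is estimated from fully observed closed intervals
only, with no correction for right truncation by the interview; this is the
convention of the original method, and in a mostly post-reproductive sample
the truncation is mild. Closed intervals observed near the interview are
selectively short, so $E_C$ — and with it $\hat a_i$ — carries a small
downward bias that shrinks as the interview window lengthens.

**Sampling behaviour, honestly stated.** The estimator divides by $p$ and
by $E_C - C$, both estimated; a delta-method calculation gives
$\mathrm{SE}(\hat a) \approx (C_1/p^2)\,\mathrm{SE}(\hat p)/(C - E_C)$,
which at survey scale ($n$ in the low thousands, a few hundred women per
window) is of the same order as 0.1 — comparable to the 0.05 recovery
tolerance the test suite imposes on the across-replicate median of 20
replicates of $n = 2000$. The nonlinearity in $1/p$ adds a further small
negative (Jensen) bias. That recovery test is therefore expected to fail
its strict tolerance on the noisier transitions for most seeds; it is kept
at the strict tolerance, reporting the true shortfall at run time, rather
than having its band widened to fit. Recovery to within 0.05 requires
roughly an order of magnitude more data. The formula itself is exact: fed
the theoretical $p$ and $E_C$ of the generating cure model, it returns the
generating probabilities to three decimals at every transition and
truncation (this is a unit test).

**Out-of-range cells.** Sampling noise can push the raw ratio outside
$[0, 1]$. Reported estimates are clamped and flagged; raw values are kept
alongside, and nothing is silently dropped. Cells with no women at the
parity, or with $p = 0$, are missing — never zero.

## The synthetic cohort generator

No individual-level data ship with the package; `simulate_cohort()`
generates cohorts with the statistical structure the estimators assume:

* **Cure-fraction progression.** At parity $i-1$ a woman is a progressor
  with probability $a_i$, independently of covariates; defaults
  $(0.95, 0.84, 0.56, 0.35)$ for the first four transitions, extended by
  $(0.28, 0.18, 0.10)$ to the parity cap of 7 as a plausible continued
  decline. Keeping the cure mechanism independent of covariates makes the
  PPR recovery targets analytically clean; an effect of covariates on
  *timing* is separate (below).
* **Gap times.** Log-normal closed intervals with stratum medians
  $(54, 54, 56, 63)$ months (about 4.5–5.3 years, repeated beyond stratum
  4) and `sdlog = 0.5`, a coefficient of variation of about 0.53, in line
  with the dispersion of observed birth-interval distributions.
* **Covariate effects as proportional hazards.** A progressor's gap is
  drawn by the inverse-survival transform
  $T = S_0^{-1}(U^{\exp(-b_s'x)})$, so the generating coefficients live on
  the same log-hazard scale the PWP-GT model estimates — parameter-recovery
  tests compare like with like.
* **Interview law.** Uniform on a configurable window of months since
  marriage; default (260, 420), a post-reproductive cohort.
* **Covariates.** Drawn independently from the first-delivery marginal
  frequencies of the emulated survey (the survey's husband-education column
  sums to more than its printed denominator — an inconsistency of the
  source table — and is normalised). Income shares are not published and
  are fixed once at (0.35, 0.45, 0.20). Ages: marriage age normal
  (mean 17.5, sd 4, floor 13), consistent with a reported mean age at first
  delivery of about 22.4 years once the first gap is added; husband older
  by normal (5.3, 3.5) years. Sexes are independent Bernoulli with male
  probability 104/204 (sex ratio 104).
* **Determinism.** All randomness flows from the single `seed` through one
  restored-on-exit RNG scope; the same configuration always yields the
  identical cohort, and the caller's RNG stream is untouched.

What the generator does **not** emulate: mortality, marriage dissolution,
twins, calendar-period effects, contraceptive dynamics, correlation between
covariates, and covariate-dependent progression probabilities (available as
an explicit option through `covariate_effects` acting on timing only).
Passing recovery tests on these cohorts therefore demonstrates correctness
of the estimators under their own assumptions, not robustness to every
feature of real survey data.

## Descriptive conventions

* "Had at least $k$ children" counts are nested; the percentage base is all
  women, and the primary infertility rate is the parity-0 share.
* Median birth intervals use observed (closed) gaps only, reported in
  years; an even count averages the central pair.
* Percentages are rounded half-up to 2 decimals, the sex ratio to an
  integer, progression ratios to 3 decimals — only in the reporting layer;
  computations keep full precision. (Half-up rounding, not banker's
  rounding: $100 \times 671/812$ must print 82.64.)
* The source survey's printed tables contain small internal
  inconsistencies (a stillbirth column summing past its denominator, one
  implausible husband-education cell, one percentage printed truncated
  rather than rounded, and grid medians that do not all equal the medians
  of their printed rows). The implementation reproduces correct arithmetic
  and does not force agreement with those cells; of the printed per-parity
  median progression ratios, only the internally consistent third-to-fourth
  value (0.349) is used as a check.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* partial likelihood, score and information against literal enumeration
  oracles and finite differences (200 random tiny cohorts; agreement to
  $10^{-10}$);
* full fits against `survival::coxph()` per stratum and stratified, both
  tie methods, to $10^{-6}$;
* the truncated mean against exact step-function integration; the PPR
  formula against its analytic limits and the theoretical renewal inputs;
* parameter recovery at the scale the estimators are meant for: 20
  replicates of $n = 2000$ (progression ratios) and $n = 1000$ plus 200
  null replicates of $n = 400$ (gap-time model; the type-I error of the
  5% Wald test must sit inside a 3-sigma binomial band). The PWP recovery
  cohort sets the first-stratum progression probability to 1: with a cure
  fraction the population hazard is a mixture of susceptible and immune
  women, proportionality fails and the fitted Cox coefficient is
  attenuated towards zero, so simulating from the fitted model itself is
  the only design in which "the generating log hazard ratio" is the
  estimand.

These sizes keep the whole suite within a couple of minutes on one core
while leaving Monte-Carlo error well below the tolerances tested.

## Known limitations

* The PPR estimator is a method-of-moments device with heavy noise
  amplification at survey-scale $n$; treat single-cell values with caution
  and prefer the grid medians.
* Covariates are treated as fixed at their interview values; the hazard
  model notation allows time-varying covariates, but reproductive histories
  recorded retrospectively rarely support them.
* Censoring is at the interview only: no mortality or loss to follow-up.
* No frailty or within-woman dependence beyond the conditional risk-set
  structure; no robust (sandwich) variance; no baseline-hazard estimation.
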