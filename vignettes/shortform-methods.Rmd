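---
title: "Deriving ordinal short forms by ant-colony optimization: models and methods"
author: "acoshort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving ordinal short forms by ant-colony optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`acoshort` implements a complete workflow for deriving and validating a
fixed-length short form of an ordinal (Likert-type) questionnaire: simulate
realistic item responses from a threshold factor model, fit ordinal
confirmatory factor models, select items by ant-colony optimization (ACO)
against several psychometric criteria at once, test measurement invariance
across groups, and summarize construct validity with regularized
partial-correlation networks.  This vignette documents the models, the
estimation choices, and the places where the design was genuinely open.

## The data-generating model

Item $j$ has a standard-normal latent response
$$y^*_j = g_j G + \lambda_j' f + e_j, \qquad \operatorname{Var}(y^*_j) = 1,$$
with correlated common factors $f$ (unit variances, correlation matrix
$\Phi$), an optional orthogonal general factor $G$ (bifactor mode), and
unique noise $e_j$.  The observed code $X_j \in \{0, \dots, K\}$ counts the
thresholds $\tau_{j1} < \dots < \tau_{jK}$ that $y^*_j$ exceeds.  Two items
therefore have latent correlation $\lambda_i \lambda_j \operatorname{corr}(p, q)$
when they load on factors $p$ and $q$ — the quantity a polychoric
correlation estimates.

The default instrument emulated throughout is a 14-item two-factor
perceived-stress scale: seven helplessness and seven self-efficacy items on
a 5-point scale, inter-factor correlation $-0.37$, and published
standardized loadings (`pss14_population()`).  Choices a user can override,
with their defaults and rationale:

* **Thresholds** default to the symmetric cut-points $(-1.2, -0.4, 0.4, 1.2)$.
  These produce mildly peaked, near-symmetric category distributions with
  item skewness well inside $\pm 1.5$, matching the mild non-normality such
  scales show in practice; per-item shifts can be supplied to plant skew.
* **Retest model**: wave-2 factors follow a latent first-order
  autoregression, $f^{(2)} = s f^{(1)} + \eta$ with fresh unique noise at
  wave 2 and stationary variance; the default stability $s = 0.85$ yields
  sum-score retest ICCs around $0.70$–$0.75$ for well-measured 2-item
  parcels, the range reported for short stress scales over about four weeks.
* **Covariates** are generated as $c = \beta d'f + \sigma \epsilon$ with
  unit variance.  Because the ordinal sum-score moments have closed forms in
  $\Phi$ and $\Phi_2$ (univariate and bivariate normal probabilities),
  $\beta$ is solved exactly so that the model-implied Pearson correlation
  between $c$ and a named sum score equals its target — by default $0.59$
  (mental-health problems) and $-0.53$ (stressor recovery ability) with the
  helplessness sum, and $0.44$ (self-efficacy beliefs) with the
  self-efficacy sum.  `verify_targets()` checks the realized correlations.
* **Missingness** is completely at random at rate $0.001$, mirroring the
  near-complete data such online panels deliver.
* **Groups**: proportions default to $0.528/0.472$ (female/male); planted
  non-invariance enters through per-group additive offsets on chosen
  loadings or thresholds (`group_deltas`).
* **Seeding**: one master seed; every stochastic component draws from a
  deterministically derived child stream, so any stage can be reproduced in
  isolation.

The marker/distractor population used by the selection studies
(`shortform_population()`) plants two marker items per factor at loading
$0.90$ among distractors at $0.40$–$0.60$.  The generator emulates the
factorial and correlational structure of real panel data but deliberately
not panel attrition, response styles, careless responding, or
item-wording effects; passing tests therefore certify the statistical
machinery under a known truth, not robustness to those artifacts.

## Polychoric correlations

Estimation is two-step: thresholds from inverse-normal cumulative category
proportions, then each pairwise $\rho$ maximizes the bivariate-normal
two-way-table likelihood over $[-0.999, 0.999]$ (bounded golden-section /
parabolic refinement, tolerance $10^{-6}$; perfect association lands on the
clip).  Bivariate rectangle probabilities come from a 48-node
Gauss–Legendre evaluation of the Drezner–Wesolowsky identity, accurate to
about $10^{-7}$ and vectorized so a full 14-item matrix at $n = 50{,}000$
takes well under a second.  Each estimate carries an asymptotic variance
from the observed information of its pairwise likelihood; these become the
DWLS weights.

## Ordinal confirmatory factor analysis

`cfa()` fits by diagonally weighted least squares on the polychoric
correlations: minimize $\sum_m (r_m - \sigma_m(\theta))^2 / \widehat{avar}_m$
over the unique correlations, with standardized loadings, unit factor
variances (the identification rule everywhere, including two-indicator
factors), and unique variances implied as $1 - $ communality.  Bifactor
models add a general loading per item with specifics orthogonal to it and
to each other.  A normal-theory ML path on the Pearson covariance matrix is
available for sensitivity analyses.  The optimizer is BFGS on an
unconstrained reparameterization (factor correlations through $\tanh$, ML
unique variances through $\log$), relative tolerance $10^{-10}$, at most
500 iterations; non-convergence is returned as a flagged fit and Heywood
cases are flagged, never clipped.

The reported statistic is the *unadjusted* weighted discrepancy with
$df = p(p-1)/2 - (\text{free parameters})$; the baseline for CFI is the
independence model.  With diagonal weights this statistic is not
chi-square calibrated (it runs conservative), which is why incremental fit
indices — CFI $= 1 - \max(\chi^2_M - df_M, 0) / \max(\chi^2_B - df_B,
\chi^2_M - df_M, 0)$ and RMSEA $= \sqrt{\max(\chi^2_M - df_M, 0) /
(df_M (n-1))}$ — and *scaled* difference tests carry the inferential load.
`chi2_diff()` provides the plain difference against the central chi-square,
which is also how published difference tests are reproduced from printed
statistics.

## Measurement invariance

`mg_cfa()` fits multigroup ordinal models in a delta-parameterization:
group-1 latent responses have unit variance; standardized thresholds are
saturated (and drop out of the discrepancy) as long as they are free per
group.  The ladder is configural (same structure), metric (equal loadings),
scalar (equal thresholds, with group-2 latent means and item scales freed),
and strict (equal unique variances, which determines the scales).  Factor
correlations stay free per group at every level.

Decisions use a mean-scaled chi-square difference.  The naive DWLS
difference runs conservative under the null, so the difference is rescaled
by $c = \operatorname{tr}\{(V_r - V_f)\Gamma\} / \Delta df$, where $V$ is
each fit's residual weight operator and $\Gamma$ is the influence-function
covariance of the threshold and polychoric estimates (including the
two-step threshold plug-in correction).  The test suite verifies the
resulting metric-step type-I error against its nominal 5% level over 200
null replicates.  A Satterthwaite-style mean-and-variance version was
evaluated and ran over-conservative at this sample size (the second trace
is noisy under estimation error), so mean scaling is the default; the
scalar step can retain mild residual miscalibration, a documented
approximation.  Partial invariance is searched
greedily: the constrained parameter whose release drops the discrepancy
most is freed, the level is refit and re-tested, stopping at
non-significance or after `max_freed` (default 4) releases.

## Ant-colony item selection

Candidates are fixed-length item sets, $k$ per factor.  Each candidate is
scored on five criteria: CFI $\ge 0.96$ and RMSEA $\le 0.05$ from its
two-factor DWLS fit, McDonald's $\omega \ge 0.85$ (worse factor),
retest ICC $\ge 0.70$ of the factor sum scores (worse factor), and mean
absolute deviation $\le 0.15$ of the covariate correlations from their
targets.  Raw values map to pheromones through a logistic
$\varphi_c = 1/(1 + e^{-(x_c - t_c)/s_c})$ centred at the published cut-off
$t_c$ (sign flipped for lower-is-better), so $\varphi_c = 0.5$ exactly at
the cut-off; the scale $s_c$ defaults to one half of ten percent of the
threshold (for the covariate criterion, half its $\pm 0.15$ tolerance),
keeping all criteria commensurate before their unit-weighted sum $\Phi$.

The colony runs 40 ants for 30 iterations with evaporation $0.70$ read as
a retention multiplier ($\tau \leftarrow 0.70\,\tau +$ deposit) and an
elitist deposit (the global best adds its $\Phi$ to its items' pheromone
each iteration; iteration-best deposits are a config option).  Because the
elitist deposit concentrates pheromone within a few iterations while the
minimum-over-factors criteria make the landscape flat away from the
optimum, the floor is max–min style: pheromone never falls below 10% of
the current maximum (plus an absolute floor of $0.01$), which keeps
exploration alive for the whole run; early stopping is available but off
by default at this iteration budget.  Five
independently seeded runs form a consensus; the modal best item set is
reported with its reproduction count.  Because the candidate space at
$k = 2$ from 7-item pools is only $\binom{7}{2}^2 = 441$,
`brute_force_optimum()` enumerates it exactly and serves as the oracle the
stochastic search is validated against.  All candidate evaluations share
one precomputed polychoric matrix and an item-set cache, which keeps a full
five-run consensus under a second after the bundle is built.

Two-item factors need a convention for $\omega$: the one-factor model is
identified by equal loadings, $\hat\lambda = \sqrt{r_{12}}$ from the
polychoric correlation.  The retest ICC defaults to ICC(2,1) — two-way
random effects, absolute agreement, single measurement — the stricter
test-retest choice; a consistency variant ICC(3,1) is available.

## Partial-correlation networks

Node scores (short-form factor sums and covariates) pass through a
nonparanormal transform (ranks, Winsorized empirical CDF, normal
quantiles).  `ebic_glasso()` solves the $\ell_1$-penalized Gaussian
precision problem by block coordinate descent with warm starts along a
100-point log-spaced path from $\lambda_{max}$ (the smallest penalty giving
an empty graph) to $0.01\,\lambda_{max}$, leaving the diagonal unpenalized.
Model selection minimizes
$\mathrm{EBIC} = -2\,\ell + E \log n + 4 \gamma E \log p$ with
$\gamma = 0.25$.  By default the likelihood entering the EBIC (and the
reported precision matrix) is the unpenalized MLE restricted to each
penalty's support: comparing penalized likelihoods lets shrinkage bias,
not fit, drive the selection toward the bottom of the path, and the
refit variant recovers planted sparse structures exactly in our checks
(`refit = FALSE` reproduces the penalized-likelihood convention).  Edge
weights are $-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$.

Centralities: strength $\sum_j |w_{ij}|$; closeness as the reciprocal of
summed shortest-path distances with edge lengths $1/|w|$, where
unreachable nodes contribute nothing and an isolated node scores 0; and
weighted betweenness.  Edge stability uses nonparametric case resampling
with full re-estimation (including penalty re-selection) per draw and
percentile 95% intervals; centrality stability is the correlation-stability
coefficient — the largest case-drop proportion at which subsampled
centralities correlate at least $0.7$ with the full-sample centralities in
at least 95% of subsamples.

## Numerical conventions and degenerate inputs

Item codes are $0\dots K$ (sums, reversals `max_code - value`, and targets
all follow this convention; nothing downstream depends on a $1\dots K{+}1$
recoding).  Person-mean imputation replaces exactly one missing item per
scale by that person's mean of the remaining items (a sample-item-mean
variant is available); two or more missing items flag the person's scale
score unusable.  Because imputation creates fractional codes, all
polychoric-based stages consume the raw codes with pairwise-complete
deletion, and the pipeline computes descriptives on the raw codes as well.
Constant items, single-category items, non-monotone thresholds,
non-positive-definite inputs and undersized groups raise immediate errors
with the offending name; near-singular correlation inputs to the network
stage receive a logged ridge fix-up.  Shapiro–Wilk is delegated to the
standard routine on a fixed-seed subsample of at most 5000 values, and the
non-normality flag follows the joint rule (significant test *and* skewness
or excess kurtosis outside $[-1.5, 1.5]$, both SPSS-style type-2
estimates).

## Problem sizes in the test suite

The suite validates the generator's moments at $n$ up to $10^5$, estimator
recovery on exact model-implied matrices, ACO-versus-enumeration agreement
on twenty independent bundles at $n = 1437$, null calibration of the
invariance difference test over 200 replicates at $n = 1437$, and the
network identities on a five-node chain at $n = 10^4$ — sizes chosen so
each check has the power it needs while the whole suite stays comfortably
interactive.

## Known limitations

* The DWLS model statistic is unadjusted; its absolute value is not
  chi-square distributed and should be read through fit indices and scaled
  differences.  Exact parity with mean-and-variance-adjusted statistics of
  dedicated SEM software is not attempted.
* The scalar-step difference test retains mild type-I inflation.
* Second-order factor models and exploratory factor analysis are out of
  scope, as are longitudinal invariance and alignment methods.
* Bootstrap intervals re-select the penalty per draw; they quantify
  sampling variability of the whole procedure, not of a fixed graph.
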