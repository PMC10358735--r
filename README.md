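# acoshort

Ant-colony-optimization (ACO) short-form selection for ordinal
psychometric scales, with the full validation workflow around it: ordinal
confirmatory factor analysis on polychoric correlations, reliability
(Cronbach's α, McDonald's ω, test–retest ICC), measurement invariance
across groups, and regularized partial-correlation networks.

## The problem

Short forms of questionnaires are usually built by optimizing one
criterion at a time (drop the item with the lowest loading, then check
reliability, then validity), which easily trades away properties that were
not on the table at that step.  `acoshort` treats item selection as a
combinatorial search over fixed-length item sets — for a two-factor
perceived-stress instrument, two items per factor out of 7+7 — scored on
several psychometric criteria *simultaneously*.  Each candidate set is
evaluated by:

* model fit of its two-factor ordinal CFA (CFI ≥ 0.96, RMSEA ≤ 0.05),
* McDonald's ω of each factor (≥ 0.85, worse factor counts),
* test–retest ICC(2,1) of each factor sum across two waves (≥ 0.70),
* mean absolute deviation of covariate correlations from target values
  (≤ 0.15).

Each raw value is mapped through a logistic pheromone function
φ_c = 1 / (1 + exp(−(x_c − t_c)/s_c)) centred at its cut-off t_c, and the
candidate's total pheromone Φ = Σ_c φ_c drives a colony of 40 ants over 30
iterations (evaporation 0.70, elitist deposit): items belonging to the
best solutions accumulate pheromone and become more likely to be sampled.
Five independently seeded runs form a consensus, and an exhaustive oracle
(`brute_force_optimum()`, 441 candidates at k = 2) verifies the
metaheuristic exactly.

Because real response-level data of this kind are typically not publicly
deposited, the package ships a calibrated generator
(`population_model()`, `simulate_responses()`): a threshold factor model
with published loadings, inter-factor correlation −0.37, a latent
autoregression linking two assessment waves, group offsets for planting
measurement non-invariance, and covariates solved in closed form to hit
target correlations (0.59, −0.53, 0.44) with named sum scores.

## Worked example

```r
library(acoshort)
report <- run_study(default_study_config(seed = 42, n_boot = NULL))
print(report)
```

```
Short-form derivation report (seed 42, n = 1437)

-- Long-form model comparison --
      model   chisq df   cfi rmsea converged
 one_factor 13500.0 77 0.491 0.351      TRUE
 two_factor    54.8 76 1.000 0.000      TRUE
   bifactor    30.6 63 1.000 0.000      TRUE
      comparison  dchisq ddf      p
      one vs two 13445.2   1 0.0000
 two vs bifactor    24.1  13 0.0298

-- Short-form selection --
ACO consensus over 5 runs: modal solution in 5 run(s)
Item solution: helplessness={item02,item14}  selfefficacy={item06,item10}
Raw: cfi=1.000, rmsea=0.000, omega_min=0.896, icc_min=0.703, covariate_dev=0.027

-- Reliability of selected factors --
  helplessness: alpha = 0.866, omega = 0.900, ICC = 0.703
  selfefficacy: alpha = 0.863, omega = 0.896, ICC = 0.737

-- Partial-correlation network --
Partial-correlation network: 5 nodes, 5 edges (lambda = 0.2995, gamma = 0.25, n = 1434)
             helplessness selfefficacy   mhp recovery  ase
helplessness         0.00        -0.20  0.49    -0.40 0.00
selfefficacy        -0.20         0.00  0.00     0.00 0.48
mhp                  0.49         0.00  0.00    -0.09 0.00
recovery            -0.40         0.00 -0.09     0.00 0.00
ase                  0.00         0.48  0.00     0.00 0.00
```

Reading this: the one-factor model of the 14 items is untenable (CFI
0.49), the two-factor structure fits, and the colony picked exactly the
four marker items planted by the generator — in all five runs.  The
selected 2+2 form meets every optimization criterion: CFI 1.0 ≥ 0.96,
RMSEA 0 ≤ 0.05, both ω ≥ 0.85, both ICC ≥ 0.70, and covariate
correlations within 0.03 of their targets.  The EBIC-selected
partial-correlation network shows helplessness carrying the links to
mental-health problems (0.49) and stressor recovery (−0.40) while
self-efficacy links to self-efficacy beliefs (0.48), the two factors
partially correlating at −0.20; `centrality_indices()`,
`bootstrap_edges()` and `casedrop_stability()` quantify its robustness.

Lower-level entry points mirror the workflow: `polychoric_matrix()`,
`cfa()` / `anova()`, `mg_cfa()` / `invariance_ladder()` /
`partial_release()`, `cronbach_alpha()` / `omega_from_items()` /
`icc_retest()`, `aco_bundle()` / `run_aco()` / `repeat_runs()`,
`ebic_glasso()` / `pcor_network()`.  The methods vignette
(`vignettes/shortform-methods.Rmd`) documents the models and every
numerical convention.

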