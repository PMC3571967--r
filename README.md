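# stressmix

Analysis of gene expression under **combined nitrogen and water stress**
in a factorial design, built around model-based clustering of short
longitudinal expression trajectories.

The package targets the classic crossed-stress maize setup: three organs
(leaf, root, stem) x two nitrogen regimes (optimal, limiting) x five
ordered water conditions (optimal supply, mild stress, severe stress,
re-watered 2 h, re-watered 5 h), a few biological replicates each — 30
conditions, ~90 arrays. It answers, per organ:

* which entities respond to nitrogen limitation or to mild/severe water
  stress (fold-change filter, pooled t-test, Benjamini–Hochberg FDR);
* which respond to the *interaction* of nitrogen and water status
  (two-way type-III ANOVA on the 2x2 subdesign), and which respond
  **exclusively** through the interaction;
* what the principal water-response trajectory shapes are, under each
  nitrogen regime (Gaussian-mixture clustering); and
* which genes **change trajectory shape** between nitrogen regimes
  (a two-component mixture comparison of paired profiles).

## The model at the core

Each entity's water response is a 5-point profile $x \in \mathbb{R}^5$
(replicate-median log2 expression over the ordered water conditions),
modelled by a finite Gaussian mixture

$$f(x) = \sum_{g=1}^{G} \pi_g\, \mathcal{N}(x;\ \mu_g, \Sigma_g),
\qquad \Sigma_g^{-1} = T_g^\top D_g^{-1} T_g,$$

where $T_g$ is unit lower-triangular and $D_g$ positive diagonal — the
**modified Cholesky decomposition**, the natural covariance
parameterization for ordered (longitudinal) measurements: $T_g$ holds
generalized autoregressive coefficients, $D_g$ innovation variances.
The model is fitted by EM with restarts (`longmix()`), the number of
groups is chosen by BIC, $2\ell - k\log n$, over $G = 1..8$
(`longmix_select()`), and clusters are split a posteriori into up/down
subgroups (`split_up_down()`). Genes measured under both nitrogen
regimes are paired and a $G = 2$ fit flags those whose two profiles land
in different components (`detect_trend_change()`).

Because studies of this design rarely deposit raw data, the package
includes a first-class synthetic-data generator
(`simulate_stress_experiment()`) that emulates the full factorial layout
with planted trajectory clusters, interaction effects and trend changes,
so every stage is testable end to end.

## Worked example

```r
library(stressmix)

cfg <- sim_config(n_entities = 600, organs = "leaf", seed = 11)
sim <- simulate_stress_experiment(cfg)

detected <- detection_filter(sim$raw, sim$metadata, threshold = 20)
expr     <- log_and_baseline(sim$raw[detected, ])

## single-factor differential expression: severe water stress vs optimal
de <- de_call(expr, sim$metadata, organ = "leaf",
              comparison = "severe_water")
sum(de$significant)
#> [1] 427

## cluster the water-response trajectories under optimal nitrogen
profiles <- condition_profiles(expr, sim$metadata, "leaf", "optimal")
keep     <- prescreen_profiles(profiles, fc_threshold = 3)
fit      <- longmix_select(profiles[keep, ], G = 1:6, seed = 11)
fit
#> Longitudinal Gaussian mixture (modified-Cholesky covariance)
#>   G = 5 components, model = unconstrained, n = 241 profiles of length 5
#>   log-likelihood = 62.591, params = 104, BIC = -445.237
#>   converged: yes after 8 EM iteration(s)
```

427 of the 600 simulated entities are called for severe water stress
(the generator plants strong trajectory responses in most entities, so a
large fraction clears the 2-fold/FDR-0.05 screen). The mixture selects
5 components for the 241 prescreened profiles — 4 planted shapes plus
one extra arising from the fold-change truncation of the profile
distribution, a known property of prescreen-then-cluster discussed in
the methods vignette; the adjusted Rand index against the planted labels
is 0.87. `plot(fit)` draws the per-cluster trajectory panels;
`summary(fit)`, `coef(fit)`, `predict(fit)`, `simulate(fit)` behave as
for any fitted-model object.

The whole chain — simulation, preprocessing, DE, interaction screen,
clustering under both nitrogen regimes, trend comparison, summary
tables — runs from one configuration via `run_pipeline(cfg)`.

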