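---
title: "Methods: factorial stress analysis and longitudinal mixture clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial stress analysis and longitudinal mixture clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`stressmix` analyses bulk expression data from a crossed abiotic-stress
design in maize: three organs (leaf, root, stem), two nitrogen regimes
(optimal, limiting) and five ordered water conditions (optimal supply,
mild stress, severe stress, and 2 h / 5 h after re-watering), each
combination measured in a few biological replicates — 30 conditions and
around 90 arrays in the full design. The questions the pipeline answers,
per organ:

1. Which entities (probe sets) respond to nitrogen limitation alone, or to
   mild/severe water stress alone?
2. Which entities respond to the *interaction* of nitrogen and water
   status, beyond additive main effects — and which respond exclusively
   through that interaction?
3. What are the principal water-response *trajectory shapes* over the
   five ordered water conditions, under each nitrogen regime?
4. Which genes change their trajectory shape between nitrogen regimes?

Stages 1–2 are classical filtered testing; stages 3–4 are the methodological
core: model-based clustering of 5-point longitudinal profiles with a
Gaussian mixture whose covariance is parameterized by the modified Cholesky
decomposition.

# Preprocessing

The pipeline accepts a summarized entities-by-samples intensity matrix
(probe-level summarization such as RMA is upstream of this package and out
of scope). Stages:

* **Detection filter** (`detection_filter()`): an entity is kept when there
  is at least one condition in which *every* replicate's raw signal exceeds
  the detection threshold (default 20 intensity units). "Above" is strict
  (`>`); a `strict = FALSE` switch gives `>=`, since tie behaviour at the
  threshold is a dialect choice.
* **Log + baseline** (`log_and_baseline()`): raw values are floored at 1.0,
  log2-transformed, and each entity is centered to its median across all
  samples ("baseline transformation to the median"), so every row has
  median 0. A scale flag travels with the matrix so the transform cannot be
  applied twice. Within-entity contrasts (fold changes, ANOVA terms) are
  invariant to this centering; only absolute levels change.
* **Condition profiles** (`condition_profiles()`): replicates are collapsed
  by the *median* (less outlier-sensitive than the mean; even counts use
  the midpoint of the central pair), giving each entity one 5-vector per
  organ-by-nitrogen stratum, ordered along the water series. We center
  first and take medians second; the reverse order would give the same
  within-profile contrasts but different absolute levels, and
  baseline-then-median keeps the profile on the same scale as the
  baselined matrix.

# Single-factor differential expression

For each organ, comparisons are limiting vs optimal nitrogen (at optimal
water) and mild/severe water stress vs optimal water (at optimal
nitrogen). Calls follow the *filter-then-test* order: entities with a
linear fold change of at least 2 (computed as the difference of mean log2
signals — the mean-of-logs convention) form the family, which is then
tested with the unpaired equal-variance (pooled) t-test and corrected with
Benjamini–Hochberg at FDR 0.05. The BH family is therefore the set of
fold-change survivors, and correction is applied per organ and comparison,
matching the per-organ analysis design. A `test-then-filter` switch exists
for sensitivity analysis. When the pooled variance is exactly zero and the
means are equal, p is defined as 1; zero variance with unequal means is
rejected as degenerate input. Whether the fold-change screen uses replicate
means or medians is a genuine ambiguity; we use means (the usual convention of commercial microarray suites)
and document it.

# Interaction screen

Only the 2x2 subdesign (optimal/limiting nitrogen x optimal water/severe
drought) enters this stage. Entities are prescreened on the maximum of the
four pairwise cell fold changes (water response under each nitrogen
regime; nitrogen response under each water level) at a threshold of 2.
Each surviving entity is fitted with a two-way ANOVA using *type-III*
(partial) sums of squares under sum-to-zero effect coding — the standard
definition, and the reason `car::Anova` rather than sequential `anova()`
stands behind `anova2_type3()`; on balanced data the two coincide exactly,
which the tests exploit as an oracle. Unbalanced replicate counts (dropped
arrays) are supported as long as no cell is empty.

P-values are BH-corrected separately per family (nitrogen, water,
interaction) within an organ. Classification: a factor is "responsive"
when its adjusted ANOVA p-value is at most 0.05; an entity is *exclusively
interaction-responsive* when the interaction is significant while neither
factor-level t-test is.

A design decision worth stating: the factor-level t-tests are the
*marginal* two-group comparisons over the 2x2 subdesign (each factor's
samples pooled across the other factor). Under the alternative reading —
cell-vs-cell pairwise tests — a pure cross-over interaction with zero
marginal means would always show significant pairwise differences (each
pairwise contrast equals half the interaction contrast), making the
"exclusively interaction" category empty by construction. The marginal
reading makes the category coherent: a cross-over gene has no marginal
nitrogen effect, no marginal water effect, and a significant interaction.

# The longitudinal mixture model

Each 5-point profile $x_i \in \mathbb{R}^5$ is modelled as a draw from a
$G$-component Gaussian mixture

$$f(x) = \sum_{g=1}^G \pi_g \, \mathcal{N}(x;\, \mu_g, \Sigma_g),$$

where the component precision is parameterized by the modified Cholesky
decomposition

$$\Sigma_g^{-1} = T_g^\top D_g^{-1} T_g,$$

with $T_g$ unit lower-triangular and $D_g$ positive diagonal. This is the
natural covariance structure for ordered measurements: row $k$ of $T_g$
contains the negatives of the coefficients regressing condition $k$ on its
predecessors (generalized autoregressive parameters), and $D_g$ holds the
innovation variances. The density is evaluated without inverting
$\Sigma_g$: the quadratic form is $\lVert D_g^{-1/2} T_g (x-\mu_g)
\rVert^2$ and $\log\lvert\Sigma_g\rvert = \sum_k \log d_{gk}$ because
$\det T_g = 1$.

Three covariance families are available:

* `unconstrained` (default): full per-component $\Sigma_g$,
  $G\,d(d{+}1)/2$ covariance parameters;
* `shared`: one $\Sigma$ (hence one $T$, $D$) for all components;
* `diagonal`: $T_g = I$ with per-component diagonal $D_g$ (conditions
  independent within a component).

The unconstrained family is the default because nothing constrains the
water-condition covariance a priori; the constrained families trade
flexibility for stability on small strata.

## EM, initialization, degeneracy

`longmix()` fits by expectation–maximization: the E-step computes
responsibilities in log space with log-sum-exp (responsibility rows sum to
1 exactly); the M-step updates weights, means and weighted-scatter
covariances, then refactors each covariance through the modified Cholesky
decomposition. The observed-data log-likelihood is nondecreasing across
iterations — the tests assert this on every fit at tolerance 1e-9 — and
iteration stops when the relative log-likelihood change falls below `tol`
(default 1e-8) or the Aitken-accelerated estimate of the asymptotic
log-likelihood is within `tol` of the current value, or after `max_iter`
(default 1000) iterations.

Because EM only finds local optima, each fit runs `n_restarts` (default
10) seeded initializations — hard labels from a k-means partition followed
by one M-step — and returns the best converged restart. Restart $r$ of
seed $s$ uses sub-seed $s + r$, so runs are reproducible end to end.
Degeneracy is handled two ways: innovation variances are floored at
`ridge` (default 1e-6, with the diagonal inflated until the factorization
succeeds), and a component whose expected count falls below one
observation triggers re-initialization of that restart from random labels
(at most three attempts, reported via messages).

## Model selection and subgrouping

`longmix_select()` fits $G = 1..8$ (the range found adequate for these
data sizes) and keeps the fit maximizing

$$\mathrm{BIC} = 2\ell - k \log n$$

(*larger is better* — stated explicitly because sign conventions differ
across software). For the default family in $d = 5$, $k = (G-1) + 5G +
15G$; e.g. 83 parameters at $G = 4$.

The mixture is symmetric in sign — up- and down-regulated versions of a
trajectory shape land in the same cluster — so `split_up_down()` splits
each cluster a posteriori by the sign of the change between two
conditions: mild stress vs optimal water (pair 2–1) for optimal-nitrogen
runs, severe vs mild stress (pair 3–2) for limiting-nitrogen runs. Ties go
to "down" and are reported.

## Profile prescreen

Clustering is run on entities whose profile changes by at least a linear
fold threshold under mild or severe stress relative to optimal water:
threshold 3 under optimal nitrogen and a deliberately relaxed 2 under
limiting nitrogen, where response amplitudes are smaller; both are exposed
as arguments.

# Trend comparison between nitrogen regimes

Entities passing *both* prescreens contribute two observations each — their
optimal-N and limiting-N profiles — to a two-component mixture fit
(`detect_trend_change()`). A gene whose two profiles receive different MAP
components follows a different trajectory shape under limiting nitrogen.
Flags compare the two MAP labels, so they are invariant to component
relabeling, and a gene with identical profiles under both regimes can
never be flagged.

Two open choices, both decided and exposed:

* **Stratification.** The two-component fit runs within each
  optimal-nitrogen cluster group (default), reflecting that trajectories
  were grouped in the first pass; `global = TRUE` fits all stacked
  observations at once for sensitivity analysis.
* **Covariance family.** By default (`model = "auto"`) strata with at
  least 30 observations use the unconstrained family — a full
  per-component covariance can stretch its "divergent" component over
  genes that moved to several different target shapes — while smaller
  strata, where a full 5x5 covariance is not estimable, fall back to the
  diagonal family. Either family can be forced via `model=`.

`summarize_trends()` reports the qualifying count, the flagged count and
the percentage to one decimal (round-half-even). A `min_confidence` option
additionally requires both observations' max responsibility to reach a cutoff
before flagging.

# The synthetic-data generator

No raw data accompany the study design this package targets, so
`simulate_stress_experiment()` is a first-class module that emulates the
design: per entity and condition, the log2 mean is

> baseline + trajectory shape (nitrogen-specific for trend-change
> entities) + nitrogen main effect + interaction term,

with i.i.d. Gaussian replicate noise on the log2 scale (the standard
microarray noise model at this level of summarization) and a raw-scale
export `2^value` floored at 1 intensity unit so the detection filter has
something to reject when baselines are set low. Default condition: three
organs, 3 replicates (90 arrays), 2000 entities, four trajectory shapes of
amplitude 3 log2 units, replicate noise SD 0.25, 5% of entities with a
planted cross-over interaction of 1.5 log2 units, 5% with a planted
nitrogen main effect of 2 log2 units (4-fold), and 10% trend-change
entities. These values are realistic for strong-stress microarray
contrasts: 2–4-fold planted effects against ~0.25 log2-unit replicate
noise match the magnitudes the filtering thresholds (fold change 2–3)
presuppose.

Specifics worth knowing:

* The shape library holds five canonical water responses — flat, monotone
  down, monotone up, stress-peak with recovery, stress-trough with
  recovery — scaled so all pairwise L2 distances are at least half the
  amplitude; beyond five, seeded smooth perturbations extend the library.
* The interaction is planted as a cross-over on the 2x2
  (nitrogen x optimal/severe water) cells with zero marginal means, so the
  interaction cell contrast equals `interaction_effect` exactly at zero
  noise, and such entities are detectable *only* through the interaction
  term.
* Trend-change entities swap their shape (different cluster id) between
  nitrogen regimes rather than rescaling, so the planted truth is
  unambiguous for the trend detector.
* Per-entity baselines are uniform over `baseline_mean ± baseline_spread`,
  giving the detection filter realistic variation.
* One RNG stream is seeded once per simulation; equal seeds give
  bit-identical output. The truth object stores both absolute and
  median-centered planted profiles, the latter matching exactly what the
  preprocessing produces at zero noise.

What the generator does *not* emulate: probe-level effects, intensity-
dependent variance, array batch effects, heavy-tailed noise, or
correlated entities. Passing tests therefore demonstrate the pipeline's
correctness and power under the stated Gaussian conditions, not
performance on any real array set.

# Numerical and testing choices

* Cholesky round-trips, the mixture density against a dense
  solve/determinant oracle, and type-III vs sequential ANOVA on balanced
  data are asserted at 1e-10; EM monotonicity at 1e-9; the G = 1 closed
  form at 1e-8.
* Test problem sizes: cluster recovery uses 4 shapes of amplitude 3,
  noise SD 0.25, 1200 profiles over 20 seeds (component-count selection
  and ARI) and 1000 profiles over 10 seeds (mean recovery, L-infinity
  0.05); trend detection uses 300–400 entities over 20 seeds; null
  calibration uses 50 seeds. These sizes give stable Monte-Carlo estimates
  while keeping the suite quick to run.
* EM restarts are reduced (3–5) from the default 10 in the
  component-count selection studies, where the planted separations make
  the k-means initialization reliable and extra restarts change nothing
  but runtime; fixed-G fits and the trend-comparison fits keep the
  default, which measurably matters there.

# Known limitations

* The interaction stage models each organ separately and only the 2x2
  subdesign; no three-way organ x nitrogen x water model is offered.
* No moderated (shrinkage) t statistics; with 2–3 replicates the pooled
  t-test is noticeably underpowered relative to, e.g., empirical-Bayes
  approaches — a deliberate choice to keep the classical filtered-t
  workflow intact.
* The mixture assumes Gaussian components; heavy-tailed or skewed profile
  distributions will inflate the selected number of components.
* Prescreen-then-cluster truncates the profile distribution at the
  fold-change boundary, which can make BIC prefer more components than
  shapes were planted — visible in end-to-end runs, and a property of the
  procedure, not a defect of the fit.
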