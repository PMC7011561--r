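---
title: "Testing treatment effect heterogeneity by repeated data splitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing treatment effect heterogeneity by repeated data splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tehsplit)
```

## The problem

Retrospective subgroup analyses of randomised controlled trials (RCTs) are
notoriously prone to false positives: flexible models trawled over baseline
covariates will always "find" strata that appear to respond differently,
and with machine-learning (ML) discovery models the classical
degrees-of-freedom accounting that disciplines parametric interaction tests
is unavailable. `tehsplit` implements a testing-only framework that lets an
arbitrary statistical or ML model hunt for treatment effect heterogeneity
(TEH) while keeping the type I error of the final declaration at or below a
prespecified level $\alpha$. It deliberately answers only the omnibus
question "is there evidence of TEH?" — it reports a p value, not an
estimate of who is in a subgroup; estimation is a separate, explicitly
post-hoc exercise whose outputs should be treated as qualitative.

Two distinct one-sided hypotheses are covered, reported separately and with
no cross-test multiplicity correction (they are distinct prespecified
analyses):

1. **Crossover TEH (benefitting subgroup)** — is there a stratum of
   patients whose *optimal* treatment differs from the prespecified
   standard of care?
2. **Added predictive benefit** — does the ML model predict the outcome
   better than a baseline logistic GLM, i.e. is the extra flexibility
   earning its keep?

## The procedure

Both tests rest on the same engine: repeated arm-balanced 50/50 random
splits with out-of-sample cross-prediction.

For each of $K$ random partitions of the trial into halves $A$ and $B$
(balanced within each treatment arm, so each half is itself a miniature
two-arm trial):

**Crossover test.** A discovery model fitted to $A$ predicts, for every
subject in $B$, the event probability under each arm; the difference
$\Delta_i = \hat{\Pr}(Y=1 \mid X_i, T=1) - \hat{\Pr}(Y=1 \mid X_i, T=0)$ is
the estimated individual treatment effect (ITE), and symmetrically for $B$
scoring $A$. Every subject is scored exactly once, always by a model that
never saw them. Subjects with $\Delta_i < 0$ (predicted strict benefit from
the experimental arm; ties conservatively stay with standard of care) form
a held-out subgroup of size $n_s$. Randomisation guarantees that within
this subgroup roughly half actually received each arm, so a one-sided
two-sample test (default: Fisher's exact test on the received-arm × event
2×2 table, exact at small $n_s$) asks whether those who received the
experimental treatment really did better. Under the null — no subgroup
benefits from switching — this p value is uniform (conservatively
super-uniform, see degeneracy below). The mean of $n_s/n$ across splits
estimates the prevalence of the predicted-to-benefit stratum.

**Added-benefit test.** On the same partition, both a baseline GLM and the
ML model are fitted to each half and produce out-of-sample predictions for
the other half under each subject's *actual* treatment: the GLM linear
predictor $\hat{Z}^{GLM}_i$ and the ML log-odds $\hat{Z}^{ML}_i =
\mathrm{logit}(\hat{P}_i)$. A second-stage ("stacked") logistic model
$\mathrm{logit}\,\Pr(Y_i = 1) = \theta_0 + \hat{Z}^{GLM}_i\theta_{GLM} +
\hat{Z}^{ML}_i\theta_{ML}$ is fitted to the full data and $\theta_{ML} = 0$
is tested by the 1-df deviance (likelihood-ratio) comparison of the nested
fits — the standard analysis-of-deviance for nested GLMs.

**Aggregation.** Either procedure yields $K$ dependent p values
$p_1,\dots,p_K$. They are merged by quantile scaling:
$$Q_\gamma = \min\Big(1, \mathrm{Quantile}_\gamma\{p_i/\gamma\}\Big),
  \qquad
  p_{\mathrm{agg}} = \min_{\gamma\in[\alpha,1]}
  \min\big(1, (1-\log\alpha)\,Q_\gamma\big),$$
with natural logarithm; the $(1-\log\alpha)$ factor pays for the search
over $\gamma$. Fixing $\gamma$ in the analysis plan instead removes the
penalty; $\gamma = 0.5$ gives the memorable "twice the median" rule
$p_{\mathrm{agg}} = \min(1, \mathrm{Median}(2p_1,\dots,2p_K))$. Under
either rule, rejection at level $\alpha$ has probability at most $\alpha$
under the null, for *any* dependence among the $p_i$ — the property the
package's calibration studies verify by simulation.

## Numerical and design choices

These choices were genuinely open and are fixed as follows.

* **Quantile convention.** $\mathrm{Quantile}_\gamma$ is the inverse-ECDF
  (type-1) quantile: the smallest order statistic whose ECDF reaches
  $\gamma$. Conventions differ materially at small $K$; this one makes the
  $\gamma = 0.5$ rule agree exactly with the median-of-doubled-p closed
  form used throughout.
* **Exact $\gamma$ minimisation.** $Q_\gamma$ is piecewise in $\gamma$
  through the order statistics and decreasing within each piece, so the
  sweep is evaluated on $\{\alpha\} \cup \{j/K\}$, attaining the true
  minimum rather than approximating on an arbitrary grid. A matching
  closed-form boundary in the ECDF plane, $x = \gamma\alpha/(1-\log\alpha)$,
  drives the visual read-out (`plot_pvalue_ecdf()`): rejection iff the
  p-value ECDF touches or crosses above it; the equivalence is exact and
  tested.
* **Degenerate splits.** A split can fail to produce a usable test: a
  training half with one arm or constant outcome, an empty subgroup, a
  subgroup entirely within one received arm, or no outcome variation in
  the subgroup. Such splits are assigned p = 1 and flagged, never dropped
  — dropping them would condition on an outcome-dependent event and bias
  the aggregate towards small p. This also makes the per-split p
  super-uniform rather than exactly uniform, i.e. conservative.
* **Ties.** $\Delta_i = 0$ assigns standard of care: a patient is never
  moved off the default arm without predicted strict benefit.
* **Probability clipping.** Ensemble learners can emit probabilities of
  exactly 0 or 1, whose log-odds are infinite; ML probabilities are clipped
  to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 0.001$ by default,
  before stacking. The value is small relative to plausible event rates and
  configurable.
* **Intercept in the stacked model.** Included by default: out-of-sample
  predictors can be miscalibrated in level, and an intercept-free stack can
  convert pure miscalibration into spurious "added benefit". An
  intercept-free mode (`intercept = FALSE`) is retained for exact
  replication of analyses that stack without one.
* **Perfect separation.** If the stacked logistic fit separates (detected
  via the usual fitted-probability warning, non-convergence, or fitted
  probabilities pinned within $10^{-10}$ of 0/1), both nested models are
  refitted with an identical small ridge penalty and the penalised deviance
  difference is used, flagged on the split. Exactly collinear
  $\hat{Z}^{ML}$ gives statistic 0, p = 1.
* **Seeds.** One master seed per run; split $k$ uses `master_seed + k` for
  both the partition and the model fit, and every seed is echoed in the
  JSON report, so a run is reproducible from the data file and the config
  alone.
* **Split ratio and K.** The split is always 50/50 in the headline API:
  each subject's prediction error scales like the inverse square root of
  the opposite training-half size, so the error across both directions is
  proportional to $1/(\sqrt{n_1} + \sqrt{n_2})$, minimised at $n_1 = n_2$.
  `split_ratio_experiment()` demonstrates this empirically (unequal ratios
  exist only there). The experiment isolates sampling variability — the SD
  of ITE predictions at fixed evaluation points across replicate training
  draws — because the learner's bias does not depend on the split ratio
  and would otherwise swamp the comparison; its default learner is the
  GLM, whose prediction SE shows the $1/\sqrt{n_{train}}$ scaling cleanly
  at moderate $n$, whereas randomised ensembles add a size-independent
  randomisation variance that flattens the curve at desk scale. Default
  $K = 1000$; the running-aggregate traceplot
  (`plot_trace()`) shows stabilisation, typically by a couple of hundred
  splits — if the tail still drifts, increase $K$.

## What the synthetic generator emulates — and what it does not

`sim_scenario()`/`generate_trial()` draw trials from
$$\mathrm{logit}\,\Pr(Y=1) = b_0 + X\beta + T\tau +
  T\,\mathbf{1}[x_1 > q_{1-\pi}]\,\delta,$$
with independent standard normal covariates, fair-coin randomisation
independent of $X$, and a single subgroup interaction — the simplest
structure realising each kind of TEH: `none` ($\delta=0$), `noncrossover`
($\delta$ reinforcing $\tau$), `crossover` ($\tau+\delta$ opposite in sign
to $\tau$). A `smooth` variant replaces the indicator with a logistic ramp
for a drifting rather than jumping ITE. Defaults emulate a mid-sized
mortality trial: $n = 500$, five covariates, baseline event rate near 20%,
$\tau = -0.5$ (odds ratio $\approx$ 0.6) where the experimental arm is
protective, and for the crossover kind $\tau = +0.5$, $\delta = -2.0$,
prevalence $\pi = 0.3$ — the standard of care optimal outside the subgroup
and a strong reversal inside it.

One orientation subtlety is worth spelling out: the crossover test's null
is "nobody benefits from switching off standard of care". A uniformly
*beneficial* experimental arm ($\tau < 0$, no heterogeneity at all) is an
alternative for this test — the predicted-to-benefit subgroup then truly
benefits — so the `none` scenario defaults to $\tau = 0$, the boundary
null. Any `none` scenario is a null for the added-benefit test, because its
truth is exactly linear in $X$ and $T$.

Ground truth (each subject's true ITE and subgroup membership) is returned
beside the data for oracle checks and power studies, and
`oracle_predictor()` turns the generative model itself into a discovery
model, separating the behaviour of the test machinery from learner noise.

What passing tests on these trials do **not** show: the generator has
independent, homoscedastic, all-numeric covariates, no missingness, no
measurement error, logistic outcome structure and exact randomisation.
Real trials have correlated mixed-type covariates, informative
missingness, and model misspecification. The validity guarantee itself
needs none of those assumptions (only independently recruited subjects —
paired or clustered recruitment breaks it), but *power* estimated on
synthetic trials transfers to real data only loosely.

## Problem sizes used in the shipped studies

The package's own calibration and power studies (test suite and the
acceptance script) run at desk scale, chosen to make Monte-Carlo
assertions meaningful while keeping a full run comfortable on one CPU:
null calibrations with 40–60 fresh trials of $n = 500$ at $K = 20$ splits
and 60-tree forests; power studies with 16 trials of $n = 1000$ at $K =
12$; aggregation validity with hundreds of thousands of simulated p
values. The binomial 3-standard-error tolerances are computed at the
replicate counts actually used. Production analyses should use $K \ge
200$ (ideally 1000) and full-size forests; all sizes are arguments, not
constants.

## Finite-sample calibration of the two tests

The two tests do not control the type I error by the same mechanism, and
it shows at finite $n$.

The **crossover test's** per-split p value is conservative by
randomisation alone: under the null, treatment assignment within the
held-out subgroup is independent of outcomes, and Fisher's exact test is
exact (degenerate splits only add p = 1 mass). Null calibrations
accordingly come out at or well below the nominal level.

The **added-benefit test's** per-split p value relies on the asymptotic
$\chi^2_1$ reference for the stacked likelihood-ratio statistic, *and* on
treating the cross-fitted predictions as fixed covariates. Both are
approximations: the baseline channel $\hat Z^{GLM}$ is an estimate, not
the true risk score, and the ML channel can legitimately pick up part of
the estimation residual even when the truth is exactly linear; the
cross-observation dependence induced by cross-fitting is likewise ignored
by the reference distribution. In the package's own null calibration
(linear truth, $n = 500$, random-forest channel) the per-split rejection
rate at the 5% level is around 10% rather than 5%, independent of the
forest size, and the aggregated test inherits a milder version of this
inflation. The effect shrinks with $n$ (the baseline estimate converges to
the true risk). Practically: treat borderline added-benefit p values
near $\alpha$ with caution at small samples, while small crossover-test p
values can be taken at face value.

## Limitations

* Two-arm, individually randomised trials with binary endpoints only (the
  statistic registry accepts ordinal/continuous two-sample statistics, but
  the shipped pipeline is built around binary outcomes).
* Complete cases are required; imputation is out of scope and must happen
  — prespecified — upstream.
* The tests are non-constructive by design: a small aggregate p value
  licenses exploratory characterisation of the heterogeneity (e.g.
  fitting the ML model to the full data and exporting per-subject ITEs),
  but those downstream numbers carry no formal error control.
* Rarer subgroups are intrinsically harder: power falls with subgroup
  prevalence, and the cross-fitted discovery model only ever sees half the
  trial.

## A worked miniature

```{r example, eval = FALSE}
sc <- sim_scenario(n = 500, teh_kind = "crossover", seed = 7)
trial <- generate_trial(sc)

res <- run_crossover_test(
  trial$data,
  predictor = predictor_spec("random_forest", list(num_trees = 200)),
  K = 200, alpha = 0.05, master_seed = 7)
print(res)
plot(res, "ecdf")
plot(res, "trace")

ab <- run_added_benefit_test(
  trial$data,
  ml_spec = predictor_spec("random_forest", list(num_trees = 200)),
  K = 200, alpha = 0.05, master_seed = 7)
print(ab)

write_report(res, "subgroup_report.json")
```
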