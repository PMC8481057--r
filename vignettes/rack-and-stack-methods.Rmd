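---
title: "Measuring pre/post training change with rating-scale Rasch stacking and racking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pre/post training change with rating-scale Rasch stacking and racking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rackstack)
```

## The measurement problem

Observer-scored skill checklists — for example, community health volunteers
rated on each step of an anthropometric measurement protocol before and after
a training — produce ordinal ratings (here 0 = cannot perform, 1 = performs
imperfectly, 2 = performs perfectly). Raw sum scores on such rubrics are
ordinal, not interval: one extra point near the ceiling represents a much
larger skill difference than one near the middle. Before pre/post change can
be compared across people or items, the ratings need to be placed on a common
interval scale.

`rackstack` does this with the Andrich **rating scale model** (RSM), the
polytomous Rasch model in which all items of an instrument share one set of
category thresholds. For person ability $\theta_n$, item difficulty
$\delta_i$ and thresholds $\tau_1, \dots, \tau_m$ (all in logits),

$$
P(X_{ni} = k) \;=\;
\frac{\exp\!\Big(\sum_{j=1}^{k} (\theta_n - \delta_i - \tau_j)\Big)}
     {\sum_{l=0}^{m} \exp\!\Big(\sum_{j=1}^{l} (\theta_n - \delta_i - \tau_j)\Big)},
\qquad k = 0, \dots, m,
$$

with the empty sum equal to zero. The RSM (rather than the partial credit
model) is the natural choice when every item uses the same verbal rubric, as
a 0/1/2 "cannot / imperfect / perfect" checklist does; a per-item threshold
model is deliberately out of scope.

## Estimation

`rasch_rsm()` fits the model by **joint maximum likelihood** (JMLE, also
called UCON): alternating damped Newton steps that match each person's and
item's expected raw score to its observed raw score, plus a Newton step on
the cumulative category counts for the thresholds.

* **Initialisation** is PROX: log-odds of the raw-score margins and
  log-ratios of adjacent category counts (`prox_initialize()`).
* **Identification.** The likelihood is invariant to translating all
  $\theta$ and $\delta$ together, so every sweep re-anchors
  $\text{mean}(\delta) = 0$ over non-extreme items and $\sum_j \tau_j = 0$,
  compensating $\theta$ so the likelihood is untouched.
* **Update order** is fixed — persons, then items, then thresholds — and
  each update is capped at 1 logit per sweep. Undamped alternating Newton
  can oscillate on small matrices; the cap costs a few extra sweeps and
  removes that failure mode.
* **Convergence** requires both a maximum absolute score residual below
  `score_tol` (default 0.01 score points) and a maximum logit change below
  `change_tol` (default 0.001), within `max_iter` (default 100) sweeps.
  These defaults are far tighter than the two decimals at which logit
  measures are usually read. Non-convergence warns and is flagged in the
  result, never silent.
* **Extreme scores.** Zero and perfect raw scores have no finite MLE. They
  are excluded from the joint fit, then given finite measures by solving the
  estimating equation for an adjusted score (0 becomes 0.3, the maximum
  becomes maximum − 0.3 score points; `extreme_adjust`) against the fixed
  co-parameters, and flagged `extreme`. This matters in practice: a strong
  training effect routinely puts a quarter of posttest persons at the
  ceiling (`ceiling_rate()`).
* **Standard errors** are model-based Fisher information,
  $1/\sqrt{\sum W}$, where $W$ is the model score variance of a cell.
* **Missing data** are simply excluded from every sum. Identifier matching
  across occasions is exact and case-sensitive; silent fuzzy matching can
  corrupt a paired design.
* **Bias correction.** JMLE measures are systematically inflated by a factor
  of roughly $I/(I-1)$ for an $I$-item instrument (about 8% at $I = 13$).
  Following the convention of the field's standard software, no correction
  is applied by default, so fitted logits are comparable with published
  ones. `calibration_config(bias_correct = TRUE)` applies the classical
  $(I-1)/I$ rescaling of item difficulties; the package's own
  truth-recovery checks use it, because there the target is the generating
  values rather than comparability of the printed scale — without it the
  systematic inflation (≈0.09 logit at these difficulty magnitudes)
  dominates the recovery error budget.

The test suite pins the estimator to an independent oracle: on small fixed
matrices, cyclic coordinate ascent of the joint log-likelihood over a
0.01-logit grid (the likelihood is concave, so the grid ascent finds the
global maximum at grid resolution) agrees with `rasch_rsm()` to well within
0.05 logits on every parameter.

## Stacking and racking

Both arrangements ask "what changed after training?", but isolate different
things:

* **Stacking** (`rasch_stack()`): the pre and post matrices are
  row-concatenated, so each person appears twice (pretest ids prefixed `P`,
  posttest ids prefixed `0`) against a *single shared set of item
  difficulties*. Each person gets one ability per occasion ("logit value
  person", LVP), and the per-person differences measure individual skill
  change on a common ruler.
* **Racking** (`rasch_rack()`): the matrices are column-concatenated, so
  each item appears twice (prefixes `i` and `o`) against a *single shared
  ability per person*. Each item gets one difficulty per occasion ("logit
  value item", LVI); a negative post − pre difference means the item became
  easier, i.e. that skill improved. Because the paired design quotes drops
  as positive numbers, summaries also report the absolute magnitude.

One joint calibration per arrangement is used, following the plain reading
of "combining the two datasets"; an anchored two-step equating variant would
be a reasonable alternative but gives the same qualitative structure and is
left as future work.

Group change is tested with the **Wilcoxon signed-rank test**
(`wilcoxon_signed_rank()`): zeros dropped, midranks for ties, exact
two-sided p by full $2^n$ enumeration of sign assignments for up to 12
nonzero differences (4096 assignments — instant, and unlike
`stats::wilcox.test` the enumeration handles ties exactly via the permuted
midrank distribution), and beyond that a normal approximation with
tie-corrected variance and a 0.5 continuity correction.

`difficulty_crossplot()` reproduces the item-level reading: both occasions'
difficulties are median-centred and each item is classified against the
identity line. Items **above** the line dropped less than is typical — the
skills that stayed hard (in the motivating application, the mid-upper arm
circumference and head circumference blocks) — and are the candidates for
targeted follow-up training. Note that the majority of items necessarily
straddles the line (the medians anchor it), so the informative signal is the
flagged minority.

`wright_map()` renders the shared logit scale as a monospace person–item
map (persons left, items right, landmarks M/S/T at the mean and ±1/±2 SD;
ties within a bin ordered lexicographically so output is deterministic).
Text is the primary artifact — diff-able and parseable
(`parse_wright_map()` recovers every entity's bin) — with
`autoplot()` as the graphical layer.

## Quality diagnostics

`psychometric_panel()` summarises instrument quality per occasion:

* **Separation and reliability** for persons and items: with observed
  variance $SD^2$ and mean squared error $MSE$, true variance
  $T = \max(SD^2 - MSE, 0)$, reliability $R = T/SD^2$, separation
  $G = \sqrt{T/MSE}$, tied by $R = G^2/(1+G^2)$.
* **Cronbach's alpha**, definitional formula on listwise-complete persons.
* **Raw variance explained by measures.** The package uses the expected-value
  decomposition $100 \cdot \mathrm{Var}(E_{ni}) / (\mathrm{Var}(E_{ni}) +
  \overline{W}_{ni})$: the modelled cell values carry the variance the
  measures explain, the model score variances are the unexplained noise
  floor. Conventional software computes an observed-data analogue; the two
  agree to the extent the model fits. This formula was chosen because it is
  exactly reproducible and testable; above ~40% is conventionally read as
  excellent unidimensionality.
* **Residual first contrast**: the largest eigenvalue of the item × item
  correlation matrix of standardised residuals (pairwise-complete where data
  are missing). Near 1 under model fit; the panel reports both the
  eigenvalue and the share of unexplained variance it carries, since
  published tables are often ambiguous about which is quoted.
* **Infit/outfit** mean squares (`fit_statistics()`), ≈1 under fit; not part
  of the published panel but indispensable quality control for any
  calibration.

## The synthetic-data generator

No raw assessment data are distributed, so `sim_design()` +
`simulate_prepost()` generate study-shaped cohorts: by default 41 persons,
11 items (the `"infant"` preset; `"toddler"` has 13) on a 0/1/2 rubric,
pretest abilities $\mathcal{N}(0.3, 1)$, difficulties equally spaced on
$[-2, 2]$, thresholds $(-1, +1)$, and a training effect of 2.7 (infant) or
3.3 (toddler) logits — magnitudes chosen to echo the motivating study's
published group gains — plus per-person effect noise with SD 0.5 logits (a
modest, realistic heterogeneity: trainees do not benefit identically) and
optional item-specific extra effects for hard-skill blocks. One random
stream is consumed in a documented fixed order (abilities, effect noise, pre
cells row-major, post cells row-major, missingness), so a seed fully
determines the dataset.

What the generator deliberately does *not* emulate: observer/rater
disagreement (the model assumes one reconciled rating per person × item ×
occasion), drop-out between occasions, local item dependence within skill
dimensions, and any misfit to the RSM itself. Passing recovery tests
therefore show that the pipeline measures what the model generates — they do
not validate the RSM against real checklist behaviour, which is what the
fit statistics and the residual contrast are for on real data.

## Problem sizes and numerical choices

The packaged checks run at deliberately modest sizes: oracle equivalence on
5×4 and 6×5 matrices; truth recovery at 500 persons × 13 items; effect
recovery at the study shape (41 × 11) averaged over 20 seeds; signed-rank
exactness enumerated for all sign patterns up to n = 10; null uniformity of
stacking p-values over 200 replicate cohorts. Degenerate inputs have defined
behaviour: a never-observed category aborts with advice to
`collapse_categories()`; identical pre/post occasions yield zero differences
and a degenerate (NA) test rather than an error; zero measure spread gives
reliability 0, not NaN.

## Known limitations

* JMLE (not CMLE/MMLE/WLE): chosen for fidelity to the field's standard
  outputs; its finite-length bias is documented above.
* One rating per person × item × occasion; rater facets are not modelled.
* No DIF analysis and no equating across different instruments.
* The exact signed-rank test is limited to 12 nonzero pairs before switching
  to the (tie-corrected, continuity-corrected) normal approximation; at that
  size the approximation error is already negligible.
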