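---
title: "Attributing disability prevalence to chronic diseases: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing disability prevalence to chronic diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disattrib)
```

## The problem

Cross-sectional health surveys measure disability with the Global Activity
Limitation Indicator (GALI): a respondent is "disabled" if they report being
limited, or severely limited, in usual activities for at least six months.
Surveys also collect a checklist of chronic conditions, grouped here into 13
disease groups, plus education (ISCED low / middle / high) and sampling
weights. Two public-health questions drive this package:

1. How much of the disability prevalence in each education group is
   attributable to each chronic disease, allowing for multimorbidity and for
   disability reported in the absence of any listed disease?
2. Is the educational gap in disability driven by the lower-educated group
   having *more disease*, or by the same diseases being *more disabling*
   for them?

## The additive hazard model

For individual $i$ with age band $a$, education $e$ and disease indicators
$X_{di}$,

$$Y_i \sim \mathrm{Bernoulli}(\pi_i), \qquad
  \pi_i = 1 - e^{-\eta_i}, \qquad
  \eta_i = \alpha_{ae} + \sum_{d=1}^{m} \beta_{cde} X_{di},$$

where $\eta_i$ is a cumulative disability rate, $\alpha_{ae} \ge 0$ is the
background rate (disability from unlisted, unreported or undiagnosed causes),
and $\beta_{cde} \ge 0$ is the disabling impact of disease $d$. The
complementary-log link makes hazards *add* across competing causes: under the
assumptions that (i) reported diseases and the background explain all
disability, (ii) they act as independent competing causes, and (iii) their
cumulative rates were proportionally stable before the survey, the
probability of escaping disability factorizes as
$e^{-\alpha}\prod_d e^{-\beta_d X_d}$.

A full age (6 bands) $\times$ disease (13) $\times$ education (3)
interaction would be badly over-parameterized, so the interaction is reduced
to rank one: $\beta_{cde} = \gamma_c\,\delta_{de}$, one age pattern
$\gamma_c$ over four coarse bands shared by all diseases, times a
disease-by-education effect $\delta_{de}$. The bilinear product is only
identified up to scale, so `fit_additive_hazard()` fixes $\gamma_1 = 1$:
$\delta_{de}$ is then the disabling impact at the youngest (reference) ages.
Models are fitted separately for men and women.

Age bands are half-open `[lo, hi)`: "25–39" contains exactly ages 25–39 in
whole years. The background bands are 25–39, 40–49, 50–59, 60–69, 70–79,
80+; the age-pattern bands are 25–39, 40–54, 55–69, 70+.

## Fitting

The weighted likelihood uses sampling weights as frequency-style multipliers
(a pseudo-likelihood), normalized to mean 1; `use_weights = FALSE` gives the
unweighted fit. Records are first collapsed to unique (band, education,
disease-pattern, outcome) cells with summed weights, which the likelihood
depends on sufficiently — evaluation cost is then independent of cohort
size.

Optimization is block-alternating bounded quasi-Newton (`optim` L-BFGS-B
with a lower bound of 0, analytic gradients):

* with $\gamma$ fixed, the model is additive in $(\alpha, \delta)$ and that
  block is solved under box constraints;
* with $(\alpha, \delta)$ fixed, the free elements $\gamma_2, \gamma_3,
  \gamma_4$ are solved likewise;
* blocks alternate until the relative change in log-likelihood is below
  `tol` (default $10^{-8}$), with monotone ascent asserted at every step.

Starting values are cheap moment-style estimates: $\alpha$ from the weighted
disability rate among the disease-free in each cell, $\delta$ from crude
with-versus-without cumulative-rate differences (halved, to discount
multimorbidity double-counting), $\gamma \equiv 1$. Because the surface is
bilinear, `n_starts` (default 2) jittered initializations are run and the
best likelihood kept; the jitter is reproducible from `seed`. Diseases with
zero weighted prevalence in an education stratum have $\delta$ pinned at 0,
and empty education-by-band cells have $\alpha$ pinned at 0; both are
reported in `boundary_flags` rather than raised as errors. A disabled record
with $\eta = 0$ would make the log-likelihood $-\infty$; $\pi$ is floored at
$10^{-12}$ so the penalty is large but finite and the optimum stays interior.

## Attribution

The fitted prevalence of each scope is partitioned with the
proportional-hazard-share rule: individual $i$'s probability splits as

$$\text{share}_{di} = \pi_i\,\frac{\beta_{cde} X_{di}}{\eta_i}, \qquad
  \text{background}_i = \pi_i\,\frac{\alpha_{ae}}{\eta_i},$$

with all shares zero when $\eta_i = 0$. These sum to $\pi_i$ exactly, so
weighted averages of shares over any scope partition the *model-predicted*
prevalence (weighted mean $\hat\pi_i$) additively to machine precision. We
partition the predicted rather than the observed prevalence because the
former makes additivity exact; the weighted observed prevalence is carried
alongside as a fit diagnostic (`scope$observed_prevalence`), and no
rescaling to the observed prevalence is applied.

Age standardization is the linear operation
$\sum_a v_a w_a / \sum_a w_a$ with standard-population weights $w_a$;
applied band-by-band to each cause's contribution it therefore preserves
additivity exactly. The single standardized "disabling impact" reported per
disease and education is the standardized mean of $\beta_{cde} =
\gamma_c \delta_{de}$ over the age structure; since the standard population
is tabulated on the six background bands while $\gamma$ lives on the four
coarser bands, band weights are projected assuming a uniform age
distribution within bands (only the 50–59 band straddles a pattern boundary,
split 50/50). `disabling_impact()` also accepts rank-band weights directly.

Confidence intervals for weighted proportions use a normal approximation
with the Kish effective sample size $(\sum w)^2 / \sum w^2$; the educational
odds ratio of disability is crude (unadjusted), with a Woolf-type interval
on the log scale using effective cell counts.

## Counterfactual decomposition of the educational gap

Two scenarios re-compute the low-educated group's standardized attribution:

* **swap_prevalence** — give the low-educated group the high-educated
  group's *age-specific* weighted disease prevalences, keeping its own
  $\alpha$, $\gamma$, $\delta$. Age-specific (not standardized) prevalences
  matter: a disease can be rarer overall in the donor group yet more common
  at the oldest ages, which changes the result. The expected attribution is
  computed exactly by enumerating all $2^m$ disease states per band under
  independence (8192 states for 13 diseases; beyond `max_exact_m = 15` a
  seeded Monte-Carlo fallback engages and is flagged). The independence
  assumption mirrors model assumption (ii); observed multimorbidity
  correlation is not preserved, which is a stated limitation.
* **swap_impact** — replace $\delta_{\cdot,\mathrm{low}}$ with
  $\delta_{\cdot,\mathrm{high}}$ and re-attribute the low-educated group's
  *observed* records.

The background $\alpha$ is never swapped: the scenarios equalize disease
prevalence or disease impact only, though the background *contribution*
still shifts through the proportional-share rule. `decompose_gap()` then
reports the baseline gap (low minus high), the gap remaining with equal
prevalences (the impact-driven part) and the gap remaining with equal
impacts (the prevalence-driven part), overall and per cause;
`render_table2()` lays this out as one row per cause and seven columns.
The decomposition is descriptive ("what-if" recalculation), not a causal
mediation analysis.

Within the enumeration, the age-pattern value for a background band is the
$\gamma$ average weighted by the recipient group's observed rank-band
composition inside that band (uniform-age split as fallback), so an identity
swap reproduces the baseline closely.

## Bootstrap uncertainty

`bootstrap_ci()` resamples individual records with replacement, weights
travelling with records, and re-runs the full fit-plus-attribution statistic
per replicate (1000 replicates is the survey convention; tests use 100–200).
The default interval is normal-type, point $\pm 1.96 \times$ bootstrap SD:
for parameters constrained non-negative this can produce lower bounds below
zero — which published applications of the method show — whereas percentile
intervals cannot. Resampling is simple iid over individuals; no
design-stratified resampling is attempted. Replicates whose fit fails are
dropped and counted; above 10% failures the output is flagged.

## The synthetic-cohort generator

Because disability-survey microdata are access-restricted, validation runs
on synthetic cohorts with known truth. `default_truth()` fixes the study
conditions: a cohort of 23,348 by default (a typical national-survey size;
validation runs scale n up or down as stated below), three education strata
(35/40/25%), six age bands weighted toward younger adults, disease
prevalences rising with age and graded by education (e.g. arthritis more
prevalent *and* more disabling among the low-educated), background hazards
rising with age and falling with education, an age pattern
$\gamma = (1, 1.3, 1.7, 2.2)$, and gamma-distributed sampling weights with
mean 1 and CV 0.5. The rarer disease groups are set near 4% prevalence so
that every disease-by-education cell contains cases at moderate cohort
sizes. All values are fixture choices on realistic scales — not estimates
from any survey — and the generator's disability law is exactly the additive
hazard model, so parameter-recovery tests validate the estimator, not the
model's adequacy for real data.

What the generator does not emulate: household/area two-stage sampling and
non-response (weights are iid gamma draws), proxy responding, reporting
bias by education, and — by default — multimorbidity clustering. A
`disease_correlation` knob adds a shared latent Gaussian tilt
(copula-style, marginals preserved) for robustness probes. Passing tests on
this generator therefore demonstrate correctness of estimation and
decomposition under the model's own assumptions, not robustness to their
violation.

## Validation design and problem sizes

The test suite validates, at sizes chosen to balance resolution against
runtime:

* **parameter recovery** on a 200,000-record `default_truth()` cohort
  (each $\delta_{de}$ within max(15%, 0.05)); the package's own fits take a
  few seconds at this size thanks to the collapsed likelihood;
* **null calibration**: a 200,000-record single-sex cohort with all
  $\delta = 0$ and a flat 20% prevalence for every disease — a deliberately
  well-conditioned design in which every disease-by-education cell has
  thousands of exposed respondents, so the check that all fitted
  $\hat\delta \le 0.02$ measures boundary bias of the constrained estimator
  rather than sampling noise in rare cells;
* **oracle equivalence**: the fitted likelihood against a dense grid scan
  on a two-disease toy, and the $2^m$ enumeration against a $10^6$-draw
  Monte-Carlo oracle;
* **decomposition validity** on 100,000-record cohorts constructed so the
  education groups differ *only* in prevalence (or only in impact): the
  matching counterfactual removes the gap and the other leaves it, within
  0.02 (two percentage points of prevalence, ~3 Monte-Carlo standard
  errors at this size);
* **bootstrap calibration** at reduced scale: 200 cohorts of 5,000 records,
  200 replicates each, on a small two-disease model; nominal 95% intervals
  for a mid-sized $\delta$ must cover truth in 90–99% of cohorts.

## Known limitations

* The attribution is model-based: if the additive hazard with rank-one
  interactions misfits, contributions inherit the misfit; compare predicted
  with observed prevalence per scope.
* The prevalence-swap counterfactual assumes independent diseases within
  strata; with strong multimorbidity clustering the expected prevalence
  under swapped marginals is approximate.
* Normal-type bootstrap intervals can cross zero for non-negative
  parameters; they are reported as computed.
* The cross-sectional design supports no causal reading of the
  decomposition, and education-differential disease reporting is not
  modelled.
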