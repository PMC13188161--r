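---
title: "Hierarchical calibration of chemical-agnostic qAOPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical calibration of chemical-agnostic qAOPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qaopcal)
```

## The model

A quantitative adverse outcome pathway (qAOP) links a dose to a
continuous upstream key event (KE_up, e.g. % BrdU-positive hepatocytes)
and onward to a dichotomous downstream key event (KE_down, e.g. liver
tumor incidence). `qaopcal` works with summarized dose-group data: per
chemical $k$ and dose group $j$, the natural-scale mean, SD and size of
the upstream measurements $(m_{Yj}, s_{Yj}, n_{1j})$ and the downstream
case count and group size $(X_j, n_{2j})$.

The upstream responses are lognormal. Natural-scale summaries are moved
to the log scale by moment matching,
$s = \sqrt{\log(1 + (s_Y/m_Y)^2)}$, $m = \log m_Y - s^2/2$, which is
exact under lognormality and algebraically invertible
(`transform_summary_to_log()`). On the log scale each group has a latent
mean $M_j$ with within-group SD $\sigma_1$; the summaries are sufficient
statistics, so the upstream log-likelihood is

$$
LL = -\tfrac{N}{2}\log(2\pi) - \sum_j \Big[ \tfrac{n_{1j}}{2}\log\sigma_1^2
  + \frac{n_{1j}(m_j - M_j)^2 + (n_{1j}-1)s_j^2}{2\sigma_1^2} \Big],
$$

identical to the per-individual normal log-density sum (this equivalence
is tested to 1e-8). The latent mean follows a continuous Hill
dose-response curve, $M_j \sim N(f_1(d_j), \sigma_2)$ with
$f_1(d) = a + b\,d^g/(c^g + d^g)$, and the downstream counts are
binomial, $X_j \sim \mathrm{Bin}(n_{2j}, f_2(M_j))$, through a
dichotomous Hill response-response curve

$$
f_2(M) = v\,\frac{q + e^{r(M-h)}}{1 + e^{r(M-h)}},
$$

so the probability runs from the background $vq$ to the maximum $v$,
with half-maximal effect at $M = h$ and slope $r > 0$ for increasing
trends. An alternative orientation of this curve (selectable with
`orientation = "printed"`) swaps the roles of the bounds; it is kept
only for sensitivity analysis because it contradicts the parameter
semantics above ($vq$ would become the *maximum*), and because with it
the zero-level background used by the benchmark-level inversion would be
$v$ rather than $vq$.

Because the two key events are usually measured in different dose
groups, one latent $M_j$ is kept per (chemical, dose) design point in
the union of both datasets; a chemical appearing only in the downstream
data cannot be anchored and is rejected at validation.

## Flat versus hierarchical calibration

Both calibrations share an identical dose-response block — chemical-
specific $a_k, b_k, c_k, \sigma_{1k}$ with global $g, \sigma_2$ — so any
difference in predictive performance is attributable to the
response-response part alone. The *flat* model shares one
$(v, q, h, r)$ across all chemicals. The *hierarchical* model gives each
chemical $v_k, q_k, h_k$ built from chemical-agnostic centers
($\mu_v, \mu_q, \mu_h$), chemical-agnostic scales
($\sigma_v, \sigma_q, \sigma_h$) and chemical-specific standardized
deviations $z_k$, with $(z^v_k, z^q_k)$ correlated (the upper and lower
response bounds of a chemical tend to move together) and the power $r$
chemical-agnostic (curve shape is a pathway property).

Two numerical choices are worth stating:

* **Domain handling.** Additive normal random effects can push $v_k$ or
  $q_k$ outside $(0,1)$. By default the random effects act additively on
  the *logit* scale ($v_k = \mathrm{logit}^{-1}(\mathrm{logit}(\mu_v) +
  \sigma_v z^v_k)$), so domains hold by construction and $\mu_v$ remains
  the median of the $v_k$ distribution. The raw natural-scale variant is
  available (`re_scale = "additive"`); the data generator uses the
  natural-scale version with resampling at the domain boundary, so
  fitted and generating scales are not numerically identical — recovery
  is assessed on the centers, which both parameterizations share.
* **Non-centering.** Both the latent means ($M_j = f_1 + \sigma_2 t_j$,
  $t_j \sim N(0,1)$) and the random effects are non-centered, which is
  what makes the posterior geometry tractable for HMC at small $K$.

## Priors

No uniform priors are used anywhere (uniform priors on benchmark-dose
parameters are a known source of bias in the derived point of
departure). Dose-response locations get normal priors centered on
data-derived anchors — $a_k$ at the chemical's control log mean, $b_k$
at its observed maximum change, $c_k$ at its median positive dose — with
generous SDs; positives ($c_k$, $g$, all $\sigma$) are sampled on the
log scale with the appropriate Jacobians; scales carry half-Cauchy
priors. In the flat model $v, q \sim \mathrm{Beta}(2,2)$; in the
hierarchical model $\mu_v, \mu_q \sim N(0.5, 0.25)$ on the probability
scale, $\mu_h \sim N(0,2)$, $r \sim N(0,2)$, and the $(v,q)$
random-effect correlation has an LKJ(2) prior. The half-Cauchy scale for
$\sigma_v, \sigma_q, \sigma_h$ defaults to 0.5 rather than 1: these SDs
act on the logit scale, and prior-predictive simulation
(`prior_predictive()`) shows that scale-1 half-Cauchys concentrate the
implied $q_k$ at the domain edges, exactly the "excessive concentration
in a subregion" that the iterative prior-predictive screening procedure
is meant to weed out. All hyperparameters are overridable through
`qaop_priors()`.

## Sampling and diagnostics

No Stan-class sampler is assumed to be installed; the package ships its
own gradient-based No-U-Turn HMC sampler (C++): analytic gradients of
the full joint density, dual-averaging step-size adaptation (target
acceptance 0.8), windowed diagonal mass-matrix estimation, slice-type
multinomial trajectory sampling with a divergence threshold of
$\Delta H > 1000$, maximum tree depth 10. Gradients are verified against
central finite differences in the test suite, and the sampler against
analytically known posteriors (prior-only runs). Seeded runs are
bit-reproducible.

The default schedule (4 chains, 1,000 warmup, 2,000 sampling draws per
chain) is a desk-scale reduction; `mcmc_config(full = TRUE)` gives the
full-length 10,000/50,000 schedule. Convergence gates: split R-hat
below 1.01 ("close to 1") and ESS above 400 for every sampled
parameter. A fit failing the gates is returned with `pass = FALSE` and
a warning — never silently. Divergence counts are reported alongside
but are not part of the gate; a small residual divergence fraction
(typically below 1%, from the random-effect-scale funnel) is normal at
desk scale and shrinks with higher `adapt_delta`. In the simulation
study driver, a fit missing the R-hat gate is retried once with doubled
warmup and a tighter step-size target; iterations still failing after
the retry are excluded from aggregates (they indicate invalid
exploration) while ESS shortfalls are recorded but kept, since at
reduced draw counts they affect precision rather than validity. At the
large heterogeneity level a fraction of *flat* fits fail persistently —
the flat model is badly misspecified there and its posterior can be
multimodal — which is itself a symptom of the heterogeneity the
comparison is designed to expose.

## Model comparison

Predictive performance is summarized by the expected log predictive
density, approximated two ways from the draws-by-observations pointwise
log-likelihood matrix: PSIS-LOO (importance ratios Pareto-smoothed over
a tail of length $\min(0.2S, 3\sqrt{S})$, truncated at the raw maximum,
with per-observation shape diagnostics flagged above $k = 0.7$) and
WAIC (variance penalty, sample-variance convention). The implementation
follows the standard published recipe and matches an independent
reference implementation to ~1e-6 on random matrices (frozen in the
test suite). The observation unit is one dose-group record with its
upstream and downstream contributions summed — the qAOP's likelihood is
the sum of the two — with a split-unit mode available.

Because every dose group carries its own latent $t_j$, leave-one-out
ratios are often heavy-tailed here (many Pareto $k$ above 0.7). The
comparison that matters — hierarchical minus flat on identical data —
subtracts pointwise contributions with the same latent structure, and
WAIC is computed alongside as a robustness check; both are reported.
Positive differences support the hierarchical model.

## Heterogeneity as Cohen's f

Cross-chemical heterogeneity is quantified as Cohen's
$f = \sqrt{SSB/SSW}$ with $SSB = \sum_k n_k(\mu_k - \hat\mu)^2$ over
chemicals and $SST = \sum_i (y_i - \hat\mu)^2$ over *individual*
downstream outcomes. Two choices deserve explanation:

* **Observation unit.** The downstream responses enter at the subject
  level (each group contributes `ke_down_n` 0/1 outcomes through its
  sufficient statistics), so binomial within-group variability sits in
  the denominator. This is what makes the conventional "no
  heterogeneity" value $f \approx 0.05$ attainable: the null expectation
  of the sample statistic is about $\sqrt{(K-1)/N}$, and with group-level
  proportions instead of subjects $f$ would sit near 0.3-0.8 under a
  shared curve at desk-scale designs.
* **Trend adjustment.** The ratio is meant to compare KE_down variation
  *across* chemicals to variation *along KE_up* within chemicals, so the
  default removes a global isotonic trend of incidence on the log
  upstream group mean before grouping (`adjust = "ke_up"`). Adjusting on
  log-dose is available (`adjust = "dose"`), but since dose-response
  parameters are chemical-specific by design, a dose trend cannot
  isolate response-response heterogeneity: at zero response-response
  random effects the dose-adjusted statistic still reads ~0.8 on the
  default generator, while the KE_up-adjusted statistic reads ~0.045.

Levels follow the conventional thresholds (none < 0.1 ≤ small < 0.2 ≤
medium < 0.4 ≤ large), with boundary values classified into the upper
level. The generator's tuner targets the achieved values 0.05 / 0.1 /
0.2 / 0.5.

## The synthetic world

`sim_config()` states the generative world once: K = 6 chemicals with
G = 5 dose groups (a control plus log-spaced doses over 5-500
internal-dose units), 10 subjects per upstream group and 50 per
downstream group. Chemical dose-response curves draw
$a_k \sim N(0, 0.25)$, $b_k \sim N(2.2, 0.3)$,
$c_k \sim \mathrm{logN}(\log 50, 0.4)$ around shared $g = 1.5$,
$\sigma_1 = 0.4$, $\sigma_2 = 0.1$ — log upstream responses spanning
roughly 0-2.5, i.e. BrdU-like percentages of about 1-12 with a ~40%
within-group CV, matching the case study's reported low/medium/high
ranges. Response-response centers are $\mu_v = 0.6$, $\mu_q = 0.05$
(background incidence $\approx 3\%$), $\mu_h = 1.2$, $r = 2$; base
random-effect SDs (0.12, 0.03, 0.45, correlation 0.3) are multiplied by
a common tuned factor to reach each target effect size —
`tune_heterogeneity()` bisects that factor using common random numbers,
which makes the mean achieved f monotone in it. Upstream summaries are
always computed from actually generated individuals.

What the generator does *not* emulate: study-to-study assay
differences, dose-group imbalance beyond the fixture's 3-6 groups,
non-lognormal measurement error, and background-incidence adjustment
artifacts. A green simulation test therefore establishes that the
machinery separates response-response heterogeneity from pathway
effects *in this stated world*, not that it reproduces any particular
laboratory dataset. The packaged "case-study-like" fixture emulates the
*structure* of the liver-proliferation case study (10 chemicals across
11 study clusters, one chemical duplicated across two studies and kept
as two clusters, effect size tuned to ~0.17); its values are synthetic
throughout, as its filename and sidecar metadata state.

## Benchmark levels

Points of departure are derived on the upstream scale (benchmark
*levels*): for extra risk $BMR = (f_2(L) - f_2(0))/(1 - f_2(0))$ with
background $f_2(0) = vq$, the closed-form inversion is
$L = \exp(h + \log\frac{p^*-vq}{v-p^*}/r)$ with
$p^* = vq + BMR(1-vq)$, verified against root-finding to 1e-10. The
default BMR is 0.05 (5% extra incidence). Applied per posterior draw —
flat $(v,q,h,r)$, hierarchical chemical-agnostic centers
$(\mu_v,\mu_q,\mu_h,r)$, or a chosen chemical's $(v_k,q_k,h_k,r)$ — it
yields a BML distribution summarized as BML (posterior mean by default;
the central-estimate convention is configurable to the median), BMLL
and BMLU (5th/95th percentiles by default, the one-sided 95% lower-bound
convention; 2.5/97.5 configurable), on the natural and log scales. Draws
where the BMR exceeds the curve's headroom are dropped with a warning
above 1% and an error above 50%. The BML/BMLL ratio is reported on both
scales and `reliability_check()` applies the 1-3 empirical-reliability
band to the natural-scale ratio; lower ratios indicate better
characterized uncertainty.

## Degenerate inputs and tie-breaks

* Groups with `ke_up_sd = 0` and `n > 1` are rejected at validation, not
  silently regularized.
* The binomial coefficient is omitted from the downstream likelihood (it
  is constant in the parameters and cancels in all comparisons).
* A pinned probability (0 or 1) contradicting observed counts yields
  `-Inf` with a warning, never `NaN`; inside the sampler probabilities
  are clamped at 1e-12 from the boundaries.
* The constant-CV test needs at least three informative groups;
  otherwise it returns "untestable" and defaults to constant CV with a
  warning. Its adequacy p-values use Bartlett-corrected homogeneity
  statistics (the raw LR is anticonservative at n ≈ 20), with an extra
  inflation term for the CV variant because scaling by the *sample*
  mean adds about $2\,\mathrm{cv}^2$ relative variance per group. When
  both restricted variance models are adequate, the one with the higher
  likelihood wins; when neither is, the free-per-group structure is
  used. A selected constant natural-scale SD conflicts with the
  lognormal measurement model and falls back to free-per-group
  `sigma1` with a warning.
* Heterogeneity tuning with an unattainable target (e.g. below the
  baseline sampling noise of the statistic) fails loudly with its search
  trace.

## Known limitations

* The sampler is a desk-scale NUTS; at the full 10,000/50,000 schedule
  it is CPU-minutes per fit, not seconds.
* Pareto-k diagnostics flag many observations in these latent-variable
  models; LOO differences are still informative (and WAIC agrees in the
  simulation study), but absolute elpd values should not be
  over-interpreted.
* With K = 6 chemicals the random-effect scales are weakly identified;
  their posteriors lean on the priors, which is why the prior-predictive
  screening above matters.
* The case-study fixture is a synthetic stand-in: quantitative targets
  tied to the real supplementary data (empirical f, case-study LOO/WAIC
  differences, Table-style BML values) cannot be reproduced or asserted
  from this package alone.

## A worked run

```{r example, eval = FALSE}
ds <- make_fixture("medium", seed = 1)
cohens_f(ds)
cv <- constant_cv_test(ds)
flat <- fit_qaop(build_qaop_model(ds, "flat", variance = cv))
hier <- fit_qaop(build_qaop_model(ds, "hierarchical", variance = cv))
compare_models(flat, hier)
posterior_bml(hier, bmr = bmr_spec(0.05))
```
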