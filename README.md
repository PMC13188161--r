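# qaopcal

Hierarchical Bayesian calibration of chemical-agnostic quantitative
Adverse Outcome Pathways (qAOPs) on summarized multi-chemical
toxicology data.

## The problem

A qAOP chains a dose to a continuous upstream key event (KE_up, e.g.
% BrdU-positive hepatocytes) and onward to a dichotomous downstream key
event (KE_down, e.g. liver tumor incidence). To be *chemical-agnostic*
— usable for chemicals beyond those it was calibrated on — the
response–response relationship between the key events must not be
confounded by cross-chemical heterogeneity. Pooling multi-chemical data
into a single ("flat") response–response curve does exactly that
confounding when heterogeneity is substantial.

`qaopcal` is for toxicologists and risk assessors who calibrate qAOPs
on summarized dose-group data (per chemical $k$ and group $j$: dose
$d_j$; KE_up mean/SD/size $m_{Yj}, s_{Yj}, n_{1j}$; KE_down cases/size
$X_j, n_{2j}$). It fits, by built-in NUTS MCMC, two models sharing an
identical dose-response block (continuous Hill
$f_1(d) = a + b d^g/(c^g+d^g)$, lognormal measurement with latent group
means $M_j$, summarized-data likelihood through sufficient statistics):

* a **flat** model — one dichotomous-Hill response–response curve
  $f_2(M) = v (q + e^{r(M-h)})/(1 + e^{r(M-h)})$ shared by all
  chemicals, and
* a **hierarchical** model — chemical-specific $v_k, q_k, h_k$
  decomposed into chemical-agnostic centers $\mu_v, \mu_q, \mu_h$,
  chemical-agnostic scales $\sigma_v, \sigma_q, \sigma_h$ and correlated
  chemical-specific deviations $z_k$ (random effects), with the power
  $r$ chemical-agnostic.

The two fits are compared by PSIS-LOO and WAIC (positive
hierarchical-minus-flat differences support the hierarchical model);
cross-chemical heterogeneity is quantified as Cohen's
$f = \sqrt{SSB/SSW}$ on dose-trend-adjusted downstream outcomes; and
points of departure are derived as upstream benchmark levels: the BML
solves the extra-risk equation $BMR = (f_2(L) - f_2(0))/(1 - f_2(0))$
per posterior draw, summarized as BML / BMLL / BMLU with the BML/BMLL
reliability ratio (empirically reliable within 1–3). A simulator
generates multi-chemical datasets at tuned heterogeneity levels
(targets f = 0.05, 0.1, 0.2, 0.5) and drives the full
generate–fit–compare study.

## Worked example

```r
library(qaopcal)

ds <- make_fixture("medium", seed = 1)      # synthetic, K = 6 chemicals
cohens_f(ds)
#> Cohen's f = 0.2570 (f^2 = 0.0661), level: medium [ke_up-adjusted]
#> SSB = 13.75, SSW = 208.2, SST = 222 over 6 chemicals

cv   <- constant_cv_test(ds)                # -> constant CV upheld
flat <- fit_qaop(build_qaop_model(ds, "flat", variance = cv))
hier <- fit_qaop(build_qaop_model(ds, "hierarchical", variance = cv))

compare_models(flat, hier)
#> Flat vs hierarchical predictive performance (positive diff favors hierarchical):
#>  method elpd_flat elpd_hierarchical  diff diff_se    preferred
#>     loo    -884.8            -830.8 54.06   18.32 hierarchical
#>    waic    -878.1            -823.2 54.94   18.33 hierarchical

posterior_bml(hier, bmr = bmr_spec(0.05))   # 5% extra risk
#> Benchmark level at BMR = 0.05 (extra risk), hierarchical model
#>            BML    BMLL   BMLU   ratio
#> natural 1.8971  0.9278 2.8282  2.0448
#> log     0.5838 -0.0750 1.0396 -7.7863
```

Read: at medium heterogeneity (f ≈ 0.26) the hierarchical model is
clearly favored by both metrics (LOO difference +54 ± 18), and the
chemical-agnostic benchmark level for a 5% extra downstream incidence
is about 1.90 on the natural upstream scale (90% interval 0.93–2.83,
BML/BMLL ratio 2.04, inside the 1–3 empirical-reliability band; the
log-scale ratio is unstable when the log-BMLL sits near zero and is
reported for completeness).
Fitted objects have `tidy()`/`glance()` methods and `autoplot()`
displays; `validate_qaop_data()` documents the CSV schema, and a thin
CLI (`inst/exec/qaopcal`) exposes `fit`, `compare`, `simulate`, `tune`,
`bml`, `hetero` and `fixture` subcommands.

The methods vignette (`vignettes/qaop-calibration.Rmd`) documents the
model, priors, sampler, numerical choices and the limits of what the
synthetic world establishes.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the simulation-study proportions from scratch: for each
heterogeneity level (large, none, medium) it tunes the generator to the
level's target Cohen's f, generates 20 multi-chemical datasets, fits
the flat and hierarchical models by MCMC (4 chains, 1k/2k reduced
schedule), compares them by PSIS-LOO, and writes the percentage of
iterations favoring the hierarchical model per level to the JSON file
given by `--out`.
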