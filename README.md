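# pcbias

Agent-based calibration of how strongly people rely on **pseudocontingencies**
— relationships inferred from the separate base rates of two variables —
versus **actual contingencies** — their co-occurrence structure — when forming
beliefs. The implemented case is the belief that unhealthy food tastes
better, which skewed food environments can induce even when the true
health-taste association is zero or opposite.

## The model

An agent sequentially observes foods, tallying a 2x2 table per context of
two binary attributes, healthy (H/U) and tasty (T/N). From the current
context's table it computes base rates `p_H, p_T`, their skews
`d_H = p_H - 0.5`, `d_T = p_T - 0.5`, the pseudocontingency effect

    psi = 4 * d_H * d_T            (in [-1, 1])

and the actual contingency, the phi coefficient

    phi = (HT*UN - HN*UT) / sqrt((HT+HN)(UT+UN)(HT+UT)(HN+UN)),

equal to the Pearson correlation of the 0/1-coded attributes. The momentary
belief is the bias-weighted blend

    phi_hat = (1 - beta) * phi + beta * psi,

with bias strength `beta` (0 = pure contingency use, 1 = pure base-rate
use), folded into a running belief by exponential smoothing with learning
rate `alpha`. The package

* builds the skewed two-context calibration design (per-context
  `phi = -1/3 / +1/3 / 0` for the healthy / unhealthy / balanced
  conditions, with opposing base-rate skews) and an independent
  zero-contingency validation design;
* simulates agents, populations, and phase-space vector fields;
* generates synthetic cohorts with known ground-truth `beta_i` and
  reporting noise;
* calibrates `beta` at group level (distribution matching by
  quantile-paired MAE + Kolmogorov-Smirnov, grid 0..1 by 0.01) and at
  individual level (one `beta_i` per participant), with percentile
  bootstrap confidence intervals;
* fits a four-parameter cell-weighting integration model for comparison;
* cross-validates calibrated parameters on the validation design.

## Worked example

```r
library(pcbias)
report <- run_pipeline("results", seed = 2026)
print(report$calibration, digits = 3)
#>   condition      level  n estimate    mae    ks sd_emp sd_sim sd_ratio
#> 1   healthy      group 52    0.770 0.1284 0.394 0.1887 0.0252     7.48
#> 2 unhealthy      group 52    0.750 0.1268 0.385 0.1882 0.0244     7.72
#> 3  balanced      group 52    0.000 0.0186 0.138 0.0803 0.0566     1.42
#> 4   healthy individual 52    0.780 0.0122 0.154 0.1887 0.1743     1.08
#> 5 unhealthy individual 52    0.745 0.0152 0.192 0.1882 0.1686     1.12
#> 6  balanced individual 52    0.000 0.0610 0.519 0.0803 0.0028    28.71
```

Reading the table: on a synthetic cohort of 52 participants per condition,
the group-level fit finds strong reliance on pseudocontingencies in both
skewed conditions (`beta` around 0.75–0.77) and none in the balanced
control, but its simulated belief distribution is far too narrow (SD ratio
about 7): a single bias strength cannot reproduce the spread of reported
beliefs. Individual-level calibration recovers that spread almost exactly
(SD ratio about 1.1). The bundle written to `results/` also contains the
bootstrap intervals (`bootstrap.csv`), the group-vs-individual reduction
summary (`reduction.csv`), the integration-model comparison
(`comparison.csv`) and the cross-experiment validation metrics
(`validation.csv`), where sampling from the individual-level `beta_i` pool
again captures belief variability that the single group parameter cannot
(validation SD ratio 1.6–1.8 versus 7–8 in the skewed conditions).

Single pieces are available directly:

```r
env <- calibration_environment("healthy", seed = 1)
sapply(env$contexts, phi_coef)        # -0.333 -0.333
simulate_agent(env, beta = 1, alpha = 0.5)$final_belief

cohort <- generate_cohort(cohort_config(seed = 1))
fit <- fit_bias(cohort, "individual")
summary(fit); confint(fit); plot(fit)
```

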