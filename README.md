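# delmi

Strategies for handling missing daily assessments when a **summary
exposure** is regressed on a long-term outcome.

## The problem

In critical-care cohorts, delirium is assessed daily as a yes/no status, and
the exposure of scientific interest is often the *summary* of those
assessments — delirium duration, the number of delirious days during the ICU
stay. The analysis model is an unadjusted linear regression

```
outcome_i = alpha + beta_del * duration_i + eps_i,   eps_i ~ N(0, sigma^2)
```

A single missing daily assessment leaves `duration_i` undefined, so even low
assessment-level missingness knocks out many participants. Analysts respond
in one of five ways, all implemented here behind one fitting function:

| strategy | what it does |
|---|---|
| `complete_case` | drop every participant with any missing day |
| `adhoc_worst` / `adhoc_best` | substitute missing days with delirium present / absent |
| `passive_mi` | impute the *daily* statuses B times (logistic model on daily SOFA + outcome), recompute the duration per completed dataset, pool with Rubin's rules |
| `active_mi` | impute the *duration itself* B times (Bayesian normal linear model on mean SOFA + outcome), ignoring the observed days of affected participants |

Rubin's rules pool B imputation-specific estimates as
`q_bar = mean(beta_b)`, `T = W + (1 + 1/B) * B_var`, with
`W = mean(se_b^2)`, `B_var = var(beta_b)`, and degrees of freedom
`(B - 1)(1 + W / ((1 + 1/B) B_var))^2`.

The package also generates synthetic participant-day cohorts (two-state
Markov daily delirium, correlated integer SOFA scores, variable lengths of
stay), imposes MCAR / MAR / MNAR missingness at a calibrated target
proportion (logistic mechanisms `logit(missing) = alpha + beta * SOFA` or
`... + beta * delirium`, with the intercept solved so the expected missing
fraction hits the target), and evaluates every strategy on a scenario grid —
4 proportions x (MCAR + 3 MAR strengths + 3 MNAR strengths) x 5 strategies =
140 cells — reporting bias, mean standard error, and coverage of the nominal
95% confidence interval per cell.

## Worked example

```r
library(delmi)

base <- generate_base_cohort(base_cohort_params(), seed = 11)
summarize_base(base)
#> Cohort: 1000 participants, 6869 participant-days (mean LOS 6.87)
#> Delirium prevalence: 0.385 of days; mean duration 2.65 days
#> Duration quantiles: 0%=0 25%=1 50%=2 75%=4 100%=18
#> Mean SOFA: 7.94 (delirium days) vs 5.90 (non-delirium days)

coh  <- generate_outcome(cluster_resample(base, 200, seed = 2), seed = 3)
spec <- calibrate_alpha(missingness_spec("MAR", 0.2, strength = 0.2), coh)
coh  <- impose_missingness(coh, spec, seed = 4)

fit_strategy(coh, "passive_mi", B = 10, seed = 7)
#> <strategy_fit> passive_mi
#>   duration slope -1.5060 (SE 0.3418, df 1473.9, n = 200, B = 10)
```

The printed slope estimates the association between delirium duration and
the outcome in this one masked dataset (generating value -1; the single-
replicate estimate varies by its standard error). `complete_case` on the
same data keeps only the 70 fully assessed participants and pays for it with
SE 0.86; the Monte-Carlo machinery quantifies those differences over many
replicates:

```r
res <- run_grid(n_replicates = 200, seed = 1, verbose = TRUE)  # 140 cells
plot_grid_results(res, "coverage")
```

A thin command-line front end (`inst/scripts/delmi`) exposes
`generate-base`, `simulate` (YAML config), `apply` (five strategies on a
user-supplied participant-day CSV), and `report`.

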