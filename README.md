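# coexhub

Statistical toolkit for gene co-expression analysis of two-class expression
experiments (stress vs. control), aimed at researchers analyzing normalized
log2 microarray or expression panels who want significance-based answers to
three questions the usual heuristics answer by eye:

1. **Which genes are informative for the condition?** Genes are ranked by
   linear SVM recursive feature elimination (SVM-RFE) inside bootstrap
   resamples; rank *p* becomes a rank score `R = (N + 1 − p)/N`, and each
   gene's scores are tested against the uninformative-gene median
   `Q = (N + 1)/(2N)` with a one-sided signed-rank statistic `T⁺` using its
   null moments `E(T⁺) = n(n+1)/4`, `Var(T⁺) = n(n+1)(2n+1)/24` and a
   normal approximation. Genes are selected when `−log₁₀ p ≥ 2.5`
   (bootstrap test) **and** `−log₁₀ p ≥ 4` (Welch t-test).
2. **Which genes are hubs in the co-expression network?** The network uses
   similarity `s_ij = |cor(x_i, x_j)|` and adjacency `a_ij = s_ij^β`, with β
   chosen by the scale-free criterion (log–log fit of the connectivity
   distribution, R² ≥ 0.80/0.85 with negative slope). A gene's weighted
   gene score `WGS_i = Σ_{j≠i} a_ij` is recomputed on S random subsamples
   of the arrays and tested against the full network's mean connectivity μ
   with the same signed-rank statistic (`W⁺`); two conditions are crossed
   into housekeeping hubs, condition-unique hubs and non-hubs
   (differential hub gene analysis, DHGA).
3. **How do modules interact over time?** Module mean-expression series
   are spline-interpolated to a uniform grid (canonically 50 points over
   0–72 h) and each module is regressed on all others at the previous time
   step, `M_d(t) = β₀ + Σ_{h≠d} β_h M_h(t−1) + ε`, with BIC-weighted
   Bayesian model averaging; directed edges keep posterior inclusion
   probability ≥ 0.2.

Synthetic-data generators with planted ground truth (informative genes,
module memberships, hub genes, lagged edges) make every stage testable
offline. See the methods vignette
(`vignettes/coexpression-hub-analysis.Rmd`) for the models, assumptions,
parameter choices, and known limitations — including an honest account of
what the resampling p-values do and do not guarantee.

## Worked example

```r
library(coexhub)

# 60 genes, 10 samples per class, 8 genes shifted by 2 SD under stress
sim <- simulate_two_class(60, 10, 8, effect = 2, seed = 1)
fit <- boot_svmrfe(sim$expr, n_boot = 30, seed = 1)
print(fit)
#> Bootstrap SVM-RFE gene selection
#>   genes: 60   bootstraps: 30
#>   selected: 3 (thresholds -log10 p >= 2.5 and 4)
```

The eight planted genes occupy the top of the ranking (all reach the
minimal attainable bootstrap p of `8.67e-07` at 30 bootstraps — the test
saturates when a gene out-ranks the median in every resample); the final
selection additionally requires the t-test axis, which at this small sample
size keeps only three genes:

```r
summary(fit)
#> Top genes by bootstrap p-value:
#>  gene_id mean_rank_score t_plus        z      p_value selected
#>    g0001       0.9094444  465.0 4.782139 8.671988e-07    FALSE
#>    g0005       0.9638889  465.0 4.782139 8.671988e-07     TRUE
#>    ...
```

Network, hubs, and module interactions:

```r
mod <- simulate_modular(100, 50, rep(20, 4), seed = 2)   # 4 planted modules
pick_soft_threshold(mod$expr, 1:8, r2_cut = 0.8)$beta
#> [1] 7

sub <- subsample_wgs(mod$expr, beta = 7, S = 200, seed = 3)
hubs <- hub_significance(sub)          # per-gene connectivity p-values

edges <- data.frame(regulator = c(1, 2), target = c(3, 4), coefficient = 0.8)
ss <- simulate_module_series(6, 40, edges, noise_sd = 0.2, seed = 4)
fit_min(ss$series, n_points = NULL)
#> Module interaction network: 6 modules, 2 edges at posterior >= 0.2
#>  regulator target posterior coefficient
#>       mod2   mod4     1.000       0.579
#>       mod1   mod3     0.898       0.433
```

Both planted lagged edges are recovered with no false positives; the
posterior column is the total model-averaging weight of regressions that
include the regulator.

A thin command-line front end wrapping these functions ships in
`inst/cli/coexhub.R` (subcommands `simulate`, `select`, `network`, `dhga`,
`min`; every stochastic command requires `--seed` and writes a manifest of
its parameters).

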