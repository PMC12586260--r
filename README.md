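# pfcrosslink

Validation tooling for IRT-based score linking between the ten-item SF-36
physical function scale (PF-10) and the PROMIS physical function T-score
metric.

## The problem

Physical function is measured by many instruments whose scores live on
incompatible scales. The PROMIS initiative defines a common reporting
metric — the T-score, with reference-population mean 50 and SD 10 — and
item response theory (IRT) makes it possible to *link* a legacy
instrument such as the SF-36 PF-10 onto that metric. Three linking
approaches are in practical use:

1. **Item-level linking** — score PF-10 response patterns directly with
   the item parameters from the original joint calibration;
2. **Cross-walk tables** — a raw-summed-score → T-score lookup table,
   usable without psychometric software;
3. **IRT re-estimation** — re-estimate the PF-10 item parameters in the
   target sample by fixed-parameter calibration, holding a 20-item
   anchor short form (and the latent N(0,1) density) fixed to the
   reference metric.

This package implements all three, the assumption checks that justify
unidimensional linking (polychoric one-factor fit, exploratory bifactor
ECV / omega-hierarchical, DIF screening by ordinal regression with the
Nagelkerke ΔR² > 0.03 rule), and the agreement statistics used to judge
them (Pearson *r*, mean differences, MAE/RMSE with bootstrap CIs, paired
pooled-SD standardized mean differences, Bland–Altman limits of
agreement). Because patient-level data of this kind are rarely shareable,
a synthetic-data module generates study-like clinical samples with known
latent truth — including the contamination processes (wholly missing
questionnaires, reversed-coding responders) behind a realistic exclusion
screen — so the whole pipeline can be exercised end to end.

## The model

Items follow the graded response model in slope–threshold form: for item
*i* with ordered categories k = 1..K and latent trait θ,

    P(X_i >= k | θ) = logistic(a_i (θ − b_{i,k−1})),   b_{i,1} < … < b_{i,K−1}

(pure logistic metric, no 1.7 constant). Person scores are expected a
posteriori (EAP) estimates by quadrature against a standard-normal prior,
reported as T = 50 + 10·θ. Cross-walk tables come from the
Lord–Wingersky recursion: the summed-score likelihoods L(s | θ) give a
posterior mean and SD of θ per raw score. Re-estimation is
marginal-maximum-likelihood EM with the anchor parameters fixed.

## Worked example

```r
library(pfcrosslink)

cfg   <- synthetic_config()               # study-shaped defaults
banks <- make_item_banks(cfg, seed = 1)
ds    <- simulate_sample(banks, cfg, seed = 2)
ds    <- contaminate(ds, seed = 3)        # reversed + missing responders
scr   <- screen_exclusions(ds, banks)
scr$log
#>               reason  n
#> 1 missing_instrument  5
#> 2    reversed_coding 40

rep <- run_validation(list(seed = 1, bootstrap = list(B = 200),
                           check_assumptions = FALSE))
rep
#> <validation report: n=574 analytic (of 619), 3 linking methods>
#>   IRT re-estimation    r=0.92 MD=-0.85 (SD 3.65)
#>   item-level linking   r=0.91 MD=-0.65 (SD 3.62)
#>   cross-walk table     r=0.91 MD=-0.70 (SD 3.70)
```

All three linking approaches correlate at r ≈ 0.91–0.92 with the 20-item
benchmark and differ from it by under one T-score point on average — the
kind of group-level agreement (|SMD| < 0.2) under which linked scores are
considered interchangeable with observed ones. The crosswalk itself is an
ordinary lookup table:

```r
round(as.data.frame(build_crosswalk(banks$linked))[1:4, ], 2)
#>    raw_score theta theta_se t_score t_se
#> 10        10 -3.26     0.44   17.35 4.38
#> 11        11 -2.91     0.38   20.91 3.83
#> 12        12 -2.63     0.35   23.66 3.53
#> 13        13 -2.40     0.33   25.96 3.33
```

`run_validation()` also writes, when given `out_dir`, the report files
(`table2.json`, `table3.csv`–`table5.csv`, `bland_altman.csv`,
`run_log.json`) and `derive_summary_checks()` verifies the internal
consistency of any report (RMSE/MD/SD identity, SMD recomputation,
crosswalk monotonicity, sample bookkeeping).

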