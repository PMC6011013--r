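# screennet

Screening-network penalized Cox models for survival prediction from
high-dimensional omics data.

## What it does, and for whom

Cancer cohorts routinely measure tens of thousands of gene features on a few
hundred patients with censored survival outcomes. `screennet` is for
biostatisticians and computational biologists who want to extract a small,
network-coherent prognostic gene signature from such data and validate it
honestly on held-out patients. The workflow is two-stage:

1. **Screening** reduces the feature space to a moderate set of candidates —
   by external biomedical evidence (genes with disease-association p-value
   ≤ 0.05; *BMD*), by marginal Cox coefficients (sure-independence
   screening on $|\hat\beta^M_k|$, default size $\lfloor n\log n\rfloor$;
   *DAD*), or by their union (*BMD+DAD*).
2. **Network-penalized Cox regression** on the screened genes minimizes

   $$-\ell(\beta) \;+\; \lambda\big[\alpha\|\beta\|_1 +
   (1-\alpha)\,\Phi(\beta)\big],$$

   where $\ell$ is the Breslow-form Cox log partial likelihood and $\Phi$
   couples coefficients along a weighted gene network $G=(V,E,W)$,
   $w_{ij}\in[0,1]$. Two estimators are provided: an **adaptive signed
   Laplacian** penalty
   $\Phi(\beta)=\sum_{(i,j)\in E} w_{ij}\big(\mathrm{sgn}(\tilde\beta_i)
   \beta_i/\sqrt{d_i}-\mathrm{sgn}(\tilde\beta_j)\beta_j/\sqrt{d_j}\big)^2$
   solved by coordinate descent, and a **quadratic Laplacian** penalty
   $\Phi(\beta)=\beta^\top L\beta$ solved by ADMM, with $L$ the normalized
   Laplacian and $d_i$ the weighted degree.

λ is tuned by 5-fold cross-validated partial likelihood (van Houwelingen
form), repeated with reshuffled folds and averaged, at fixed α = 0.5. The
fitted signature yields a prognostic index $PI_i = x_i^\top\hat\beta$
(standardized scale); an adaptive quantile scan over
γ ∈ {0.20, 0.25, …, 0.80} picks the training cutoff with the best log-rank
separation, and the frozen rule is evaluated on a held-out cohort by the
two-group log-rank test. A pathway co-membership report annotates the
signature. A seeded synthetic-cohort generator with planted signals makes
the whole pipeline testable end to end without controlled-access data.

## Worked example

Simulate a 600-patient cohort (200 genes in correlated modules, five causal
genes with unit effects, 30% censoring), split it in half, and run the full
pipeline — union screening, adaptive-Laplacian fit, cross-validated λ,
adaptive cutoff, held-out validation:

```r
library(screennet)

sim <- simulate_dataset(sim_config(n = 600, p = 200, seed = 7))
train <- list(expression = sim$expression[1:300, ],
              survival   = sim$survival[1:300, ])
test  <- list(expression = sim$expression[301:600, ],
              survival   = sim$survival[301:600, ])

run <- run_pipeline(train, test, sim$network, sim$association, sim$pathways,
                    mode = "union", method = "adalnet", d_dad = 50,
                    cv = cv_settings(k = 5, repeats = 3), seed = 7)
#> [pipeline] stage=input train=300x200 test=300x200 mode=union method=adalnet seed=7
#> [pipeline] stage=bmd_screen d_bmd=3 alpha_cut=0.05
#> [pipeline] stage=screen d_dad=50 kind=BMD+DAD d=50
#> [pipeline] stage=tune lambda_hat=8.3477 (mean 8.1227 over 3 repeats)
#> [pipeline] stage=fit method=adalnet n_signature=31 objective=919.347
#> [pipeline] stage=cutoff gamma_star=0.70 pi_star=1.1366 train_p=1.81e-69
#> [pipeline] stage=validate evaluable=TRUE test_p=3.93e-52

tidy(run)
#> # A tibble: 1 × 10
#>   d_dad kind    d_screened lambda_hat n_signature gamma_star pi_star  train_p
#>   <int> <chr>        <int>      <dbl>       <int>      <dbl>   <dbl>    <dbl>
#> 1    50 BMD+DAD         50       8.35          31        0.7    1.14 1.81e-69
#> # ℹ 2 more variables: test_p <dbl>, evaluable <lgl>
```

Reading the log: BMD screening found 3 externally annotated genes, the
union with the top-50 marginal genes gave 50 candidates; cross-validation
picked λ ≈ 8.35; the penalized fit kept a 31-gene signature; the best
training split was at the 70% PI quantile; and on the untouched test half
the high/low-risk split separates survival at log-rank p ≈ 4e-52. The
signature itself:

```r
head(tidy(run$runs[[1]]$fit, nonzero_only = TRUE))
#> # A tibble: 6 × 2
#>   gene    beta
#>   <chr>  <dbl>
#> 1 g0001 0.920
#> 2 g0031 0.682
#> 3 g0041 0.891
#> 4 g0011 0.912
#> 5 g0021 0.665
#> 6 g0016 0.0701
```

The five planted causal genes (`g0001`, `g0011`, `g0021`, `g0031`,
`g0041`) carry the largest coefficients. `autoplot()` methods cover KM
curves and CVPL surfaces; `plot_risk_groups()` draws the validated
high/low-risk curves; `write_sif()` / `write_graphml()` export the pathway
co-membership network. A thin command-line front end with `simulate`,
`screen`, `fit`, `tune`, `stratify`, `evaluate`, `report` and `run-all`
subcommands ships in `inst/cli/screennet.R`.

See the methods vignette (`vignettes/screening-network-cox.Rmd`) for the
model, its assumptions, tuning parameters and design decisions.

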