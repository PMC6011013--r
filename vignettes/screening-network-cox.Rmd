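---
title: "Screening-network penalized Cox models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening-network penalized Cox models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screennet)
```

## The problem

High-dimensional omics cohorts measure tens of thousands of genes on a few
hundred patients with censored survival outcomes. A Cox proportional-hazards
model over all genes is unidentifiable at that scale, and a plain lasso
ignores what is already known about how genes work together. `screennet`
implements a two-stage strategy: first *screen* the feature space down to a
moderate number of candidates, then fit a *network-penalized* Cox model on
the screened set, so that the sparsity pattern respects a weighted
gene-gene network. The fitted signature is turned into a deployable patient
risk rule and validated on held-out data.

## Data model

The observed data are triplets $(t_i, \delta_i, x_i)$: the follow-up time
$t_i = \min(T_i, C_i)$ in months, the event indicator
$\delta_i = I(T_i \le C_i)$ (1 = died of disease; living patients and
deaths from other causes are censored), and the gene-expression vector
$x_i$. Survival and censoring are assumed conditionally independent given
$x_i$, with noninformative censoring. Estimation works on the Cox log
partial likelihood

$$\ell(\beta) = \sum_{i:\delta_i=1}\Big[x_i^\top\beta -
\log\sum_{j \in R(t_i)} e^{x_j^\top\beta}\Big],$$

where $R(t)$ is the risk set just before $t$. Tied event times share one
risk-set log-sum (the Breslow convention) throughout the package — the
simplest choice consistent with the form of the likelihood above; the
Efron correction is deliberately out of scope.

## Stage one: screening

Three screens reduce $p$ genes to $d \ll p$ candidates:

* **Biomedical (BMD).** Keep genes whose external disease-association
  p-value is $\le 0.05$ (inclusive). No multiplicity correction is applied:
  the screen is a pre-selection, and variable selection proper happens in
  the penalized fit.
* **Data-driven (DAD).** For each gene compute the marginal Cox coefficient
  $\hat\beta^M_k$ (the univariate maximizer of $\ell$), rank by
  $|\hat\beta^M_k|$ and keep the top $d_{DAD}$; the customary default size
  is $\lfloor n \log n \rfloor$. Columns are standardized before ranking so
  magnitudes are comparable; ties at the cutoff are all kept (deterministic
  and order-independent); genes whose marginal likelihood is monotone
  (maximizer beyond $|\beta| = 15$ on standardized data, a hazard ratio far
  beyond biological plausibility) are flagged degenerate and ranked last.
* **Union (BMD+DAD).** The set union of the two, keeping marginal
  statistics where available — external knowledge is partial, and the two
  screens complement each other.

Selection by rank size is the primary interface; the magnitude of the last
kept gene (the implied threshold) is reported alongside.

## Stage two: network-penalized Cox regression

The gene network is a weighted undirected graph with weights
$w_{ij} \in [0,1]$; genes of the screened set not covered by the network
are completed with zero weights, i.e. enter as isolated vertices. With
weighted degrees $d_i = \sum_j w_{ij}$, the normalized Laplacian has unit
diagonal on connected vertices and $-w_{ij}/\sqrt{d_i d_j}$ on edges; rows
of isolated genes are zero. Both estimators minimize

$$-\ell(\beta) + \lambda\big[\alpha\|\beta\|_1 +
(1-\alpha)\,\Phi(\beta)\big],$$

and differ in the smoothness term $\Phi$ and the algorithm:

* **Adaptive signed Laplacian** (coordinate descent).
  $\Phi(\beta) = \sum_{(i,j)} w_{ij}\big(s_i\beta_i/\sqrt{d_i} -
  s_j\beta_j/\sqrt{d_j}\big)^2$ with $s_i = \mathrm{sgn}(\tilde\beta_i)$
  from a preliminary estimate (marginal coefficients by default, an
  $\ell_2$-penalized joint fit behind a flag; $\mathrm{sgn}(0) := +1$ so
  the penalty stays well defined). The sign flip tolerates neighbouring
  genes regulated in opposite directions; the degree scaling lets hub
  genes carry larger coefficients. Solved by iteratively reweighted least
  squares with cyclic coordinate descent (each update a closed-form soft
  threshold, inner loop in compiled code) and a step-halving guard that
  keeps the objective non-increasing.
* **Quadratic Laplacian** (ADMM). $\Phi(\beta) = \beta^\top L \beta$.
  Operator splitting with smooth part $-\ell(x) + \lambda(1-\alpha)x^\top
  Lx$, an $\ell_1$ part $\lambda\alpha\|z\|_1$ and constraint $x = z$: a
  damped-Newton x-update, a soft-threshold z-update, the dual step
  $y \leftarrow y + \rho(x - z)$, with residual balancing of $\rho$
  (factor 2 whenever one residual exceeds ten times the other), stopping
  tolerances $10^{-6}\sqrt{d}$ and a 5000-iteration cap. The returned
  coefficients are $z$, so zeros are exact.

One orientation note: the estimator is sometimes displayed as an argmin of
the log partial likelihood *plus* the penalty; that problem would be
unbounded, so the package minimizes $-\ell + P_{\lambda,\alpha}$, the
standard convention. Likewise the signed-Laplacian denominators are
$\sqrt{d_i}$, matching the normalized Laplacian's $-w_{ij}/\sqrt{d_id_j}$;
the two must agree for the quadratic-form identity
$\beta^\top L\beta = \sum_{(i,j)} w_{ij}(\beta_i/\sqrt{d_i} -
\beta_j/\sqrt{d_j})^2$ to hold. Whether the quadratic term should be
rescaled by edge count is left as stated: no rescaling. Columns are
centered and scaled internally; coefficients are reported on the
standardized scale, and prognostic indices always reuse the *training*
means and standard deviations, so risk ordering is unaffected and no
test-set information leaks into the rule.

`lambda_max` — the smallest $\lambda$ with an all-zero solution — is
$\max_j |\partial\ell/\partial\beta_j(0)|/\alpha$, since the quadratic
term has zero gradient at the origin. The regularization path uses 50
geometrically spaced values from $\lambda_{\max}$ down to
$0.01\,\lambda_{\max}$ with warm starts.

## Tuning by cross-validated partial likelihood

$\alpha$ is fixed at 0.5 (moderate network influence; a joint
$(\lambda,\alpha)$ search buys little and costs much). $\lambda$ maximizes
the van Houwelingen cross-validated partial likelihood

$$\mathrm{CVPL}(\lambda) = \frac{1}{n}\sum_{k=1}^{K}
\big[\ell(\hat\beta^{(-k)}) - \ell^{(-k)}(\hat\beta^{(-k)})\big],$$

with $K = 5$ folds, where $\ell$ is evaluated on all samples and
$\ell^{(-k)}$ on the data without fold $k$. Some write-ups print this
display with a leading minus while still describing maximization of the
cross-validated likelihood; this package keeps the to-be-maximized
orientation and says so here once. Fold assignment is event-stratified
(events dealt round-robin across folds, with a continuing offset so fold
sizes differ by at most one) to rule out event-free folds; plain
randomization sits behind a flag. The whole 5-fold procedure is repeated
(10 times by default) with reshuffled folds, the per-repeat maximizers are
averaged — a literal reading of "take the mean of this estimate" — and the
mean is snapped to the nearest grid point, where a warm-started fit
already exists. Path fits inside cross-validation run through the
coordinate-descent engine on the requested method's own objective (both
solvers target the same optimum; the final refit uses the requested
algorithm) with looser inner tolerances, since only the ranking of
$\lambda$ values matters there; the final fit is solved tightly.

## Risk stratification and validation

The signature is the set of genes with $\hat\beta \ne 0$. Each training
patient gets a prognostic index $PI_i = \sum_g \hat\beta_g (x_{ig} -
\bar x_g)/s_g$. A cutoff is chosen adaptively on training data only: for
$\gamma \in \{0.20, 0.25, \ldots, 0.80\}$ (13 levels), the
$\gamma$-quantile of the training PI (type-7, linear interpolation — the
convention matters at small $n$, so it is fixed and surfaced here) splits
patients into high risk (strictly above) and low risk, and the level with
the smallest two-group log-rank p-value wins; ties break toward the
smaller $\gamma$, i.e. the larger high-risk group. Held-out patients are
then scored with the *training* standardization, assigned by the *frozen*
cutoff, and compared by the log-rank test; the resulting p-value is the
performance measure (5% level). Kaplan-Meier curves and the log-rank
statistic are computed via the survival package, cross-checked in the test
suite against textbook product-limit and hypergeometric implementations.

Because the cutoff scan minimizes a p-value over 13 candidate splits, the
*training-set* p-value is optimistically biased by construction; the
held-out p-value is the honest quantity. The test suite verifies both
sides: with a fixed median split under a global null the test-set
rejection rate at the 5% level stays inside the exact binomial 95% band
over 200 replicates, while the adaptive scan is documented (not asserted)
as anti-conservative on training data.

## Synthetic cohorts

The generator produces the data the analysis assumes, with a planted
truth, so every stage is testable without controlled-access data:
expression rows are zero-mean unit-variance with equicorrelation
$\rho$ = 0.6 inside modules of 10 genes (one-factor construction) and
independence across modules; the network connects within-module pairs at
weight $\rho$; survival times follow
$T = -\log(U)/(h_0 e^{x^\top\beta^*})$ with constant baseline hazard
$h_0 = 0.1$ per month (the methods never use the shape of $h_0$, so the
exponential baseline is the simplest generator consistent with
proportional hazards); censoring is uniform on $(0, c_{\max})$,
independent of covariates (noninformative), with $c_{\max}$ calibrated by
Monte-Carlo root-finding to a target censoring fraction (default 30%, a
typical cohort value). The planted signal defaults to five causal genes
with $\beta^* = 1$ placed at the heads of five different modules, so the
signal is network-concordant. The association table marks 60% of causal
genes significant — biomedical knowledge is partial by design — covers 80%
of the remaining genes with null p-values, and leaves the rest uncovered;
each module carries one pathway id; copy-number codes are 5-bin
thresholded mixtures of the expression z-score and independent noise
(concordance 0.8). Identical configurations are bit-reproducible.

What the generator does *not* emulate: heavy-tailed expression,
platform/batch effects, long-range (LD-like) correlation, time-varying
effects, informative censoring, and realistic genomic coordinates.
Passing end-to-end tests therefore demonstrates the machinery and its
statistical calibration under the stated model, not performance on any
real cohort.

## Numerical choices and degenerate inputs

* Solver defaults: coordinate-descent outer/inner tolerances $10^{-11}$ /
  $10^{-10}$ (final fits); ADMM $\rho = 1$ with residual balancing.
  Solutions from both solvers agree with an independent proximal-gradient
  (FISTA) minimizer to $10^{-6}$ relative in objective on the test
  fixtures.
* Duplicate network edges keep the maximum weight (weights are
  relationship strengths, max is conservative toward connectivity);
  self-loops are dropped with a warning.
* Patients present in the matrix but not the survival table (or vice
  versa) are intersected with a warning, never silently reordered.
* A constant gene yields a degenerate marginal fit (coefficient 0); a
  constant prognostic index makes every split degenerate and is an error;
  an empty signature marks stratification non-evaluable rather than
  failing the run.
* Genes at exactly $p = 0.05$ in the evidence tiers go to the "high"
  category, consistent with the inclusive screening cutoff.

## Problem sizes in the shipped checks

The test suite and the acceptance script run on deliberately moderate
sizes chosen as representative desk-scale study conditions: solver-oracle
comparisons at $n = 60$, $d \in \{5, 6\}$; screening recovery at
$n = 500$, $p = 200$ with $|\beta^*| = 0.8$ and 30% censoring; end-to-end
runs at $n_{train} = n_{test} = 300$, $p = 200$, union screening with
$d_{DAD} = 50$, 5-fold cross-validation repeated 3 times; null
calibration over a few hundred replicates at $n = 300$, $p = 20$.

## Known limitations

No Efron tie handling, stratified Cox, clinical-covariate adjustment,
competing risks or time-dependent effects; the network is always an
input, never inferred; concordance-based multi-omic adjustment of the
expression matrix is accepted as an externally produced input rather than
recomputed. The adaptive cutoff's training p-value should never be quoted
as a performance number — use the held-out one.
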