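---
title: "Methods: high-dimensional mediation analysis for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-dimensional mediation analysis for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmedsurv)
```

## The problem and the model

Epigenome-wide studies routinely ask whether an exposure (smoking, say)
affects a time-to-event outcome (overall survival) *through* molecular
intermediates such as DNA-methylation probes. With hundreds of thousands of
candidate mediators and a few hundred subjects, the mediation question
becomes a joint selection-and-inference problem under censoring.

`hdmedsurv` works with two linked regression models. The outcome follows a
Cox proportional hazards model in the exposure $X$, baseline covariates
$Z$, and all $p$ candidate mediators $M_1, \dots, M_p$:

$$\lambda_i(t \mid X_i, M_i) = \lambda_0(t)\,
\exp\{\gamma X_i + \theta^T Z_i + \beta_1 M_{1i} + \cdots + \beta_p M_{pi}\},$$

and each mediator follows a linear model in the exposure:

$$M_{ki} = c_k + \alpha_k X_i + \vartheta^T Z_i + e_{ki},
\qquad e_{ki} \sim N(0, \sigma^2).$$

A mediator transmits exposure effect only when both paths are active, so
the per-mediator indirect effect on the log hazard-ratio scale is the
product $\alpha_k \beta_k$; the direct effect is $\gamma$. For an exposure
contrast $x \to x^*$ the decomposition is

$$\Delta_{X \to Y} = (x^* - x)\,\gamma, \qquad
\Delta_{X \to M \to Y} = (x^* - x) \sum_k \alpha_k \beta_k,$$

with the total effect their sum. These contrasts arise as differences of an
approximate counterfactual log hazard that also carries a variance term
$\tfrac12 \sigma^2_{W\beta}$ with $\sigma^2_{W\beta} = \sum_k \beta_k^2
\sigma^2_{M_k}$ and mediator-intercept terms $\beta_k (c_k + \vartheta^T
Z)$; those terms cancel in every contrast, which
`counterfactual_log_hazard()` makes explicit. The causal reading requires
the usual no-unmeasured-confounding conditions (exposure-outcome,
mediator-outcome, exposure-mediator, and no exposure-induced
mediator-outcome confounders). They are assumptions about the design, not
testable from the data, and the package does not pretend to test them.

## The four-step procedure

1. **Screening.** Marginal utilities rank all $p$ mediators and the top
   $d = \lfloor \kappa n / \log n \rfloor$ (natural log, $\kappa = 2$ by
   default) are retained as $S_1$. Two rankings are available.
   *Outcome path* (default, used throughout the simulations): the
   standardized coefficient $|\hat\beta_k| / \mathrm{SE}$ from the marginal
   Cox fit on $(X, Z, M_k)$. *Exposure path*: $|\hat\alpha_k|/\mathrm{SE}$
   from the mediator model, the practical choice when mediator-outcome
   associations are much stronger than exposure-mediator ones (there, a
   larger budget $\kappa = 3$ is conventional). "Correlation learning" is
   not directly defined for censored outcomes; standardized marginal
   coefficients are scale-invariant and adjust for $X$ and $Z$ so that the
   ranking does not reward mediators that merely track the exposure. Ties
   break toward the lower column index, making the ranking deterministic.

2. **Penalized selection.** Within $S_1$ the package maximizes
   $n^{-1} l_n(\beta) - \sum_k P_\lambda(\beta_k)$, where $l_n$ is the
   Breslow partial likelihood over $(X, Z, S_1)$ and $P_\lambda$ is the
   minimax concave penalty
   $P_\lambda(\beta) = \lambda|\beta| - \beta^2/(2a)$ for
   $|\beta| \le a\lambda$, constant beyond, with derivative
   $(a\lambda - |\beta|)_+ / a$. MCP applies lasso-like shrinkage near the
   origin and none beyond $a\lambda$, so large coefficients are nearly
   unbiased and the selector has the oracle property. The shape default
   $a = 3$ follows the reference implementation of the penalty; a lasso
   mode is provided for comparison. $X$ and $Z$ are never penalized: they
   are confounder adjustments, not selection targets. The selected set is
   $S_2 = \{k : \hat\beta_k \ne 0\}$ at the chosen $\lambda$.

3. **Refit and decomposition.** An unpenalized Cox model on $(X, Z, S_2)$
   supplies $\hat\gamma$, $\hat\beta_k$ and their standard errors from the
   inverse observed information; per-mediator linear models supply
   $\hat\alpha_k$, $\mathrm{SE}(\hat\alpha_k)$ and
   $\hat\sigma^2_{M_k} = \mathrm{RSS}/(n - q - 2)$. Penalized estimates are
   deliberately not used for inference: they are shrunk and carry no
   defined SE; refitting after selection is the standard practice and is
   what keeps the indirect-effect estimates nearly unbiased.

4. **Testing.** For $k \in S_2$, the Sobel test uses
   $\hat\sigma_{\alpha_k\beta_k} = (\hat\alpha_k^2 \mathrm{se}_\beta^2 +
   \hat\beta_k^2 \mathrm{se}_\alpha^2)^{1/2}$ and
   $P_{raw,k} = 2\{1 - \Phi(|\hat\alpha_k\hat\beta_k| /
   \hat\sigma_{\alpha_k\beta_k})\}$. The joint significance (causal-steps)
   test takes the maximum of the two path p-values — the Wald p-value of
   $\hat\beta_k$ from the refit and the t-test p-value of $\hat\alpha_k$
   from the mediator model — and provides no estimate. Both are Bonferroni
   adjusted by $m = |S_2|$ (not $p$), and significance is declared at
   0.05 on the adjusted scale. The Sobel statistic is known to be
   conservative for products near the null; the joint test typically has
   higher power and slightly more false positives, and the package reports
   both.

## Choosing the regularization strength

No selection rule for $\lambda$ is prescribed by the procedure itself, so
the package makes a documented choice: a BIC on the partial likelihood,
$-2 l_n(\hat\beta_\lambda) + \log(n_{events}) \cdot df_\lambda$, with
$df_\lambda$ counting nonzero penalized coefficients plus the always-present
unpenalized columns. BIC is deterministic, cheap, and the conventional
companion of oracle-property penalties; 10-fold cross-validated partial
likelihood (Verweij-Van Houwelingen, folds stratified by event status) is
available as an option. The automatic grid runs 100 log-spaced values from
$\lambda_{max}$ (the smallest value whose null quadratic approximation
zeroes every penalized coordinate) down to $0.05\,\lambda_{max}$, or
$0.01\,\lambda_{max}$ when the penalized block is smaller than $n$.

## The solver

The penalized optimum is computed by iteratively reweighted least squares
with coordinate descent, warm-started along the decreasing $\lambda$ grid.
Each cycle re-expands the partial likelihood to its diagonal-Hessian
quadratic at the current linear predictor (gradient $g_i = \delta_i -
e^{\eta_i} H_i$ and curvature $w_i = e^{\eta_i} H_i - e^{2\eta_i} G_i$ with
$H, G$ the cumulative Breslow sums), sweeps the unpenalized columns with
plain coordinate-Newton updates and the active penalized columns with the
exact one-dimensional MCP update, and step-halves whenever the true
penalized objective would decrease, so the objective is nondecreasing
across cycles by construction. The one-dimensional update is solved by
candidate enumeration over the penalty's pieces rather than the textbook
closed form: when the coordinate curvature $v \le 1/a$ the MCP middle piece
is concave and the closed form is invalid, while the candidate set (origin,
interior stationary point, unpenalized point, region boundaries) always
contains the global minimizer. Convergence of a $\lambda$ requires the
stabilized active-set cycles to be confirmed by a full sweep over all
penalized columns (a KKT check), so inactive columns cannot be silently
stuck. Penalized columns are standardized internally (population SD) and
estimates are returned on the original scale.

Ties in the observed times are handled by the Breslow convention
throughout, matching the risk-set definition $R_i = \{l : T_l \ge T_i\}$;
an Efron rule is not provided because the simulation design generates
continuous times where ties are measure-zero, and the Breslow rule is what
the screening, selection and refit layers share. Unpenalized fits use
Newton-Raphson with step halving, convergence at relative log-likelihood
change below $10^{-9}$ (100-iteration cap), standard errors from the
inverse observed information, and an explicit error on singular
information; a coefficient escaping beyond $|\hat\beta| > 30$ is treated as
monotone likelihood and flagged unconverged.

## The synthetic-data generator

`simulation_config()` encodes the generative model used for all operating
characteristics: $X \sim B(1, 0.6)$ with $\gamma = 0.5$; $Z_1 \sim B(1,
0.3)$ (gender-like) with $\theta_1 = 0.3$; $Z_2 \sim U(0, 1)$ (age-like)
with $\theta_2 = -0.2$; mediator intercepts $c_k \sim U(0, 1)$ drawn fresh
per replicate; mediator covariate effects $(\vartheta_1, \vartheta_2) =
(0.3, 0.2)$; residuals $N(0, 1)$; baseline hazard $\lambda_0 = 0.5$ so
death times are exponential with rate $0.5\,e^{\eta}$, drawn by the exact
inversion $D = -\log(U)/\mathrm{rate}$; censoring $C \sim U(0, c_0)$. The
default coefficient pattern puts $\alpha = (0.5, 0.45, 0.5, 0.4, 0.45,
0.45, 0, 0)$ and $\beta = (0.55, 0.6, 0.65, 0.7, 0, 0, 0.5, 0.5)$ on the
first eight mediators and zero elsewhere, so exactly four mediators
(k = 1..4) are true mediators, two (k = 5, 6) touch only the exposure path
and two (k = 7, 8) only the outcome path — the configurations that stress
both tests.

$c_0$ is not part of the design; it is calibrated by `calibrate_c0()` to
hit a target censoring fraction: common random numbers are drawn once under
a dedicated calibration seed (separate from the data seed), making the
Monte-Carlo censoring fraction exactly monotone in $c_0$, and bisection
stops within half a percentage point of the target. Only mediators with
nonzero $\beta$ are simulated during calibration since the others never
enter the hazard.

An optional dependence knob makes mediators serially correlated through
$\tilde M_k = M_k + \sum_{l < k} \rho^{k-l} M_l$ (computed by an exact
recursion); the default is independence. The generator does **not** attempt
to emulate real methylation data: beta-value marginals on [0, 1], probe-set
correlation structure, batch effects and non-exponential baseline hazards
are all out of scope. Passing the simulation suite therefore demonstrates
correctness of the procedure under its stated model, not robustness to
those real-data features.

## Problem sizes used in the shipped studies

The packaged experiments run at a desk scale chosen once: $p = 2000$
candidate mediators (with the identical eight nonzero coefficients) and 100
replicates per scenario across $(n, \text{censoring}) \in \{(1000, 0.15),
(500, 0.15), (300, 0.35)\}$. This preserves the $p \gg n$ regime and the
screening budget $d = \lfloor 2n/\log n\rfloor \in \{289, 160, 105\}$ while
keeping a full three-scenario study around ten minutes on one CPU; the
Monte-Carlo standard error of a TPR around 0.75 at 100 replicates is about
0.02, well inside the comparison tolerances used in the tests. The
family-wise-error study under the complete null uses $n = 200$, $p = 300$
and 500 replicates; several unit-level Monte-Carlo checks use smaller
$n$ and $p$ with the same generator. Full-scale runs ($p = 10000$, 500
replicates) are a matter of passing different arguments to
`run_experiment()`.

Per-replicate seeds are derived from the master seed and the (scenario,
replicate) indices through a small multiplicative mix kept below $2^{31}$,
so replicates are mutually independent, individually reproducible, and
order-insensitive.

## Comparators

Two deliberately weaker baselines mirror the pipeline's ablations:
`run_baseline_onestep()` applies the penalized selection directly to all
$p$ mediators (no screening), and `run_baseline_naive()` tests every
mediator marginally (no screening, no joint selection) with Bonferroni
factor $p$. Both lose power against the full pipeline at small $n$ — the
one-step method because selection over the full candidate set is harder,
the naive method because the multiplicity burden is 2000 rather than
$|S_2| \approx 6$.

## Known limitations

* Post-selection inference is handled by refitting and Bonferroni
  adjustment over $S_2$; no selective-inference correction is applied, so
  raw p-values of barely-selected mediators are mildly optimistic at small
  $n$ (visible as upward bias of the product estimates at $n = 300$).
* The total-effect CI treats the direct and indirect variance
  contributions as independent, ignoring the covariance between the Cox
  and mediator-model estimates; the decomposition identity itself is
  exact.
* The Sobel SE is used for both testing and the CI of each
  $\hat\alpha_k\hat\beta_k$; bootstrap CIs are out of scope.
* Exposure-mediator interactions, time-varying covariates, stratified or
  frailty models, and multiple exposures are out of scope.
* The joint test inherits the conservativeness of causal-steps procedures
  near the boundary of its composite null.
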