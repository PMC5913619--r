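---
title: "Measurement error breaks negative-control calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error breaks negative-control calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negctrlbias)
```

## The problem

A negative control exposure is a variable that cannot causally affect the
outcome but shares the exposure's confounding structure — the father's
smoking during the mother's pregnancy as a control for maternal smoking, for
example. If the control shows an association with the outcome, residual
confounding is present, and a tempting next step is to *calibrate*: report
the exposure's estimated effect minus the control's estimated effect,
$\hat\beta_1 - \hat\beta_2$, as a deconfounded estimate.

This package studies what measurement error does to that practice. Its two
engines are (i) a closed-form expression for the asymptotic bias of OLS when
both regressors are noisy and a confounder is omitted, and (ii) a seeded
Monte Carlo engine for the dichotomized (binary) design, where error takes
the form of misclassification.

## The structural model

All data are generated from
$$y_i = \beta_1 E_{T,i} + \beta_2 C_{T,i} + \gamma U_i + \varepsilon_i,$$
where $E_T$ is the true exposure, $C_T$ the true negative control, $U$ an
unmeasured confounder and $\varepsilon \sim N(0, \sigma_\varepsilon^2)$.
$(U, E_T, C_T)$ is trivariate standard normal with
$\mathrm{corr}(U, E_T) = \rho_{UE}$, $\mathrm{corr}(U, C_T) = \rho_{UC}$,
and — because exposure and control are correlated *only* through the
confounder — $\rho_{EC} = \rho_{UE}\rho_{UC}$. The canonical configuration
sets $\rho_{UE} = \rho_{UC} = 0.4$, hence $\rho_{EC} = 0.16$.

The analyst never sees $U$. They regress $y$ on observed versions
$E_O$, $C_O$:

* **Continuous design**: $E_O = E_T + v_E$ with
  $v_E \sim N(0, \sigma^2_{vE})$ independent of everything (classical
  error), parameterized by the intraclass correlation coefficient
  $\mathrm{ICC} = \sigma^2_u / (\sigma^2_u + \sigma^2_v)$, so
  $\sigma^2_v = (1-\mathrm{ICC})/\mathrm{ICC}$ on the unit-variance scale.
  ICC 1 means error-free.
* **Binary design**: $E_T$, $C_T$ are dichotomized at the empirical 80th
  percentile (top 20% coded 1); the outcome is generated from these *true*
  binary indicators; then each observed indicator is independently flipped
  with probability $p$ (symmetric, non-differential misclassification:
  the same flip rate in both classes). The canonical error levels are
  $p \in \{0, 0.1, 0.5\}$.

## The bias formula

With $Q_{XX}$ the limiting second-moment matrix of the true regressors
(unit diagonal, off-diagonal $\rho_{EC}$), $Q_{XU} = (\rho_{UE},
\rho_{UC})'$ and $\Sigma_v = \mathrm{diag}(\sigma^2_{vE}, \sigma^2_{vC})$,
the asymptotic bias of OLS on the observed regressors is
$$E(\hat\beta - \beta) =
  (Q_{XX}+\Sigma_v)^{-1} Q_{XU}\,\gamma \;-\;
  (Q_{XX}+\Sigma_v)^{-1} \Sigma_v\,\beta .$$
The first term is confounding transmitted into both coefficients; the
second is regression dilution. `analytic_ols_bias()` evaluates this by
solving the $2\times2$ linear system (never forming the inverse, which
matters as $|\rho_{EC}| \to 1$). Two consequences drive everything else:

* with no measurement error and $\rho_{UE} = \rho_{UC}$, both coefficients
  absorb the *same* confounding, so the calibrated estimate
  $\hat\beta_1 - \hat\beta_2$ is exact;
* with unequal error (or unequal effects), the two coefficients are
  attenuated differently and calibration is biased — possibly away from
  the null.

In the degenerate case $\gamma = 0$, $\rho_{EC} = 0$, error only in the
exposure, the formula collapses to the classical attenuation
$E(\hat\beta_1) = \beta_1/(1+\sigma^2_{vE})$, which
`univariate_attenuation()` provides as an independent closed form; the
test suite requires exact agreement.

```{r}
conf <- confounding_structure(0.4, 0.4)
analytic_ols_bias(moment_matrices(conf), structural_params(gamma = 0.5))
```

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `rho_UE`, `rho_UC` | confounder–exposure / –control correlation | 0.4 | canonical study condition; implies `rho_EC = 0.16` |
| `gamma` | confounder effect on outcome | scanned on [0, 0.5] | the bias curves' x-axis (51 points) |
| `icc_E`, `icc_C` | reliability of observed continuous variables | 1 | 1 = error-free; error variance $(1-\mathrm{ICC})/\mathrm{ICC}$ |
| `p_E`, `p_C` | misclassification proportions | 0 | canonical grid 0 / 0.1 / 0.5 |
| `quantile_cut` | dichotomization quantile | 0.8 | top 20% coded 1 |
| `sigma_eps` | outcome noise SD | 1 | the bias is invariant to it; it only scales Monte Carlo noise, so unit variance is assumed |
| `n`, `reps` | per-replicate size, replicate count | 10000, 10000 | three-decimal tables need Monte Carlo SE well below 0.0005 |

True-score variances are fixed at 1 (the moment matrix has unit diagonal);
ICC conversions accept another `sigma2_true` for generality.

## The simulation engine

`simulate_dataset()` runs the full generative pipeline with six
independently seeded sub-streams (latents, each error channel, outcome
noise) derived from one master seed via `derive_seed()`, a Lehmer-style
integer mix. Consequences, all tested: datasets are bit-reproducible;
toggling one error channel leaves every other stream untouched; cells of a
table can be run in any order, or singly, with identical results.
Measurement error is applied only to the regressors handed to estimation —
the outcome is always generated from the true (error-free, and in the
binary design pre-misclassification) values.

`fit_observed_regression()` always includes an intercept, although the
estimand equations omit one: dichotomized regressors have mean 0.2, and
without an intercept even the error-free, unconfounded model would be
misspecified (its zero-bias cells would not be zero). Rank-deficient
designs (e.g. a binary regressor collapsing to one class) are flagged
degenerate, discarded and counted rather than zero-filled; at the default
sample sizes they essentially never occur.

## Design choices that were genuinely open

* **Latent distribution.** Nothing in the model pins down the family; the
  trivariate normal is the minimal choice consistent with a correlation
  parameterization and normal error terms.
* **Binary-design correlations.** The latent correlations
  ($\rho_{UE} = \rho_{UC} = 0.4$, $\rho_{EC} = 0.16$) are imposed *before*
  dichotomization; the correlations between the resulting indicators are
  smaller (a cut at the 80th percentile retains only a fraction of the
  latent correlation) and emerge from the cut rather than being targeted
  directly. One visible consequence: when both variables are error-free,
  adjusting for the control removes a small share of the exposure's
  omitted-variable bias through their induced (binary-scale) correlation,
  so the no-error cells of the simulated tables sit slightly below the
  single-regressor value $\gamma\,\rho_{UE}\,\phi(z_{0.8})/0.16$; at these
  settings the difference is about 0.01.
* **Misclassification as Bernoulli flips.** Each observation is flipped
  independently with probability $p$, identically in both classes; this
  satisfies the symmetric-misclassification description in expectation and
  yields the clean $(1-2p)$ covariance attenuation used as a test oracle.
  Flipping an exact count per class would only change finite-replicate
  variability.
* **Empirical versus theoretical cut.** Dichotomization uses the empirical
  80th percentile of each replicate, with strict inequality; with
  continuous latents ties have probability zero and the two choices agree
  asymptotically.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly as modelled: one
confounder, classical non-differential error, no direct exposure–control
link, normal latents. Passing tests therefore certify the algebra and the
engine, not robustness to differential misclassification, correlated error
channels, multiple confounders, skewed latents, or assortative-mating-type
direct correlation — all deliberately out of scope.

## Numerical choices and problem sizes

Bias tables in the test suite use $n = 10{,}000$ per replicate and 2000
replicates per cell (Monte Carlo SE on each bias below 0.001, against a
reproduction tolerance of 0.015 on three-decimal targets); the
analytic-versus-simulation validation grid spans
$\gamma \in \{0, 0.25, 0.5\} \times \mathrm{ICC} \in \{1, 0.7, 0.4\}$ at
$n = 10{,}000$ and 200 replicates (Monte Carlo SE $\le 0.002$) with a
$|z| < 3$ equivalence criterion. Defaults for production runs are 10,000
replicates per cell. Validation happens at construction time: every
parameter object checks its invariants (positive-definite latent
correlation matrix, ICC in $(0,1]$, proportions in $[0,1]$) so downstream
code can assume well-formed inputs.

## Known limitations

The analytic formula is asymptotic — finite-sample bias at small $n$ is
not corrected. Only one confounder and one negative control are supported;
the exposure–control correlation cannot be set independently of
$\rho_{UE}\rho_{UC}$. No standard errors or confidence intervals for real
data are produced: this is a design-stage bias calculator, not an
estimation package. In the binary design with 50% misclassification the
observed regressor is pure noise, so the expected coefficient is zero
regardless of the true effect — the simulated "bias" there measures the
full loss of the signal, not a small perturbation.
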