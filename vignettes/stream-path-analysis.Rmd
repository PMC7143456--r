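---
title: "Methods: path analysis of land use, water quality and stream biota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path analysis of land use, water quality and stream biota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamsem)
```

## The model

`streamsem` analyses a recursive (acyclic) system of linear structural
equations among six observed site variables: urban and agricultural
land cover (exogenous), BOD, TN and TP concentrations (mediating water
quality) and the BMI biotic score (outcome). Writing the system as
$y = By + \zeta$ with error covariance $\Psi$, the implied covariance
matrix is $\Sigma(\theta) = (I-B)^{-1}\Psi(I-B)^{-\top}$. Estimation
minimizes the maximum-likelihood discrepancy

$$F(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
  - \ln|S| - p$$

over the free parameters: path coefficients, exogenous variances and
covariances, and one residual variance per endogenous variable (the
structural error terms). Residual covariances among structural errors
are fixed at zero — the independent-error assumption of the hypothesis
diagram — and the system must be acyclic; latent variables,
missing-data likelihoods and non-recursive systems are out of scope.

Assumptions worth stating plainly: multivariate normality of the
analyzed (log-transformed, standardized) variables justifies the ML
discrepancy and the $\chi^2 = (n-1)F_{\min}$ calibration; the causal
ordering (land use → water quality → biota) is imposed, not tested; and
the model is identified by the counting rule $t \le p(p+1)/2$ plus
recursiveness, with convergence diagnostics guarding empirical
identification.

## Numerical choices

* **Starting values** are equationwise least-squares coefficients with
  their regression residual variances, and sample moments for the
  exogenous block. For a just-identified recursive model these already
  solve the ML problem; for over-identified models they start the
  quasi-Newton (BFGS) search essentially at the solution, which is what
  makes the deterministic self-consistency targets robust.
* **Gradients** are analytic:
  $\partial F = \mathrm{tr}[\Sigma^{-1}(\Sigma-S)\Sigma^{-1}\,
  \partial\Sigma]$, assembled per parameter from $A=(I-B)^{-1}$. A
  non-positive-definite $\Sigma(\theta)$ during the search returns a
  large penalty value (a retreat step), never an error.
* **Standard errors** come from the inverse numerical Hessian of $F$
  scaled by $2/(n-1)$, on the unstandardized parameterization.
  Standardized coefficients are derived quantities
  ($\beta^{std}_{t\leftarrow s} = \beta\,\hat\sigma_s/\hat\sigma_t$
  from the implied variances), so they are invariant to rescaling any
  observed variable — fitting the covariance or the correlation matrix
  yields the same standardized solution, which the suite asserts.
  Standardized SEs are deliberately not reported: published tables of
  this design pair standardized coefficients with SEs on the analyzed
  (unstandardized) scale, and the ratio of the two is not a critical
  ratio.
* **Conventions**: $\chi^2 = (n-1)F$ (switchable to $nF$), RMSEA uses
  the matching denominator; both follow the dominant commercial-SEM
  convention. Inclusive thresholds ($\ge 0.90$, $\le 0.05$) are used
  for the criteria. A saturated model (df = 0) reports TLI, AGFI and
  RMSEA as `NA`, never 0 or 1. The GFI is the ML-weighted variant
  $1 - \mathrm{tr}[(\hat\Sigma^{-1}S - I)^2]/
  \mathrm{tr}[(\hat\Sigma^{-1}S)^2]$; which variant legacy software
  used cannot be pinned down, so the choice is documented here and in
  the output metadata.
* **Baseline model** for NFI/TLI/CFI is the independence model with
  free variances, giving the closed form $F_b = -\ln|R|$ with $R$ the
  correlation matrix.

## Pruning

Model refinement removes structural paths whose critical ratio lies
inside $\pm 1.96$ (the 0.05-level screen). The default is stepwise:
drop the single weakest path, refit, re-screen. Batch removal of all
insignificant paths at once — the behaviour that published refinements
appear to use — is available via `batch = TRUE`; stepwise is the
default because a path can regain significance after another is
removed. Only paths are ever pruned; variances and exogenous
covariances stay, and a variable orphaned by pruning remains in the
model with a free variance. The threshold is a parameter. One
published phrasing ties pruning to "low TLI values"; the implementation
prunes on critical ratios only and records TLI before and after,
without inventing a TLI-based rule.

## Preprocessing

Monitoring variables of this kind are right-skewed, so the pipeline
log-transforms (natural log) before standardizing; the base only
rescales covariances and cannot change correlations or standardized
coefficients. Exact zeros occur in percent-cover and TP columns, so the
offset policy is deterministic and scale-aware: $\varepsilon = 0$ when
all values are positive, else half the smallest positive value of that
variable. Whether a bounded score like BMI should be log-transformed is
genuinely ambiguous; the default transforms all six variables and the
set is configurable. Normality screening uses the exact KS statistic at
the order statistics; the default p-value is the Lilliefors
(parameters-estimated) approximation of Dallal–Wilkinson, since
population moments are unknown in practice, with the asymptotic
Kolmogorov series (Stephens' argument adjustment) available when the
hypothesized moments are genuinely known.

## What the generator emulates — and what it does not

`simulate_standardized()` draws sites from the exact linear-Gaussian
law of a fully specified path model: correlated Gaussian exogenous
variables, then each endogenous variable in topological order as parent
combination plus independent Gaussian error. With residual variances
from `solve_unit_variance_residuals()` (each set to one minus the
variance explained by its parents, processed in topological order) the
population is standardized, so a reference set of standardized
coefficients becomes a generating model. The default coefficient set is
the refined watershed model (`lu_wq_bmi_model("refined")`); the
urban–agricultural correlation is not part of any published set and is
fixed at 0.2 — plausible for co-occurring development — and no test or
target depends on its value beyond keeping $\Psi$ positive definite.

`to_raw_scale()` maps z-scores to measurement units against the stored
marginal targets of the 111-site network: lognormal for the five
skewed variables (log-scale moments solved by method of moments so raw
mean and SD match), affine for BMI, which is then clamped to [0, 100]
rather than resampled so that a seed always yields the same table.
`simulate_taxa()` builds assemblages hitting a target BMI exactly by
rescaling the frequencies of the low-saprobity stratum.

The generator reproduces the covariance structure and marginal moments
it states — nothing more. Real monitoring data carry spatial
autocorrelation along the river network, measurement error, detection
limits, non-Gaussian tails and a bounded outcome; none of these are
emulated. A green test therefore establishes that the estimator,
indices and pruning behave correctly under the model's own assumptions,
not that the substantive ecological conclusions would survive those
field complications. In particular, fitted raw data pass through a log
transform whose Jacobian makes the BMI column's correlations only
approximately equal to the generating ones (the suite allows 0.05
there, 0.02 for the untouched columns).

## Sampling behaviour of the acceptance thresholds

One derived expectation deserves its own paragraph because the naive
version of it is false. When data are simulated *from* the refined
model at $n = 111$ (df = 6), the model $\chi^2$ is approximately
$\chi^2_6$, and the RMSEA $\le 0.05$ criterion passes only when
$\chi^2 \le df + df(n-1)(0.05)^2 = 7.65$ — probability
$\approx 0.735$, not $\approx 1$. The pipeline test asserts exactly
this binomial behaviour (and near-certain passes for the relative
indices) rather than a higher rate no correctly specified model could
deliver. This is also why a single seed can show the *initial* model
passing or failing RMSEA by luck.

## Known limitations

* All-observed-variable models only; no measurement model.
* The ML fitter handles the moderate dimensions of this design
  (p ≤ ~20) comfortably but is not engineered for large p.
* The Lilliefors p-value is an analytic approximation calibrated for
  the normal null; extreme tail p-values are clipped to [0, 1].
* Reported p-values for paths are normal-theory two-sided values; no
  bootstrap or robust alternatives.
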