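---
title: "Fisher Scoring for crossed-factor linear mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher Scoring for crossed-factor linear mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

`fslmm` estimates linear mixed models with one or more random-effect
grouping factors that may be fully crossed:

$$Y = X\beta + Zb + \varepsilon, \qquad
  b \sim N(0, \sigma^2 D), \qquad
  \varepsilon \sim N(0, \sigma^2 I_n),$$

so that $\mathrm{Var}(Y) = \sigma^2 V$ with $V = I_n + ZDZ'$. For each of
the $r$ factors, $D$ holds one $q_k \times q_k$ covariance block $D_k$
repeated over the factor's $l_k$ levels; $Z$ collects the per-factor
random-effect covariates, one column block per level. Crossed factors
(e.g. subjects crossed with items) make $V$ non-block-diagonal, which is
the case this package targets.

## Product forms

All estimation works from six cross-products of the data,

$$P = X'X,\; Q = X'Y,\; R = X'Z,\; S = Y'Y,\; T = Y'Z,\; U = Z'Z,$$

computed once by `product_forms()`. Every likelihood, score and Fisher
Information evaluation is then free of $n$-sized objects: the matrices
above have dimensions governed by $p$ (fixed effects) and
$q_{\text{total}} = \sum_k q_k l_k$ only. A Woodbury identity converts
$V^{-1}$ solves into $q_{\text{total}}$-sized solves, and the
information-matrix blocks use a reshape-and-permute identity for sums of
Kronecker products (`kron_sum_vectorized()`) instead of looping over
levels.

## The five scoring algorithms

`lmm_fit()` offers five variants that share the same stationary points:

* **FS** — joint Fisher Scoring on $(\beta, \sigma^2, \mathrm{vech}(D_k))$,
  the non-redundant "half" representation of each symmetric block.
* **FFS** — joint scoring on the full (redundant) $\mathrm{vec}(D_k)$
  representation, using the scoring-matrix surrogate whose plain inverse
  reproduces the pseudo-inverse update. Its iterates match FS exactly.
* **SFS** — simplified scoring: $\beta$ by generalized least squares,
  $\sigma^2$ in closed form, then per-factor $\mathrm{vech}(D_k)$ scoring
  updates.
* **FSFS** — the full-representation analogue of SFS; iterates match SFS
  exactly.
* **CSFS** — scoring on the Cholesky factor $\Lambda_k$ with
  $D_k = \Lambda_k \Lambda_k'$, which keeps every iterate positive
  semi-definite. Near rank-deficient $\Lambda_k$ the parameterisation
  loses first-order information (the derivative of $D$ with respect to
  the last diagonal entry vanishes at the boundary), so CSFS can stall on
  boundary cases; the other methods use an eigendecomposition projection
  (`project_psd()`) after each step instead.

Both maximum likelihood and restricted maximum likelihood (`criterion =
"ReML"`) are supported; ReML adds the standard residual-projection terms
to the score and uses denominator $n - p$ in the $\sigma^2$ update.

```{r}
library(fslmm)

st <- sim_setting("setting2")    # two crossed factors, q = (3, 2)
ds <- generate_dataset(st, seed = 7)
fit <- lmm_fit(ds$design, method = "FSFS", criterion = "ReML")
fit
```

Tidyverse-style accessors summarise the fit:

```{r}
tidy(fit)
glance(fit)
autoplot(fit)    # accepted log-likelihood trace, non-decreasing
```

## Constrained covariance structures

`lmm_fit_constrained()` performs scoring in a constrained parameterisation
$\mathrm{vec}(D_k) = \text{reconstruct}(u)$ with Jacobian $C_k$, mapping
the full-representation score and information through $C_k$. Builtins
cover diagonal, compound-symmetry, scaled-identity and unstructured
blocks; `ace_constraints()` implements the twin-study ACE decomposition
$D_k = \tau_a^2 K^a_k + \tau_c^2 K^c_k$ with parameters shared across
factors, from which `ace_components()` reports
$(\sigma_a^2, \sigma_c^2, \sigma_e^2)$:

```{r}
ace <- generate_ace_dataset(n_families = 80, seed = 11)
afit <- lmm_fit_constrained(ace$design, ace$spec, criterion = "ML")
ace_components(afit)
```

## Inference

`approx_t()` tests a single fixed-effect contrast $L\beta = 0$ with
$T = L\hat\beta / \sqrt{S^2}$,
$S^2 = \hat\sigma^2 L (X'\hat V^{-1}X)^{-1} L'$, and Satterthwaite
degrees of freedom $\nu = 2 (S^2)^2 / \widehat{\mathrm{Var}}(S^2)$
computed *directly*: the gradient of $S^2$ in the variance parameters has
a closed form, and $\mathrm{Var}(S^2)$ follows from the inverse Fisher
Information. For ReML fits the information is evaluated in its restricted
(residual-projected) form, so with $D = 0$ and $\sigma^2$ as the only
variance parameter the degrees of freedom collapse to exactly $n - p$.

```{r}
approx_t(fit, c(0, 1, 0, 0))
```

## Files and the command line

`cli_fit()` (and the `inst/cli/fslmm` launcher's `fit` subcommand) fits a
model described by a CSV data table plus a JSON model file naming the
response, fixed-effect and per-factor columns; `cli_simulate()`,
`cli_benchmark()` and `cli_dof()` expose the synthetic-data generator, the
estimation benchmark and the degrees-of-freedom calibration harness.
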