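---
title: "Comparing spatio-temporal Poisson models under controlled correlation"
author: "stpcar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing spatio-temporal Poisson models under controlled correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpcar)
```

## The problem

Panel counts on areal units — here, annual counts of severely food-insecure
individuals across the countries of a continent — carry two kinds of
dependence: nearby units resemble each other (spatial correlation) and
successive years resemble each other (temporal correlation). A model that
mis-handles either can badly over- or under-state uncertainty. `stpcar`
provides a controlled laboratory for this question: it generates panels
whose latent log-intensity carries user-specified spatial and temporal
correlation, fits four Bayesian spatio-temporal Poisson models to each
panel, and scores them by WAIC, RMSE, MAE and out-of-sample
predictive-interval coverage across a grid of correlation scenarios.

## The models

All four models share the Poisson observation layer with log link and a
known offset (log exposure),

$$y_{it} \sim \mathrm{Poisson}(\mu_{it}), \qquad
\log \mu_{it} = \mathbf{x}_{it}'\boldsymbol\beta + \log n_{it} + v_{it},$$

for units $i = 1,\dots,N$ and times $t = 1,\dots,T$, and differ in how the
space–time random effect $v_{it}$ is decomposed:

* **SPLTM** (linear trend): $v_{it} = \omega_1 + a_i + (\omega_2 + b_i)\,
  (t - \bar t)/T$ with $\bar t = (T+1)/2$; spatially varying intercepts
  $a_i$ and slopes $b_i$.
* **SPAM** (ANOVA type): $v_{it} = a_i + b_t + c_{it}$ — spatial main
  effect, temporal main effect, iid interaction
  $c_{it} \sim N(0, k^2_I)$.
* **STSM** (separable): $v_{it} = a_{it} + b_t$ with an independent spatial
  field $a_{\cdot t}$ for every year (each with its own variance $k^2_t$)
  plus a temporally structured trend $b_t$.
* **TMS** (temporal autoregression): $v_{it} = a_{it}$ with
  $\mathbf{a}_t \mid \mathbf{a}_{t-1} \sim
  N(\rho_T\, \mathbf{a}_{t-1},\ k^2\, Q(W,\rho_s)^{-1})$ and
  $\mathbf{a}_1 \sim N(0,\ k^2\, Q(W,\rho_s)^{-1})$.

Structured effects carry the Leroux conditional-autoregressive (CAR) prior
with precision

$$Q(W, \rho) = \rho\,(W_d - W) + (1 - \rho)\,I,$$

where $W$ is the binary symmetric adjacency, $W_d$ its degree diagonal and
$\rho \in [0,1]$ interpolates between independence and the intrinsic CAR.
Temporal CAR terms use the tridiagonal lag-one adjacency $Z$. Each unit's
full conditional is
$N\!\big(\rho \sum_j w_{ij}\varphi_j / d_i^\rho,\ k^2 / d_i^\rho\big)$
with $d_i^\rho = \rho\sum_j w_{ij} + 1 - \rho$, which is what
`car_full_conditional()` returns and what the joint density
`car_log_density()` integrates to (proper only for $\rho < 1$; the package
refuses the intrinsic limit in joint-density form).

Priors: uniform$(0,1)$ on every $\rho$, inverse-gamma on every variance
(default IG(1, 0.01), a weakly informative standard for CAR variance
components; the hyperparameters are unconventional to fix from theory, so
they are exposed in `prior_config()`), improper flat priors on $\beta$ and
the $\omega$'s. Posterior propriety is carried by the likelihood in every
configuration the package runs.

### Identifiability

A free level in $a_i$ (and $c_{it}$) trades off against the intercept
terms. Rather than sampling on a constrained subspace, retained draws of
SPLTM and SPAM are post-processed: structured-effect means are removed and
folded into the level terms (for SPAM the temporal main effect carries the
level, as the model has no explicit intercept). The fitted $\log\mu_{it}$
is unchanged draw by draw — the transformation is exactly invariant — so
all reported summaries (WAIC, RMSE, MAE, coverage) are unaffected.

## Sampling

The posterior is explored with a No-U-Turn sampler: correlation parameters
are mapped to the real line by the logit, variances by the log, with
Jacobian corrections; gradients are analytic (C++ backend, verified against
finite differences in the test suite). Step size is tuned by dual averaging
toward 0.8 acceptance during burn-in, and a diagonal mass matrix is
estimated from the first half of the burn-in window. The momentum refresh
is zero-mean Gaussian — the conventional choice. Tree depth is capped at
10 doublings; non-finite trajectories are counted as divergences and the
iteration keeps the current state.

A full-scale chain uses 120,000 iterations with 20,000 burn-in and
thinning 10, retaining exactly 10,000 draws (`chain_config("full")`).
The `"desk"` profile (6,000 / 1,000 / 5, retaining 1,000 draws) is the
package's scaled-down setting for interactive work and the test suite; it
was chosen once as the smallest configuration that keeps Monte-Carlo error
in WAIC differences well below the between-model differences being
compared.

An adaptive random-walk Metropolis backend (`sampler = "rwm"`) is included
because it is bit-reproducible under a seed, which the orchestration tests
rely on; it is never the default and mixes far more slowly than NUTS on
these posteriors.

## The synthetic data generator

One replication at correlation pair $(\rho_{sp}, \rho_{tm})$ proceeds as:

1. draw per-unit 2-D coordinates iid $N(0,1)$ (the generating algorithm
   requires coordinates but does not define them; iid normal is the
   minimal structure consistent with it);
2. draw spatial noise from $N(0, \Sigma_{sp})$ and temporal noise from
   $N(0, \Sigma_{tm})$, where both covariances are equicorrelation
   (compound-symmetry) matrices — the unique exchangeable one-parameter
   structure — of dimensions $N$ and $T$;
3. the spatial term is the coordinate x-value plus spatial noise, constant
   over time within a unit; the temporal term is replicated across units;
4. the latent field $s_i + t_t$ is centered and scaled by 0.5 before
   exponentiation (without this the printed recipe can overflow; 0.5 keeps
   counts in single digits, comparable to rates after offsetting), giving
   $\lambda_{it} = \exp(\cdot)$;
5. counts are zero-truncated Poisson draws ($y_{it} \ge 1$ always — the
   generator emulates strictly positive counts; truncation, not add-one,
   preserves the stated mean relationship);
6. ten covariates are generated exactly orthogonal (QR on centered iid
   normals) and standardized, so every variance inflation factor is 1 —
   emulating principal-component covariates. They do not enter
   $\lambda$: the generating recipe has no fixed-effect term, so the true
   $\boldsymbol\beta$ is zero and the models estimate null covariate
   effects. This is faithful to the recipe and worth keeping in mind when
   interpreting the comparison;
7. the spatial adjacency is the symmetrized 4-nearest-neighbour graph of
   the coordinates (the real study used country contiguity, which has no
   synthetic counterpart).

Whether spatial noise should be redrawn every year is ambiguous in the
recipe; the replicated-noise reading is the default, with
`resample_spatial_each_time = TRUE` exposed for sensitivity analysis.
Offsets default to zero (exposure 1) and can be supplied per cell.

What the generator does *not* emulate: real border adjacency, covariates
that actually drive the intensity, missing data, and overdispersion beyond
what the latent field induces. Passing tests therefore demonstrate
correctness of the machinery and the qualitative model ordering under the
stated conditions, not performance on real surveillance data.

## Evaluation

* **WAIC** $= -2(\mathrm{lpd} - p_{\mathrm{WAIC}})$ with
  $\mathrm{lpd} = \sum_i \log \frac1S \sum_s p(y_i \mid \theta^{(s)})$
  (log-sum-exp) and the variance-based
  $p_{\mathrm{WAIC}} = \sum_i \widehat{\mathrm{Var}}_s \log p(y_i \mid
  \theta^{(s)})$. The printed formula in the source material omits the
  posterior average inside lpd; the standard definition is implemented.
* **RMSE / MAE** against posterior-mean fitted values; the standard
  "root of the mean of squared differences" form is used (the printed
  equation nests $n$ inside the square, read as a typesetting slip).
* **Coverage**: records are split 70/30; the model is fitted with the test
  cells masked out of the likelihood (their random effects then follow
  their priors given the sampled hyperparameters); equal-tailed 95%
  intervals come from one zero-truncated Poisson predictive draw of $y$
  per retained state. Credible intervals for $\mu$ instead of predictive
  intervals for $y$ are available behind `type = "mean"`, but predictive
  intervals are the default since it is $y$ that is being predicted.

## Experiment design and problem sizes

`experiment_config()` defaults are the full study design: the
$10 \times 10$ grid of correlations $0.05, 0.15, \dots, 0.95$, panels of
$54 \times 20$ (1080 records), 1000 replications per scenario, full-scale
chains. Per-replication seeds are derived by a stable hash of
(sp, tm, rep), so any scenario is reproducible in isolation, and grid runs
are resumable from the incremental CSV they write.

The package's own scaled-down runs — used in the test suite and the
bundled acceptance script — use a $3 \times 3$ grid
($\{0.05, 0.5, 0.95\}^2$), panels of $20 \times 10$, 5 replications and
desk-profile chains. Those sizes were fixed once as the smallest design in
which the headline ordering (SPAM's mean WAIC below SPLTM's in most
scenarios) and the coverage floor are stable across seeds. Parameter
recovery checks run at $N = 15$, $T = 8$ with $p = 3$ covariates injected
through the linear predictor.

## Numerical choices and degenerate inputs

* $\rho = 1$ is rejected in joint-density evaluation (improper); samplers
  work on the open interval via the logit transform.
* Isolated units are allowed; their CAR conditionals reduce to
  $N(0, k^2/(1-\rho))$.
* Moran's I is reported unclamped; slightly out-of-[−1, 1] values are
  possible for unusual weight configurations and are not an error.
* Exactly collinear covariates give infinite VIF with a warning.
* A single retained draw gives $p_{\mathrm{WAIC}} = 0$ with a warning.
* Ties in the model ranking break by mean RMSE, then model name.
* Replication-level chain failures are excluded from aggregates and
  counted, never imputed.
* The latent field is rescaled (with a warning) if it exceeds ±10 before
  exponentiation.

## Known limitations

* The full 100-scenario × 1000-replication × 120,000-iteration experiment
  is supported but not exercised anywhere in the package's own runs; the
  absolute WAIC magnitudes of the original study depend on scale choices
  (latent scaling, offsets, adjacency) that its description leaves open,
  so only the relative ordering of models is expected to transfer.
* Divergences at small variance values (the usual funnel geometry of
  hierarchical models) occur at low rates in the desk profile; a
  non-centered parameterization would remove them at the cost of a more
  opaque mapping to the model statements, and is left as future work.
* No negative-binomial or zero-inflated observation layers, no
  row-standardized or distance-decay weights, no GIS handling.

## A worked example

```{r example, eval = FALSE}
scen <- scenario(sp = 0.5, tm = 0.5, n_units = 20, n_times = 10, seed = 42)
panel <- generate_panel(scen)
pd <- as_panel_data(panel)
fit <- run_chain("SPAM", pd, config = chain_config("desk", seed = 7))
waic(fit)
yhat <- point_predictions(fit, pd)
c(rmse = rmse(pd$y, yhat), mae = mae(pd$y, yhat))
```

See the README for the printed output of this example and for how to
reproduce the scaled-down study with `scripts/acceptance.R`.
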