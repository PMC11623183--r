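---
title: "Estimating simultaneous-equation models as masked linear networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating simultaneous-equation models as masked linear networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsgd)
```

## The model

A linear simultaneous-equation model (SEM) relates $m$ endogenous variables
$y_1, \dots, y_m$ to each other and to $k$ exogenous variables
$x_1, \dots, x_k$, one equation per endogenous variable:

$$y_i \;=\; \sum_{j \neq i} \tilde B_{ij}\, y_j \;+\; \sum_{r=1}^k \Gamma_{ir}\, x_r \;+\; u_i,
\qquad i = 1, \dots, m,$$

with white-noise disturbances $u_i$. Part of the model is a sparsity
structure: some coefficients are known to be zero a priori, and `sem_spec()`
records exactly that as a pair of inclusion masks. In matrix form
$Y = Y \tilde B^T + X \Gamma^T + U$, and whenever $(I - \tilde B^T)$ is
invertible the system has the reduced form

$$Y = X \Pi + V, \qquad \Pi = \Gamma^T (I - \tilde B^T)^{-1}, \qquad
V = U (I - \tilde B^T)^{-1}.$$

The package stores $\tilde B$ (zero diagonal) rather than the equivalent
textbook matrix $B = \tilde B - I$; the two conventions differ only by the
diagonal and a sign, and fixing one removes a recurring source of sign errors.
`reduced_form()` converts. There are no intercepts anywhere — generation,
estimation and prediction are all through the origin; users who want a
constant add a constant column to $X$ themselves (and must then not
standardize it).

Because endogenous regressors are correlated with the disturbances,
per-equation OLS is biased under simultaneity. The classical remedy
implemented here from scratch is two-stage least squares: first project every
endogenous variable on all $k$ exogenous columns (every exogenous variable
instruments every equation — no external instruments are supported), then run
per-equation OLS with the fitted values standing in for the observed
endogenous regressors.

## The network view and the SGD estimator

The same system can be read as a single-layer linear network: one output
neuron per endogenous variable, inputs $x_1 \dots x_k$, connection weights
$\Gamma$, and lateral connections $\tilde B$ between the outputs. The a-priori
zeros are a weight mask. `fit_sgd()` trains the free weights by plain
mini-batch stochastic gradient descent on the mean-squared error

$$L = \frac{1}{b\,m} \sum_{t=1}^{b} \sum_{i=1}^m (y_{ti} - \hat y_{ti})^2$$

over batches of $b$ rows, with element-wise gradient clipping and no early
stopping. Two readings of $\hat y$ are implemented, because the lateral
connections make the network recurrent and a choice has to be made:

* **teacher-forced** (`target = "structural"`, the default): observed values
  of the other endogenous variables feed each equation,
  $\hat y_i = \sum_j \tilde B_{ij} y_j^{obs} + \sum_r \Gamma_{ir} x_r$. This
  matches the network wiring in which the output neurons exchange observed
  signals, and it makes the loss convex in the weights — its exact minimizer
  is per-equation OLS, which is what the convex-limit tests exploit.
* **reduced** (`target = "reduced"`): the system is solved first,
  $\hat Y = X \Pi(\tilde B, \Gamma)$, a pure input-to-output network. The
  gradient then involves $(I - \tilde B^T)^{-1}$ and the loss is no longer
  convex.

Both targets have analytic gradients (`loss_gradient()`), verified against
central finite differences in the test suite. Predictions for scoring are
likewise available in both modes via `predict(params, data, mode = )`, and the
benchmark reports both side by side, since which mode a validation MSE refers
to changes its meaning entirely (teacher-forced scoring conditions on the
observed outcomes; reduced scoring does not).

### Hyper-parameter defaults

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.01 | step size (use 1e-5 with 10000 iterations for the slow regime) |
| `batch_size` | 32 | rows per update, drawn uniformly without replacement per iteration |
| `n_iterations` | 5000 | weight updates ("iteration" = one mini-batch update, not one epoch) |
| `clip_value` | 0.5 | element-wise gradient clipping bound; `Inf` disables |
| `init` | `"twostage"` | warm start at the 2SLS fit; `"random"` draws free weights $N(0, 0.1^2)$ |

The random-initialization scale $N(0, 0.1^2)$ is the conventional small-weight
choice; anything on the scale of the coefficients themselves diverges
instantly on unstandardized data. Batch sampling is without replacement
within a batch and independent across iterations (no epoch shuffling).
Clipping is applied to each gradient entry after the gradient computation and
before the update. A non-finite loss aborts with an error pointing at the
learning rate and standardization rather than returning garbage.

## The synthetic generator

`sim_config()` + `simulate_sem()` emulate a fully seeded Monte-Carlo design:
structural coefficients drawn $\mathrm{Uniform}[0, 10]$, $X$ with i.i.d.
standard-normal entries (mean zero, identity covariance — the minimal reading
of "multivariate normal", and configurable in principle through the coefficient
range if correlated designs are ever needed), reduced-form noise
$V \sim N(0, \sigma^2)$ with $\sigma \in \{0.1, 1.0\}$ in the reference grid,
and sample sizes $n \in \{100, 1000\}$. `benchmark_grid()` returns the 12-cell
grid $(m,k) \in \{(2,4), (10,20), (20,40)\} \times \sigma \times n$.

Design choices that were genuinely open:

* **Mask sparsity.** Which coefficients are a-priori zero is part of the
  model, but nothing pins down a distribution for it. Each entry is included
  independently with probability 0.5 (`p_endo`, `p_exo`), and draws are
  rejected until the structure is estimable.
* **Identifiability screening.** Rejection enforces the order condition
  (each equation's excluded exogenous count must reach its endogenous
  regressor count) *and* a generic rank-condition screen: the population
  stage-2 design, evaluated at a generic coefficient draw, must have full
  column rank for every equation. The order condition alone admits structures
  whose nominal instruments never reach the regressors they are supposed to
  instrument — e.g. an instrument excluded from every equation of the system —
  and 2SLS is exactly collinear on those at any sample size. Since the rank of
  a structured matrix at one generic parameter point equals its structural
  maximum almost surely, a single randomized evaluation suffices.
* **Conditioning guard.** $\mathrm{Uniform}[0,10]$ entries in $\tilde B$
  routinely put eigenvalues of $\tilde B^T$ near 1, making
  $(I - \tilde B^T)$ near-singular and the reduced-form scale explode
  (especially at $m = 20$). Coefficient draws are therefore rejected until
  $\mathrm{cond}(I - \tilde B^T) \le$ `cond_limit` ($10^6$ by default, the
  same threshold at which the algebra routines refuse to invert).
* **Seeding.** One master seed deterministically derives named sub-streams
  (spec, coefficients, $X$, noise, split, initialization, batching) via a
  small string-hash, so every stage is independently reproducible and the
  whole pipeline is bit-identical under a repeated seed.

What the generator does **not** emulate: correlated or non-Gaussian designs,
heteroskedastic or autocorrelated disturbances, intercepts, weak-instrument
regimes, or misspecified masks. Tests passing on this generator say nothing
about robustness to any of those; they establish correctness of the algebra
and the optimizers under the stated model.

## Evaluation protocol

`run_benchmark()` scores estimators by validation MSE
$\frac{1}{nm}\sum\sum (Y - \hat Y)^2$ across the grid. Two protocols ship:

* **unified** (default): every estimator fits on the same 70% split and is
  scored on the same 30% split — the fair comparison.
* **asymmetric**: 2SLS fits on the full dataset and is scored on a random
  300-row subsample while SGD uses the 70/30 split. This uneven design exists
  for replication of a common historical setup; its 2SLS scores are partially
  in-sample.

Standardization (z-scoring all columns with *training-set* statistics, applied
unchanged to held-out rows) is on by default and applied identically to both
methods. It is not cosmetic: on raw $\mathrm{Uniform}[0,10]$-coefficient
systems the endogenous columns span thousands of units, SGD at learning rate
0.01 diverges, and MSEs across cells are incomparable. All reported MSEs state
their scale in the report settings. Repetition failures (e.g. a draw that
exhausts its retry budget) are counted in `n_fail` and excluded from the
averages rather than aborting the sweep; with the generator's screening they
do not occur in the default grid.

A consequence of this generator worth stating explicitly, because both the
test suite and the acceptance script compute it: under the stated design,
reduced-form 2SLS validation MSE sits essentially at the irreducible noise
floor ($\sigma^2$, rescaled by standardization), while teacher-forced
predictions carry the structural disturbance $u = V(I - \tilde B^T)$, whose
variance the large coefficients amplify. Teacher-forced SGD therefore does
*not* beat reduced-form 2SLS here — the win fraction the acceptance script
reports is typically 0/10. A published ordering in the opposite direction
cannot arise from this noise model on any fixed scale; reproducing it would
require undocumented preprocessing, which this package does not guess at.

## Numerical choices

* Least-squares solves use rank-revealing QR (`qr()`/`qr.coef()`); a
  rank-deficient design is an error naming the equation, never a silent
  pseudo-inverse — except for explicitly opted-in underidentified equations
  (`allow_underidentified = TRUE`), which return the minimum-norm SVD solution
  with a warning.
* $(I - \tilde B^T)$ is declared ill-conditioned at 2-norm condition number
  $> 10^6$; `reduced_form()` and the constructors refuse beyond it, reporting
  the estimate.
* Masked entries are exactly 0 by construction everywhere (the optimizer
  zeroes masked gradients; estimators only ever fill included slots), so mask
  conservation is an identity, not a tolerance.
* Tolerances in the test suite: residual round trips are checked relative to
  the magnitude of $Y$ (raw $\mathrm{Uniform}[0,10]$ systems at $m = 20$ reach
  $|Y| \sim 10^4$, where absolute $10^{-10}$ would be below representable
  precision); estimator-vs-oracle agreement is $10^{-8}$ relative against an
  SVD-based solver.
* Degenerate inputs: specs must give every equation at least one regressor;
  datasets must be finite; splits must leave both parts nonempty;
  zero-variance columns fail standardization by name.

The test suite runs the full 12-cell benchmark skeleton at 500 SGD iterations
per fit (the trainer's cost is linear in iterations and the skeleton checks
protocol mechanics, not convergence, which the dedicated convergence tests
cover at the full 5000), and Monte-Carlo checks use 10–20 repetitions — sizes
chosen so the whole suite stays in the tens of seconds while keeping
sampling-error bounds (3 standard errors) meaningful.

## Known limitations

* Only the order + generic-rank screen guards identifiability; pathological
  near-violations (weak instruments) can still produce noisy 2SLS draws, which
  is real statistics, not a defect.
* The SGD trainer is plain SGD by design — no momentum, schedules, or adaptive
  variants — so its convergence on badly scaled data is poor; standardize.
* Underidentified equations are refused by default. The minimum-norm opt-in
  exists to keep classic textbook examples runnable, but its coefficients for
  those equations are not consistent estimates of anything.
* The covariance-based "structural equation modelling" of psychometrics,
  nonlinear systems, and dynamic/time-series models are out of scope.
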