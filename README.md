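# semsgd

Estimation of linear simultaneous-equation models (SEM) by viewing the system
as a masked single-layer linear network trained with mini-batch stochastic
gradient descent, next to a from-scratch two-stage least-squares (2SLS)
baseline and a fully seeded Monte-Carlo benchmark harness.

## The problem

A linear SEM relates m endogenous variables to each other and to k exogenous
variables, one equation per endogenous variable:

    y_i = Σ_{j≠i} B̃_ij y_j + Σ_r Γ_ir x_r + u_i

with a known sparsity structure (some coefficients are zero a priori) and
white-noise disturbances u_i. In matrix form Y = Y B̃ᵀ + X Γᵀ + U, with
reduced form Y = X Π + V, Π = Γᵀ (I − B̃ᵀ)⁻¹. Because endogenous regressors
are correlated with the disturbances, per-equation OLS is biased; 2SLS
instruments each equation with the excluded exogenous variables. This package
additionally treats the SEM as a one-layer linear network — output neurons are
the endogenous variables, the a-priori zeros are a weight mask — and estimates
the free coefficients by plain SGD on the mean-squared error
(1/(n·m)) ΣΣ (Y − Ŷ)², with element-wise gradient clipping and either a
random or a 2SLS warm-start initialization.

It is aimed at econometricians and applied modellers (epidemiology, health
economics, social science) who want a reproducible sandbox for comparing
classical and gradient-based SEM estimators under a controlled synthetic
design: coefficients ~ Uniform[0, 10], Gaussian designs, noise
σ ∈ {0.1, 1.0}, n ∈ {100, 1000}, model sizes up to m = 20, k = 40.

Everything is data-frame-in / tibble-out, with broom-style `tidy()` /
`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(semsgd)

# a random identified two-equation system, n = 1000, noise sd 0.1
inst <- simulate_sem(sim_config(m = 2, k = 4, n = 1000, sigma = 0.1, seed = 42))
inst$spec
#> <sem_spec> 2 endogenous, 4 exogenous variables
#>   free coefficients: 2 endogenous, 4 exogenous
#>   identification:  eq1 overidentified, eq2 exactly_identified

# 2SLS on the raw data recovers the generating coefficients
fit2 <- fit_2sls(inst$data, inst$spec)
tidy(fit2)
#>   equation term estimate  truth
#> 1        1   y2 4.812418 4.8299
#> 2        1   x4 2.350127 2.3634
#> 3        2   y1 5.248257 5.3325
#> 4        2   x1 3.691658 3.7530
#> 5        2   x2 2.863319 2.9043
#> 6        2   x3 4.421073 4.5003
```

(the `truth` column above is `inst$params` aligned next to the estimates for
display). The estimates sit within sampling error of the generating values —
the consistency tests verify this error shrinks as n grows.

The SGD pathway works on standardized data — on the raw Uniform[0,10]
coefficient scale the loss surface is too badly conditioned for learning rate
0.01:

```r
parts  <- split_dataset(inst$data, 0.7, seed = 42)   # 700 train / 300 validation
scaler <- fit_scaler(parts$train)
train  <- standardize(parts$train, scaler)
valid  <- standardize(parts$validation, scaler)

fits <- fit_sgd(train, inst$spec, sgd_config(init = "twostage", seed = 1))
glance(fits)
#>   method     m     k n_free final_loss elapsed
#> 1 sgd        2     4      6      0.344   0.81

mse(as.matrix(valid[c("y1", "y2")]),
    predict(fits$params, valid, mode = "reduced"))
#> [1] 0.02008822      # 2SLS scores 0.01607865 on the same split
```

`autoplot(fits)` draws the training-loss trace; `run_benchmark()` sweeps the
full 12-cell grid (`benchmark_grid()`) over repetitions and returns a tibble
of average/std validation MSE per cell, method, initialization and prediction
mode, with `autoplot()` bar charts. A command-line front end covers the same
pipeline:

```sh
semsgd simulate  --m 2 --k 4 --n 1000 --sigma 0.1 --seed 7 \
                 --out data.csv --params model.json
semsgd fit       --method sgd --init 2sls --data data.csv \
                 --spec model.json --out fit.json --standardize
semsgd benchmark --config bench.yaml --out report.csv
```

(the `semsgd` script is installed under `inst/cli/`).

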