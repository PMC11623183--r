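# Independent oracles and small fixtures used across the suite. These stay
# deliberately naive (loops, normal equations, finite differences) so they do
# not share code paths with the implementation they check.

# the worked two-equation system: eq 1 includes y2, x1, x2, x4 (excludes x3);
# eq 2 includes y1 and all four exogenous variables
two_equation_spec <- function() {
  sem_spec(
    m = 2, k = 4,
    endo_mask = matrix(c(FALSE, TRUE,
                         TRUE, FALSE), 2, 2, byrow = TRUE),
    exo_mask = matrix(c(1, 1, 0, 1,
                        1, 1, 1, 1), 2, 4, byrow = TRUE)
  )
}

# element-by-element structural residual: u_ti = y_ti - sum_j B y_tj - sum_r G x_tr
residuals_loop_oracle <- function(params, X, Y) {
  m <- params$spec$m
  U <- matrix(0, nrow(Y), m)
  for (t in seq_len(nrow(Y))) {
    for (i in seq_len(m)) {
      U[t, i] <- Y[t, i] - sum(params$B[i, ] * Y[t, ]) - sum(params$Gamma[i, ] * X[t, ])
    }
  }
  U
}

# per-equation OLS by explicit normal equations (Gram-matrix solve)
ols_normal_equations_oracle <- function(spec, X, Y) {
  coefs <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    A <- cbind(Y[, spec$endo_mask[i, ], drop = FALSE],
               X[, spec$exo_mask[i, ], drop = FALSE])
    coefs[[i]] <- solve(t(A) %*% A, t(A) %*% Y[, i])
  }
  coefs
}

# SVD-based least squares: an accurate solver on a different factorization
# than the implementation's QR path
svd_lstsq_oracle <- function(A, y) {
  sv <- svd(A)
  drop(sv$v %*% ((t(sv$u) %*% y) / sv$d))
}

# literal stage-by-stage 2SLS: both regressions via the SVD solver
tsls_stagewise_oracle <- function(spec, X, Y) {
  Yhat <- X %*% apply(Y, 2, function(y) svd_lstsq_oracle(X, y))
  coefs <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    A <- cbind(Yhat[, spec$endo_mask[i, ], drop = FALSE],
               X[, spec$exo_mask[i, ], drop = FALSE])
    coefs[[i]] <- svd_lstsq_oracle(A, Y[, i])
  }
  coefs
}

# flatten an estimated sem_params to the per-equation coefficient layout the
# oracles return: [endo coefs, exo coefs] per equation
params_coef_list <- function(params) {
  spec <- params$spec
  lapply(seq_len(spec$m), function(i) {
    c(params$B[i, spec$endo_mask[i, ]], params$Gamma[i, spec$exo_mask[i, ]])
  })
}

# central finite differences of the batch loss in every free coordinate
fd_gradient_oracle <- function(params, X, Y, target = "structural", h = 1e-6) {
  spec <- params$spec
  loss_at <- function(B, G) {
    p <- params
    p$B <- B
    p$Gamma <- G
    loss_gradient(p, X, Y, target = target)$loss
  }
  gB <- matrix(0, spec$m, spec$m)
  gG <- matrix(0, spec$m, spec$k)
  for (idx in which(spec$endo_mask)) {
    Bp <- params$B; Bp[idx] <- Bp[idx] + h
    Bm <- params$B; Bm[idx] <- Bm[idx] - h
    gB[idx] <- (loss_at(Bp, params$Gamma) - loss_at(Bm, params$Gamma)) / (2 * h)
  }
  for (idx in which(spec$exo_mask)) {
    Gp <- params$Gamma; Gp[idx] <- Gp[idx] + h
    Gm <- params$Gamma; Gm[idx] <- Gm[idx] - h
    gG[idx] <- (loss_at(params$B, Gp) - loss_at(params$B, Gm)) / (2 * h)
  }
  list(grad_B = gB, grad_Gamma = gG)
}

# matrices straight from a dataset tibble (unnamed, like the package returns)
ymat <- function(data, m) unname(as.matrix(as.data.frame(data)[paste0("y", seq_len(m))]))
xmat <- function(data, k) unname(as.matrix(as.data.frame(data)[paste0("x", seq_len(k))]))

# a moderate, well-behaved random instance for unit tests
test_instance <- function(seed, m = 3, k = 6, n = 200, sigma = 0.1) {
  simulate_sem(sim_config(m = m, k = k, n = n, sigma = sigma, seed = seed))
}
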