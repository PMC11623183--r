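new_sem_fit <- function(params, method, hyper = list(), trace = NULL, timing = NA_real_) {
  structure(
    list(params = params, method = method, hyper = hyper, trace = trace,
         timing = timing),
    class = "sem_fit"
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> method=%s, m=%d, k=%d\n",
              x$method, x$params$spec$m, x$params$spec$k))
  if (!is.null(x$trace)) {
    cat(sprintf("  trace: %d points, final training loss %.6g\n",
                nrow(x$trace), utils::tail(x$trace$loss, 1)))
  }
  invisible(x)
}

# rank-checked least squares: solve min ||A b - y|| via QR, error if A is
# rank deficient (tolerance: LAPACK-style relative to the largest column norm)
lstsq <- function(A, y, context = "design matrix") {
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop(sprintf("estimation error: %s is rank deficient (rank %d < %d columns).",
                 context, qrA$rank, ncol(A)), call. = FALSE)
  }
  qr.coef(qrA, y)
}

# place per-equation coefficient vectors into full B / Gamma matrices
assemble_params <- function(spec, coef_list) {
  B <- matrix(0, spec$m, spec$m)
  Gamma <- matrix(0, spec$m, spec$k)
  for (i in seq_len(spec$m)) {
    je <- which(spec$endo_mask[i, ])
    jx <- which(spec$exo_mask[i, ])
    b <- coef_list[[i]]
    if (length(je) > 0) B[i, je] <- b[seq_along(je)]
    if (length(jx) > 0) Gamma[i, jx] <- b[length(je) + seq_along(jx)]
  }
  sem_params(spec, B, Gamma)
}

#' Per-equation ordinary least squares on the structural form
#'
#' For each equation i, regresses `y_i` on its included regressors — the
#' observed endogenous columns `y_j` with `endo_mask[i, j]` and the exogenous
#' columns with `exo_mask[i, r]` — by least squares. OLS ignores the
#' simultaneity (observed endogenous regressors are correlated with the
#' disturbance), so it is biased under simultaneity but is the exact minimizer
#' of the teacher-forced squared-error loss; it is the convex reference point
#' for the SGD trainer.
#'
#' @param data Data frame with `y1..ym`, `x1..xk` columns.
#' @param spec A [sem_spec()].
#' @return A `sem_fit` with `method = "ols"`.
#' @export
fit_ols <- function(data, spec) {
  stopifnot(inherits(spec, "sem_spec"))
  mats <- dataset_matrices(data, spec)
  t0 <- proc.time()[["elapsed"]]
  coefs <- purrr::map(seq_len(spec$m), function(i) {
    A <- cbind(mats$Y[, spec$endo_mask[i, ], drop = FALSE],
               mats$X[, spec$exo_mask[i, ], drop = FALSE])
    lstsq(A, mats$Y[, i], context = sprintf("equation %d design matrix", i))
  })
  new_sem_fit(assemble_params(spec, coefs), "ols",
              timing = proc.time()[["elapsed"]] - t0)
}

#' Two-stage least squares
#'
#' Stage 1 regresses every endogenous variable on all `k` exogenous columns,
#' giving fitted values \eqn{\hat Y = X (X^T X)^{-1} X^T Y} (every exogenous
#' variable instruments every equation). Stage 2 runs, per equation, OLS of
#' `y_i` on the stage-1 fitted values of its included endogenous regressors
#' plus its included exogenous columns. Consistent under simultaneity where
#' per-equation OLS is not.
#'
#' Equations that fail the order condition are refused by default; with
#' `allow_underidentified = TRUE` a minimum-norm least-squares solution is
#' returned for such equations and a warning is issued.
#'
#' @param data Data frame with `y1..ym`, `x1..xk` columns.
#' @param spec A [sem_spec()].
#' @param allow_underidentified Opt in to minimum-norm fits of underidentified
#'   equations.
#' @return A `sem_fit` with `method = "2sls"`.
#' @export
fit_2sls <- function(data, spec, allow_underidentified = FALSE) {
  stopifnot(inherits(spec, "sem_spec"))
  ident <- identification(spec)
  bad <- ident$equation[ident$status == "underidentified"]
  if (length(bad) > 0 && !allow_underidentified) {
    stop("identification error: equation(s) ", paste(bad, collapse = ", "),
         " fail the order condition (",
         paste(sprintf("eq %d: %d excluded exogenous < %d endogenous regressors",
                       bad, ident$n_excl_exo[bad], ident$n_endo[bad]),
               collapse = "; "),
         "). Set `allow_underidentified = TRUE` for a minimum-norm fit.",
         call. = FALSE)
  }
  mats <- dataset_matrices(data, spec)
  t0 <- proc.time()[["elapsed"]]
  # stage 1: project Y on the full exogenous design
  Yhat <- mats$X %*% lstsq(mats$X, mats$Y, context = "stage-1 exogenous design")
  coefs <- purrr::map(seq_len(spec$m), function(i) {
    A <- cbind(Yhat[, spec$endo_mask[i, ], drop = FALSE],
               mats$X[, spec$exo_mask[i, ], drop = FALSE])
    if (i %in% bad) {
      warning(sprintf("equation %d is underidentified; returning a minimum-norm fit.", i),
              call. = FALSE)
      return(minimum_norm_lstsq(A, mats$Y[, i]))
    }
    lstsq(A, mats$Y[, i], context = sprintf("equation %d stage-2 design", i))
  })
  new_sem_fit(assemble_params(spec, coefs), "2sls",
              hyper = list(allow_underidentified = allow_underidentified),
              timing = proc.time()[["elapsed"]] - t0)
}

# pseudoinverse solution (smallest-norm least-squares), for opted-in
# underidentified equations whose stage-2 design is collinear
minimum_norm_lstsq <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
}
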