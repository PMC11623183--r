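#' Structural coefficients of a simultaneous-equation model
#'
#' Holds the coefficient matrices of the structural form
#' \eqn{Y = Y \tilde B^T + X \Gamma^T + U}: `B` is the `m x m` matrix of
#' endogenous-on-endogenous coefficients \eqn{\tilde B} (zero diagonal) and
#' `Gamma` the `m x k` matrix of exogenous coefficients. Entries whose mask in
#' `spec` is `FALSE` must be exactly zero, and \eqn{(I - \tilde B^T)} must be
#' invertible so the reduced form exists. The textbook matrix form
#' \eqn{Y B^T + X \Gamma^T + U = 0} uses \eqn{B = \tilde B - I}; only
#' \eqn{\tilde B} is stored, which removes the sign/diagonal ambiguity between
#' the two conventions.
#'
#' @param spec A [sem_spec()].
#' @param B Numeric `m x m` matrix \eqn{\tilde B}; zero diagonal.
#' @param Gamma Numeric `m x k` matrix.
#' @return An object of class `sem_params`.
#' @export
sem_params <- function(spec, B, Gamma) {
  stopifnot(inherits(spec, "sem_spec"))
  B <- as.matrix(B)
  Gamma <- as.matrix(Gamma)
  if (!all(dim(B) == c(spec$m, spec$m))) stop("`B` must be m x m.", call. = FALSE)
  if (!all(dim(Gamma) == c(spec$m, spec$k))) stop("`Gamma` must be m x k.", call. = FALSE)
  if (anyNA(B) || anyNA(Gamma) || any(!is.finite(B)) || any(!is.finite(Gamma))) {
    stop("coefficients must be finite.", call. = FALSE)
  }
  if (any(B[!spec$endo_mask] != 0)) {
    stop("masked entries of `B` (including the diagonal) must be exactly zero.",
         call. = FALSE)
  }
  if (any(Gamma[!spec$exo_mask] != 0)) {
    stop("masked entries of `Gamma` must be exactly zero.", call. = FALSE)
  }
  kappa <- struct_condition(B)
  if (!is.finite(kappa) || kappa > 1e6) {
    stop(sprintf(
      "algebra error: (I - B^T) is singular or ill-conditioned (condition estimate %.3g).",
      kappa), call. = FALSE)
  }
  dimnames(B) <- dimnames(Gamma) <- NULL
  structure(list(spec = spec, B = B, Gamma = Gamma), class = "sem_params")
}

# 2-norm condition estimate of (I - B^T)
struct_condition <- function(B) {
  A <- diag(nrow(B)) - t(B)
  s <- svd(A, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

#' @export
print.sem_params <- function(x, ...) {
  cat(sprintf("<sem_params> m=%d, k=%d; %d free coefficients\n",
              x$spec$m, x$spec$k, sum(x$spec$endo_mask) + sum(x$spec$exo_mask)))
  invisible(x)
}

#' Reduced form of a structural model
#'
#' Solves the simultaneity out of the system: from
#' \eqn{Y(I - \tilde B^T) = X \Gamma^T + U} the reduced form is
#' \eqn{Y = X \Pi + V} with \eqn{\Pi = \Gamma^T (I - \tilde B^T)^{-1}}
#' (`k x m`) and \eqn{V = U (I - \tilde B^T)^{-1}}. Equivalent to the
#' \eqn{-\Gamma^T (B^T)^{-1}} form under \eqn{B = \tilde B - I}.
#'
#' @param params A [sem_params()].
#' @return A `k x m` matrix `Pi`.
#' @export
reduced_form <- function(params) {
  stopifnot(inherits(params, "sem_params"))
  m <- params$spec$m
  A <- diag(m) - t(params$B)
  kappa <- struct_condition(params$B)
  if (!is.finite(kappa) || kappa > 1e6) {
    stop(sprintf(
      "algebra error: (I - B^T) is singular or ill-conditioned (condition estimate %.3g).",
      kappa), call. = FALSE)
  }
  # Pi = Gamma^T %*% solve(A): solve A^T Pi^T = Gamma row-space instead of
  # forming the inverse
  t(solve(t(A), params$Gamma))
}

#' Structural residuals U = Y - Y B^T - X Gamma^T
#'
#' Recovers the per-equation white-noise disturbances implied by a coefficient
#' set on observed data; zero (to rounding) when the data were simulated
#' noiselessly from the same coefficients.
#'
#' @param data A data frame with columns `y1..ym` and `x1..xk`.
#' @param params A [sem_params()].
#' @return A numeric `n x m` matrix of residuals, one column per equation.
#' @export
structural_residuals <- function(data, params) {
  stopifnot(inherits(params, "sem_params"))
  mats <- dataset_matrices(data, params$spec)
  mats$Y - mats$Y %*% t(params$B) - mats$X %*% t(params$Gamma)
}

#' Predict endogenous variables from a coefficient set
#'
#' Two prediction modes mirror the two ways of reading the system.
#' `mode = "reduced"` solves the system: \eqn{\hat Y = X \Pi}, using exogenous
#' columns only. `mode = "structural"` is the teacher-forced network view
#' (the one-layer network in which observed endogenous values feed the other
#' equations): \eqn{\hat y_i = \sum_j \tilde B_{ij} y_j^{obs} + \sum_r
#' \Gamma_{ir} x_r}, requiring observed `y` columns in `newdata`.
#'
#' @param object A [sem_params()].
#' @param newdata Data frame with `x1..xk` columns; `mode = "structural"` also
#'   requires `y1..ym`.
#' @param mode `"reduced"` or `"structural"`.
#' @param ... Unused.
#' @return A numeric `n x m` matrix of predictions.
#' @export
predict.sem_params <- function(object, newdata, mode = c("reduced", "structural"), ...) {
  mode <- match.arg(mode)
  spec <- object$spec
  X <- extract_cols(newdata, "x", spec$k)
  if (mode == "reduced") {
    return(X %*% reduced_form(object))
  }
  if (!all(paste0("y", seq_len(spec$m)) %in% names(newdata))) {
    stop("usage error: mode = \"structural\" requires observed `y` columns in `newdata`.",
         call. = FALSE)
  }
  Y <- extract_cols(newdata, "y", spec$m)
  Y %*% t(object$B) + X %*% t(object$Gamma)
}

# ---- data-frame <-> matrix plumbing --------------------------------------

extract_cols <- function(data, prefix, count) {
  cols <- paste0(prefix, seq_len(count))
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("shape error: data is missing column(s) ", paste(missing, collapse = ", "),
         ".", call. = FALSE)
  }
  M <- as.matrix(as.data.frame(data)[cols])
  if (!is.numeric(M)) stop("data columns must be numeric.", call. = FALSE)
  if (any(!is.finite(M))) stop("data contains non-finite entries.", call. = FALSE)
  dimnames(M) <- NULL
  M
}

dataset_matrices <- function(data, spec) {
  X <- extract_cols(data, "x", spec$k)
  Y <- extract_cols(data, "y", spec$m)
  if (nrow(X) != nrow(Y) || nrow(X) < 1) {
    stop("shape error: X and Y must have the same, positive number of rows.",
         call. = FALSE)
  }
  list(X = X, Y = Y)
}

# assemble a dataset tibble from matrices
as_dataset <- function(X, Y) {
  colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::as_tibble(Y), tibble::as_tibble(X))
}
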