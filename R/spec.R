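#' Declare the sparsity structure of a simultaneous-equation model
#'
#' A linear SEM with `m` endogenous and `k` exogenous variables is written, one
#' equation per endogenous variable, as
#' \deqn{y_i = \sum_{j \ne i} \tilde B_{ij} y_j + \sum_r \Gamma_{ir} x_r + u_i.}
#' Which coefficients are free and which are a-priori zero is part of the model:
#' `endo_mask[i, j]` is `TRUE` iff \eqn{y_j} appears as a regressor in equation
#' `i`, and `exo_mask[i, r]` iff \eqn{x_r} does. The diagonal of `endo_mask`
#' must be `FALSE` (a variable never regresses on itself) and every equation
#' must include at least one regressor.
#'
#' @param m Number of endogenous variables (>= 1).
#' @param k Number of exogenous variables (>= 1).
#' @param endo_mask Logical (or 0/1) `m x m` matrix of endogenous inclusions.
#' @param exo_mask Logical (or 0/1) `m x k` matrix of exogenous inclusions.
#' @param names Optional list with character vectors `endo` (length `m`) and
#'   `exo` (length `k`) of display labels. Data columns are always addressed as
#'   `y1..ym`, `x1..xk`; labels are cosmetic.
#'
#' @return An object of class `sem_spec`.
#' @examples
#' # two-equation demand/supply-style system: eq 1 excludes x3
#' spec <- sem_spec(
#'   m = 2, k = 4,
#'   endo_mask = matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE),
#'   exo_mask  = matrix(c(1, 1, 0, 1,
#'                        1, 1, 1, 1), 2, 4, byrow = TRUE)
#' )
#' identification(spec)
#' @export
sem_spec <- function(m, k, endo_mask, exo_mask, names = NULL) {
  if (length(m) != 1L || length(k) != 1L || m < 1 || k < 1) {
    stop("`m` and `k` must be single counts >= 1.", call. = FALSE)
  }
  m <- as.integer(m)
  k <- as.integer(k)
  endo_mask <- as_mask(endo_mask, m, m, "endo_mask")
  exo_mask <- as_mask(exo_mask, m, k, "exo_mask")
  if (any(diag(endo_mask))) {
    stop("specification error: `endo_mask` has TRUE on its diagonal; ",
         "a variable cannot regress on itself.", call. = FALSE)
  }
  empty <- !(rowSums(endo_mask) + rowSums(exo_mask) > 0)
  if (any(empty)) {
    stop("specification error: equation(s) ", paste(which(empty), collapse = ", "),
         " include no regressor at all.", call. = FALSE)
  }
  if (!is.null(names)) {
    stopifnot(is.list(names), length(names$endo) == m, length(names$exo) == k)
  }
  structure(
    list(m = m, k = k, endo_mask = endo_mask, exo_mask = exo_mask, names = names),
    class = "sem_spec"
  )
}

as_mask <- function(x, nr, nc, what) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(nr, nc))) {
    stop(sprintf("specification error: `%s` must be %d x %d.", what, nr, nc),
         call. = FALSE)
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop(sprintf("specification error: numeric `%s` must contain only 0/1.", what),
           call. = FALSE)
    }
    x <- x == 1
  }
  storage.mode(x) <- "logical"
  if (anyNA(x)) stop(sprintf("`%s` contains NA.", what), call. = FALSE)
  dimnames(x) <- NULL
  x
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("<sem_spec> %d endogenous, %d exogenous variables\n", x$m, x$k))
  st <- identification(x)
  cat(sprintf("  free coefficients: %d endogenous, %d exogenous\n",
              sum(x$endo_mask), sum(x$exo_mask)))
  cat("  identification: ",
      paste(sprintf("eq%d %s", st$equation, st$status), collapse = ", "), "\n")
  invisible(x)
}

#' Order-condition identification status, one row per equation
#'
#' An equation with `m_i` included endogenous regressors and `k_i` included
#' exogenous regressors is identified by the order condition only if the number
#' of excluded exogenous variables, `k - k_i`, is at least `m_i` (those excluded
#' exogenous variables are the instruments available to it). The condition is
#' necessary, not sufficient; it is the standard feasibility screen for 2SLS.
#'
#' @param spec A [sem_spec()].
#' @return A tibble with columns `equation`, `n_endo` (included endogenous
#'   regressors), `n_incl_exo`, `n_excl_exo`, and `status` (one of
#'   `"underidentified"`, `"exactly_identified"`, `"overidentified"`).
#' @export
identification <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  n_endo <- rowSums(spec$endo_mask)
  n_incl <- rowSums(spec$exo_mask)
  n_excl <- spec$k - n_incl
  status <- dplyr::case_when(
    n_excl < n_endo ~ "underidentified",
    n_excl == n_endo ~ "exactly_identified",
    TRUE ~ "overidentified"
  )
  tibble::tibble(
    equation = seq_len(spec$m),
    n_endo = as.integer(n_endo),
    n_incl_exo = as.integer(n_incl),
    n_excl_exo = as.integer(n_excl),
    status = status
  )
}

is_identified <- function(spec) {
  all(identification(spec)$status != "underidentified")
}
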