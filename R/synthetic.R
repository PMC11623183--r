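#' Configuration for the synthetic SEM generator
#'
#' Encodes the simulation design the package benchmarks under: structural
#' coefficients drawn Uniform(`coef_low`, `coef_high`) (default \[0, 10\]),
#' design matrix X with i.i.d. standard-normal entries (mean-zero multivariate
#' normal, identity covariance), reduced-form noise V ~ Normal(0, `sigma`^2)
#' with `sigma` in \{0.1, 1.0\} in the reference grid, and sample sizes 100 and
#' 1000. Mask entries are included independently with probabilities `p_endo`
#' and `p_exo`; specs are resampled until every equation passes the order
#' condition, and coefficient draws are resampled until
#' \eqn{cond(I - \tilde B^T) \le} `cond_limit` (uniform-\[0,10\] systems are
#' frequently near-singular or explosive without this guard).
#'
#' @param m,k Counts of endogenous/exogenous variables.
#' @param n Sample size (>= 2).
#' @param sigma Reduced-form noise standard deviation (>= 0).
#' @param coef_low,coef_high Coefficient range, `coef_low < coef_high`.
#' @param p_endo,p_exo Inclusion probabilities in \[0, 1\] for mask entries.
#' @param cond_limit Maximum accepted condition number of \eqn{(I - \tilde B^T)}.
#' @param seed Master RNG seed; all sub-streams derive from it.
#' @param max_retries Resampling cap for specs and coefficient draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 2, k = 4, n = 1000, sigma = 0.1,
                       coef_low = 0, coef_high = 10,
                       p_endo = 0.5, p_exo = 0.5,
                       cond_limit = 1e6, seed = 1L, max_retries = 1000L) {
  for (arg in list(m, k, n, sigma, coef_low, coef_high, p_endo, p_exo,
                   cond_limit, seed, max_retries)) {
    if (length(arg) != 1 || !is.numeric(arg) || !is.finite(arg)) {
      stop("all generator settings must be single finite numbers.", call. = FALSE)
    }
  }
  stopifnot(m >= 1, k >= 1, n >= 2, sigma >= 0,
            coef_low < coef_high,
            p_endo >= 0, p_endo <= 1, p_exo >= 0, p_exo <= 1,
            cond_limit > 0, max_retries >= 1)
  structure(
    list(m = as.integer(m), k = as.integer(k), n = as.integer(n), sigma = sigma,
         coef_low = coef_low, coef_high = coef_high,
         p_endo = p_endo, p_exo = p_exo,
         cond_limit = cond_limit, seed = as.integer(seed),
         max_retries = as.integer(max_retries)),
    class = "sim_config"
  )
}

# Deterministic sub-stream seed: a named stream hashed together with the master
# seed, so spec/params/X/V/split/batching draws are independently reproducible.
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

#' Draw a random identified sparsity structure
#'
#' Each off-diagonal `endo_mask` entry is included with probability `p_endo`,
#' each `exo_mask` entry with `p_exo`, independently. The draw is rejected and
#' resampled (up to `max_retries`) until every equation has at least one
#' regressor, passes the order condition, and passes a generic rank-condition
#' screen, so every generated spec is feasible for 2SLS. The screen evaluates
#' the population stage-2 design at a generic coefficient draw: the order
#' condition alone admits structures whose excluded exogenous variables never
#' reach the endogenous regressors they are supposed to instrument (e.g. an
#' equation whose only instrument is excluded from every upstream equation),
#' and 2SLS is exactly collinear on such systems no matter the sample size.
#'
#' @param cfg A [sim_config()].
#' @return A [sem_spec()].
#' @export
generate_spec <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, "spec"), {
    for (attempt in seq_len(cfg$max_retries)) {
      endo <- matrix(stats::runif(cfg$m^2) < cfg$p_endo, cfg$m, cfg$m)
      diag(endo) <- FALSE
      exo <- matrix(stats::runif(cfg$m * cfg$k) < cfg$p_exo, cfg$m, cfg$k)
      ok <- all(rowSums(endo) + rowSums(exo) > 0) &&
        all(cfg$k - rowSums(exo) >= rowSums(endo)) &&
        rank_condition_ok(endo, exo)
      if (ok) return(sem_spec(cfg$m, cfg$k, endo, exo))
    }
    stop("generation error: no identified spec found in `max_retries` draws; ",
         "lower `p_endo` or raise `k`.", call. = FALSE)
  })
}

# Generic (structural) rank condition: with coefficients in generic position,
# the population stage-2 design [Pi[, included endo] | I[, included exo]] must
# have full column rank for every equation. Rank at one generic draw equals the
# structural maximum almost surely; B entries are scaled for diagonal dominance
# so (I - B^T) is always invertible here.
rank_condition_ok <- function(endo, exo) {
  m <- nrow(endo)
  k <- ncol(exo)
  B <- matrix(0, m, m)
  B[endo] <- stats::runif(sum(endo), 0.5, 1.5) / (2 * m)
  Gamma <- matrix(0, m, k)
  Gamma[exo] <- stats::runif(sum(exo), 0.5, 1.5)
  Pi <- t(solve(diag(m) - B, Gamma))  # = Gamma^T (I - B^T)^{-1}, k x m
  Ik <- diag(k)
  for (i in seq_len(m)) {
    A <- cbind(Pi[, endo[i, ], drop = FALSE], Ik[, exo[i, ], drop = FALSE])
    if (ncol(A) > 0 && qr(A)$rank < ncol(A)) return(FALSE)
  }
  TRUE
}

#' Draw random structural coefficients for a given structure
#'
#' Free entries of \eqn{\tilde B} and \eqn{\Gamma} are i.i.d.
#' Uniform(`coef_low`, `coef_high`); masked entries are exactly zero. The
#' \eqn{\tilde B} draw is repeated until \eqn{(I - \tilde B^T)} has condition
#' number at most `cond_limit`.
#'
#' @param spec A [sem_spec()].
#' @param cfg A [sim_config()].
#' @return A [sem_params()].
#' @export
generate_params <- function(spec, cfg) {
  stopifnot(inherits(spec, "sem_spec"), inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, "params"), {
    Gamma <- matrix(0, spec$m, spec$k)
    Gamma[spec$exo_mask] <- stats::runif(sum(spec$exo_mask), cfg$coef_low, cfg$coef_high)
    for (attempt in seq_len(cfg$max_retries)) {
      B <- matrix(0, spec$m, spec$m)
      B[spec$endo_mask] <- stats::runif(sum(spec$endo_mask), cfg$coef_low, cfg$coef_high)
      if (struct_condition(B) <= cfg$cond_limit) {
        return(sem_params(spec, B, Gamma))
      }
    }
    stop("generation error: no well-conditioned coefficient draw in `max_retries` ",
         "attempts; lower `coef_high` or `p_endo`.", call. = FALSE)
  })
}

#' Simulate a dataset from structural coefficients
#'
#' Draws `n` rows of X with i.i.d. standard-normal entries, reduced-form noise
#' V with i.i.d. Normal(0, `sigma`^2) entries, and sets
#' \eqn{Y = X \Pi + V} with \eqn{\Pi} from [reduced_form()].
#'
#' @param params A [sem_params()].
#' @param cfg A [sim_config()].
#' @return A tibble with columns `y1..ym`, `x1..xk` and attributes `sigma` and
#'   `seed` recording provenance.
#' @export
generate_dataset <- function(params, cfg) {
  stopifnot(inherits(params, "sem_params"), inherits(cfg, "sim_config"))
  spec <- params$spec
  Pi <- reduced_form(params)
  X <- withr::with_seed(derive_seed(cfg$seed, "X"),
                        matrix(stats::rnorm(cfg$n * spec$k), cfg$n, spec$k))
  V <- withr::with_seed(derive_seed(cfg$seed, "V"),
                        matrix(stats::rnorm(cfg$n * spec$m, sd = cfg$sigma),
                               cfg$n, spec$m))
  out <- as_dataset(X, X %*% Pi + V)
  attr(out, "sigma") <- cfg$sigma
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate a full synthetic SEM instance
#'
#' Convenience wrapper chaining [generate_spec()], [generate_params()] and
#' [generate_dataset()] under one master seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `spec`, `params`, `data`.
#' @export
simulate_sem <- function(cfg) {
  spec <- generate_spec(cfg)
  params <- generate_params(spec, cfg)
  list(spec = spec, params = params, data = generate_dataset(params, cfg))
}

#' The reference 12-cell simulation grid
#'
#' The benchmark design: model sizes (m, k) in \{(2, 4), (10, 20), (20, 40)\},
#' noise sigma in \{0.1, 1.0\}, sample sizes n in \{100, 1000\}; all other
#' generator settings at their defaults.
#'
#' @param seed Master seed stored in every cell (each cell later derives its
#'   own sub-seed inside [run_benchmark()]).
#' @return A list of 12 [sim_config()] objects.
#' @export
benchmark_grid <- function(seed = 1L) {
  cells <- tidyr::expand_grid(
    size = list(c(2, 4), c(10, 20), c(20, 40)),
    sigma = c(0.1, 1.0),
    n = c(100L, 1000L)
  )
  purrr::pmap(cells, function(size, sigma, n) {
    sim_config(m = size[1], k = size[2], n = n, sigma = sigma, seed = seed)
  })
}
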