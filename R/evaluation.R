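#' Mean squared error over observations and endogenous variables
#'
#' \eqn{\mathrm{MSE} = \frac{1}{n m} \sum_{j=1}^m \sum_{i=1}^n (Y_{ij} -
#' \hat Y_{ij})^2}: the squared error averaged over every entry of the
#' endogenous block, so systems of different size are on a comparable scale.
#'
#' @param Y,Yhat Numeric matrices of equal shape `n x m` (vectors are treated
#'   as one column).
#' @return A single non-negative number.
#' @export
mse <- function(Y, Yhat) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat)) || nrow(Y) < 1) {
    stop("shape error: `Y` and `Yhat` must have identical, nonempty shape.",
         call. = FALSE)
  }
  mean((Y - Yhat)^2)
}

#' Random train/validation partition
#'
#' Uniformly random, seeded split: `floor(n * train_fraction)` rows go to the
#' training set and the rest to validation; no row appears in both.
#'
#' @param data Data frame of observations.
#' @param train_fraction Fraction in (0, 1); the default 0.7 reproduces the
#'   70/30 protocol (700/300 at n = 1000).
#' @param seed Seed for the partition.
#' @return A list with tibbles `train` and `validation`.
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1L) {
  n <- nrow(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("usage error: `train_fraction` must be strictly between 0 and 1.",
         call. = FALSE)
  }
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    stop("usage error: the split leaves an empty train or validation part.",
         call. = FALSE)
  }
  idx <- withr::with_seed(derive_seed(seed, "split"), sample.int(n, n_train))
  list(train = tibble::as_tibble(data[idx, , drop = FALSE]),
       validation = tibble::as_tibble(data[-idx, , drop = FALSE]))
}

#' Column scaler fitted on training data
#'
#' Records per-column mean and standard deviation of the training set. Applied
#' through [standardize()] to train and held-out sets alike, so validation
#' errors are measured on the training scale; mandatory for stable SGD at
#' learning rate 0.01 on uniform-\[0,10\]-coefficient systems, whose raw `y`
#' columns can span thousands of units.
#'
#' @param train Training data frame (all columns numeric).
#' @return A tibble with columns `column`, `center`, `scale`.
#' @export
fit_scaler <- function(train) {
  center <- purrr::map_dbl(train, mean)
  scale <- purrr::map_dbl(train, stats::sd)
  zero <- names(train)[scale == 0 | !is.finite(scale)]
  if (length(zero) > 0) {
    stop("zero-variance column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(column = names(train), center = center, scale = scale)
}

#' Apply (or invert) a fitted column scaler
#'
#' @param data Data frame whose columns appear in `scaler`.
#' @param scaler A [fit_scaler()] record.
#' @return A tibble with z-scored (or restored) columns.
#' @export
standardize <- function(data, scaler) {
  stopifnot(all(names(data) %in% scaler$column))
  s <- scaler[match(names(data), scaler$column), ]
  out <- purrr::map2(data, seq_along(data),
                     function(col, j) (col - s$center[j]) / s$scale[j])
  tibble::as_tibble(out)
}

#' @rdname standardize
#' @export
unstandardize <- function(data, scaler) {
  stopifnot(all(names(data) %in% scaler$column))
  s <- scaler[match(names(data), scaler$column), ]
  out <- purrr::map2(data, seq_along(data),
                     function(col, j) col * s$scale[j] + s$center[j])
  tibble::as_tibble(out)
}

#' Monte-Carlo benchmark of 2SLS against the SGD trainer
#'
#' For every generator configuration in `grid` and each of `n_reps`
#' repetitions, simulates a fresh model and dataset, fits 2SLS and each SGD
#' configuration, and scores validation mean-squared error in both prediction
#' modes (reduced: \eqn{\hat Y = X\Pi}; structural: teacher-forced). Two
#' protocols are available:
#'
#' * `"unified"` (default, the fair comparison): every estimator fits on the
#'   70% training split and is scored on the same 30% validation split.
#' * `"asymmetric"` (replicating a historically common but uneven design):
#'   2SLS fits on the full dataset and is scored on a random subsample of
#'   `holdout_size` rows, while SGD fits on the 70% split and is scored on the
#'   30% split.
#'
#' With `scale_data = TRUE` (default) each fit standardizes columns with
#' training-set statistics, so reported MSEs are on the standardized scale and
#' comparable across methods; the setting is recorded in the report. Failures
#' in a repetition (e.g. a near-singular draw) are caught, logged in the
#' `n_fail` column, and excluded from the averages rather than aborting the
#' sweep.
#'
#' @param grid List of [sim_config()] cells, e.g. [benchmark_grid()].
#' @param sgd_configs List of [sgd_config()]s to run per cell (default: one
#'   warm-started at 2SLS, one randomly initialized).
#' @param n_reps Repetitions per cell (default 10).
#' @param protocol `"unified"` or `"asymmetric"`.
#' @param seed Master seed; every cell/repetition derives its own sub-seed.
#' @param scale_data Standardize with training statistics before fitting.
#' @param holdout_size 2SLS scoring subsample size for the asymmetric protocol.
#' @return An object of class `sem_benchmark`: `$rows` is a tibble with one row
#'   per (cell, method, init, prediction_mode) carrying `avg_mse`, `std_mse`,
#'   `n_reps`, `n_fail`; `$settings` snapshots the harness configuration.
#' @export
run_benchmark <- function(grid, sgd_configs = default_sgd_configs(),
                          n_reps = 10L, protocol = c("unified", "asymmetric"),
                          seed = 1L, scale_data = TRUE, holdout_size = 300L) {
  protocol <- match.arg(protocol)
  stopifnot(n_reps >= 1, length(grid) >= 1)
  rows <- purrr::imap(grid, function(cfg, ci) {
    reps <- purrr::map(seq_len(n_reps), function(r) {
      rep_seed <- derive_seed(seed, sprintf("cell%d_rep%d", ci, r))
      tryCatch(
        benchmark_rep(cfg, sgd_configs, protocol, scale_data, holdout_size, rep_seed),
        error = function(e) NULL
      )
    })
    n_fail <- sum(purrr::map_lgl(reps, is.null))
    ok <- dplyr::bind_rows(reps)
    if (nrow(ok) == 0) return(NULL)
    ok |>
      dplyr::group_by(.data$method, .data$init, .data$prediction_mode) |>
      dplyr::summarise(
        avg_mse = mean(.data$mse_val),
        std_mse = if (dplyr::n() > 1) stats::sd(.data$mse_val) else 0,
        n_reps = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(m = cfg$m, k = cfg$k, sigma = cfg$sigma, n = cfg$n,
                    n_fail = n_fail, .before = 1)
  })
  structure(
    list(
      rows = dplyr::bind_rows(rows),
      settings = list(protocol = protocol, n_reps = n_reps, seed = seed,
                      scale_data = scale_data, holdout_size = holdout_size,
                      mse_scale = if (scale_data) "standardized" else "raw",
                      sgd_configs = sgd_configs)
    ),
    class = "sem_benchmark"
  )
}

#' @rdname run_benchmark
#' @export
default_sgd_configs <- function() {
  list(sgd_config(init = "twostage"), sgd_config(init = "random"))
}

# one repetition of one grid cell; returns a tibble of per-method MSEs
benchmark_rep <- function(cfg, sgd_configs, protocol, scale_data, holdout_size,
                          rep_seed) {
  cfg$seed <- rep_seed
  inst <- simulate_sem(cfg)
  parts <- split_dataset(inst$data, 0.7, seed = rep_seed)
  if (scale_data) {
    scaler <- fit_scaler(parts$train)
    train <- standardize(parts$train, scaler)
    valid <- standardize(parts$validation, scaler)
  } else {
    train <- parts$train
    valid <- parts$validation
  }

  score <- function(params, eval_data, method, init) {
    Y <- extract_cols(eval_data, "y", cfg$m)
    purrr::map(c("reduced", "structural"), function(mode) {
      val <- tryCatch(mse(Y, predict(params, eval_data, mode = mode)),
                      error = function(e) NA_real_)
      tibble::tibble(method = method, init = init, prediction_mode = mode,
                     mse_val = val)
    }) |> dplyr::bind_rows()
  }

  if (protocol == "unified") {
    fit2 <- fit_2sls(train, inst$spec)
    rows <- score(fit2$params, valid, "2sls", NA_character_)
  } else {
    # full-data fit, scored on a random subsample
    if (scale_data) {
      full_scaler <- fit_scaler(inst$data)
      full <- standardize(inst$data, full_scaler)
    } else {
      full <- inst$data
    }
    fit2 <- fit_2sls(full, inst$spec)
    idx <- withr::with_seed(derive_seed(rep_seed, "holdout"),
                            sample.int(nrow(full), min(holdout_size, nrow(full))))
    rows <- score(fit2$params, full[idx, , drop = FALSE], "2sls", NA_character_)
  }

  sgd_rows <- purrr::map(sgd_configs, function(scfg) {
    scfg$seed <- derive_seed(rep_seed, paste0("sgd_", scfg$init))
    fit <- fit_sgd(train, inst$spec, scfg)
    score(fit$params, valid, "sgd", scfg$init)
  })
  dplyr::bind_rows(rows, sgd_rows) |>
    dplyr::filter(is.finite(.data$mse_val))
}

#' @export
print.sem_benchmark <- function(x, ...) {
  cat(sprintf("<sem_benchmark> protocol=%s, %d report rows, MSE scale: %s\n",
              x$settings$protocol, nrow(x$rows), x$settings$mse_scale))
  print(x$rows, n = 20)
  invisible(x)
}
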