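#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted SEM into one row per free coefficient
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return A tibble with columns `equation`, `term` (`y<j>` or `x<r>`),
#'   `estimate`.
#' @export
tidy.sem_fit <- function(x, ...) {
  spec <- x$params$spec
  rows <- purrr::map(seq_len(spec$m), function(i) {
    je <- which(spec$endo_mask[i, ])
    jx <- which(spec$exo_mask[i, ])
    tibble::tibble(
      equation = i,
      term = c(paste0("y", je), paste0("x", jx)),
      estimate = c(x$params$B[i, je], x$params$Gamma[i, jx])
    )
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted SEM
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return A tibble with `method`, `m`, `k`, `n_free`, `final_loss` (last
#'   traced training loss, `NA` for closed-form fits), `elapsed`.
#' @export
glance.sem_fit <- function(x, ...) {
  spec <- x$params$spec
  tibble::tibble(
    method = x$method,
    m = spec$m,
    k = spec$k,
    n_free = sum(spec$endo_mask) + sum(spec$exo_mask),
    final_loss = if (is.null(x$trace)) NA_real_ else utils::tail(x$trace$loss, 1),
    elapsed = x$timing
  )
}

#' @export
tidy.sem_benchmark <- function(x, ...) x$rows

#' @export
glance.sem_benchmark <- function(x, ...) {
  tibble::tibble(
    protocol = x$settings$protocol,
    n_reps = x$settings$n_reps,
    seed = x$settings$seed,
    mse_scale = x$settings$mse_scale,
    n_cells = nrow(dplyr::distinct(x$rows, .data$m, .data$k, .data$sigma, .data$n)),
    n_rows = nrow(x$rows)
  )
}

#' Training-loss trace of an SGD fit
#'
#' @param object A `sem_fit` from [fit_sgd()].
#' @param ... Unused.
#' @return A ggplot of mini-batch training loss against iteration (log-scale
#'   loss axis).
#' @export
autoplot.sem_fit <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("no training trace: only SGD fits carry one.", call. = FALSE)
  }
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration (weight update)", y = "mini-batch training MSE",
                  title = sprintf("SGD training trace (%s init)",
                                  object$hyper$init %||% "")) +
    ggplot2::theme_minimal()
}

#' Benchmark results as grouped bar charts
#'
#' One panel per (model size, sample size) cell; bars compare average
#' validation MSE by estimator and initialization within each noise level.
#'
#' @param object A `sem_benchmark`.
#' @param prediction_mode Which scoring mode to display (default `"reduced"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sem_benchmark <- function(object, prediction_mode = "reduced", ...) {
  df <- object$rows |>
    dplyr::filter(.data$prediction_mode == !!prediction_mode) |>
    dplyr::mutate(
      model = sprintf("m=%d, k=%d", .data$m, .data$k),
      estimator = ifelse(is.na(.data$init), .data$method,
                         paste0(.data$method, " (", .data$init, ")"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$sigma), y = .data$avg_mse,
                                   fill = .data$estimator)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$avg_mse - .data$std_mse,
                   ymax = .data$avg_mse + .data$std_mse),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::facet_grid(n ~ model, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "noise sd (sigma)",
                  y = sprintf("average validation MSE (%s scale)",
                              object$settings$mse_scale),
                  fill = NULL,
                  title = sprintf("Estimator comparison, %s predictions",
                                  prediction_mode)) +
    ggplot2::theme_minimal()
}
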