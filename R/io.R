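#' Read and write observation datasets as CSV
#'
#' Datasets are plain CSV with header `y1..ym,x1..xk`, one observation per row.
#'
#' @param data Data frame with `y1..ym`, `x1..xk` columns.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   tibble.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a model (structure, optionally coefficients) to JSON
#'
#' The JSON object carries `m`, `k`, `endo_mask`, `exo_mask` (0/1 row-major
#' nested arrays) and, when coefficients are present, `B_tilde` and `Gamma`.
#'
#' @param x A [sem_spec()] or [sem_params()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(x, path) {
  if (inherits(x, "sem_params")) {
    spec <- x$spec
    obj <- list(m = spec$m, k = spec$k,
                endo_mask = mask_rows(spec$endo_mask),
                exo_mask = mask_rows(spec$exo_mask),
                B_tilde = matrix_rows(x$B),
                Gamma = matrix_rows(x$Gamma))
  } else if (inherits(x, "sem_spec")) {
    obj <- list(m = x$m, k = x$k,
                endo_mask = mask_rows(x$endo_mask),
                exo_mask = mask_rows(x$exo_mask))
  } else {
    stop("`x` must be a sem_spec or sem_params.", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns a [sem_params()] when coefficients are
#'   present in the file, otherwise a [sem_spec()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- sem_spec(obj$m, obj$k,
                   rows_matrix(obj$endo_mask, obj$m, obj$m),
                   rows_matrix(obj$exo_mask, obj$m, obj$k))
  if (is.null(obj$B_tilde)) return(spec)
  sem_params(spec,
             rows_matrix(obj$B_tilde, obj$m, obj$m),
             rows_matrix(obj$Gamma, obj$m, obj$k))
}

# row-major nested-list views of matrices for JSON
mask_rows <- function(M) apply(M * 1L, 1, identity, simplify = FALSE)
matrix_rows <- function(M) apply(M, 1, identity, simplify = FALSE)
rows_matrix <- function(x, nr, nc) {
  M <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  if (nr == 1 && is.null(dim(M))) M <- matrix(M, nrow = 1)
  if (!all(dim(M) == c(nr, nc))) {
    stop("malformed model JSON: matrix shape mismatch.", call. = FALSE)
  }
  storage.mode(M) <- "double"
  dimnames(M) <- NULL
  M
}
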