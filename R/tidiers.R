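#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the residual trace of a factorization
#'
#' @param x an `nmf_fit` (or `hnmf_fit`).
#' @param ... unused.
#' @return A tibble with columns `iteration` (0 = initialization) and
#'   `residual` (`||X - WH||_F`).
#' @export
tidy.nmf_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$residual_trace) - 1L,
                 residual = x$residual_trace)
}

#' One-row summary of a factorization
#'
#' @param x an `nmf_fit`.
#' @param ... unused.
#' @return A tibble with `solver`, `init`, `rank`, `n_iter`, `converged`,
#'   `residual` (final) and `initial_residual`.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(
    solver = x$solver, init = x$init_method, rank = ncol(x$W),
    n_iter = x$n_iter, converged = x$converged,
    residual = x$residual_trace[[length(x$residual_trace)]],
    initial_residual = x$residual_trace[[1L]])
}

#' Plot a residual convergence trace
#'
#' Residual `||X - WH||_F` per outer iteration on a log scale, the
#' standard convergence diagnostic for comparing initializations.
#'
#' @param object an `nmf_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nmf_fit <- function(object, ...) {
  df <- tidy.nmf_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$residual)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = expression("||X - WH||"[F]),
                  title = sprintf("%s / %s", object$solver, object$init_method)) +
    ggplot2::theme_minimal()
}

#' Plot a label map as an image
#'
#' @param object a `label_map` with a grid shape.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.label_map <- function(object, ...) {
  if (is.null(object$grid_shape)) stop("label map has no grid shape", call. = FALSE)
  h <- object$grid_shape[[1L]]; w <- object$grid_shape[[2L]]
  lab <- object$labels
  length(lab) <- h * w
  df <- tibble::tibble(
    row = rep(seq_len(h), times = w),
    col = rep(seq_len(w), each = h),
    label = factor(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "source") +
    ggplot2::theme_minimal()
}

#' Plot residual traces of a pipeline run
#'
#' One line per (initializer, solver) cell, residual on a log scale —
#' the head-start / convergence comparison across initializations.
#'
#' @param object an `nmf_pipeline` from [run_pipeline()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nmf_pipeline <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$iteration, y = .data$residual,
                               colour = .data$init)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$solver), scales = "free") +
    ggplot2::labs(x = "iteration", y = expression("||X - WH||"[F])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
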