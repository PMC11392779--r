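#' Tidy a geographically weighted regression fit
#'
#' One row per location: coordinates, local coefficients, observed and
#' fitted values, residual, local R-squared and the degeneracy flag.
#'
#' @param x A `divscape_gwr` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy divscape_gwr
#' @export
tidy.divscape_gwr <- function(x, ...) {
  fit <- x
  tibble::tibble(
    model = fit$model,
    x = fit$coords[, 1], y = fit$coords[, 2],
    intercept = fit$intercept,
    slope = if (length(fit$slope) == fit$n) fit$slope else
      rep(fit$slope, fit$n),
    observed = fit$observed, fitted = fit$fitted,
    residual = fit$residuals,
    local_r2 = fit$local_r2, degenerate = fit$degenerate
  )
}

#' One-row summary of a geographically weighted regression fit
#'
#' @inheritParams tidy.divscape_gwr
#' @return A tibble with model label, method, bandwidth(s), AICc,
#'   effective parameters `tr(S)`, RSS, n and convergence status.
#' @method glance divscape_gwr
#' @export
glance.divscape_gwr <- function(x, ...) {
  tibble::tibble(
    model = x$model, method = x$method,
    bandwidth = x$bandwidth,
    bandwidth_intercept = if (!is.null(x$bandwidths)) {
      unname(x$bandwidths[1])
    } else x$bandwidth,
    aicc = x$aicc, trS = x$trS, rss = x$rss, n = x$n,
    converged = x$converged
  )
}

#' @rdname tidy.divscape_gwr
#' @method tidy divscape_suite
#' @export
tidy.divscape_suite <- function(x, ...) {
  attr(x, "classification")
}

#' @rdname glance.divscape_gwr
#' @method glance divscape_suite
#' @export
glance.divscape_suite <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

surfaces_long <- function(surfaces) {
  tidyr::pivot_longer(
    tibble::as_tibble(surfaces),
    cols = c("td", "we", "pd", "pe", "fd", "fe"),
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::mutate(metric = factor(toupper(.data$metric),
                                  levels = c("TD", "FD", "PD",
                                             "WE", "FE", "PE")))
}

#' Map the six diversity and endemism surfaces
#'
#' Facetted tile maps of TD, FD, PD, WE, FE and PE over the grid, with
#' free colour scales per metric.
#'
#' @param object A `divscape_surfaces` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divscape_surfaces <- function(object, ...) {
  surfaces_long(object) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(value = (.data$value - min(.data$value, na.rm = TRUE)) /
                    max(diff(range(.data$value, na.rm = TRUE)), 1e-12)) |>
    dplyr::ungroup() |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(name = "scaled\nvalue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Map a fitted geographically weighted regression
#'
#' Side-by-side tile maps of the local R-squared and the signed
#' residuals (response minus local expectation).
#'
#' @param object A `divscape_gwr` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divscape_gwr <- function(object, ...) {
  tidy(object) |>
    dplyr::select("x", "y", "local_r2", "residual") |>
    tidyr::pivot_longer(c("local_r2", "residual")) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$model, x = NULL, y = NULL)
}

#' Map residual mismatch classes for a model suite
#'
#' @param suite A `divscape_suite` from [run_model_suite()].
#' @return A ggplot object: per-model maps of positive / negative /
#'   neutral residual cells.
#' @export
plot_residual_map <- function(suite) {
  stopifnot(inherits(suite, "divscape_suite"))
  tidy(suite) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y,
                                 fill = .data$sign_label)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_fill_manual(values = c(positive = "#2166ac",
                                          negative = "#b2182b",
                                          neutral = "grey80"),
                               name = "residual") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
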