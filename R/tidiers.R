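#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: `tidy()` returns
#' one row per component (per day, per model term, per replicate), and
#' `glance()` a one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @name estuaryuse-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname estuaryuse-tidiers
#' @export
tidy.changepoint <- function(x, ...) x$trace

#' @rdname estuaryuse-tidiers
#' @export
glance.changepoint <- function(x, ...) {
  tibble(change_doy = x$change_doy, max_abs_cumsum = x$max_abs_cumsum,
         n_days = x$n_days, degenerate = x$degenerate)
}

#' @rdname estuaryuse-tidiers
#' @export
tidy.switch_recovery <- function(x, ...) x$estimates

#' @rdname estuaryuse-tidiers
#' @export
glance.switch_recovery <- function(x, ...) {
  tibble(n_replicates = nrow(x$estimates), switch_doy = x$switch_doy,
         bias = x$bias, mae = x$mae)
}

#' @rdname estuaryuse-tidiers
#' @export
tidy.dist_gls <- function(x, ...) {
  tt <- summary(x$fit)$tTable
  tibble(term = rownames(tt), estimate = tt[, "Value"],
         std.error = tt[, "Std.Error"], statistic = tt[, "t-value"],
         p.value = tt[, "p-value"])
}

#' @rdname estuaryuse-tidiers
#' @export
glance.dist_gls <- function(x, ...) {
  tibble(n = x$n, k = x$k, logLik = x$loglik, phi = x$phi,
         sigma = x$fit$sigma, aicc = aicc(x$loglik, x$k, x$n),
         method = x$spec$method)
}

#' @rdname estuaryuse-tidiers
#' @export
glance.lscv_bandwidth <- function(x, ...) {
  tibble(h = x$h, h_ref = x$h_ref, ratio = x$h / x$h_ref)
}

#' Plot a cumulative-sign change-point trace
#'
#' Absolute cumulative sign score by day of year, with the estimated
#' change point marked.
#'
#' @param object A [cumulative_sign_changepoint()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.changepoint <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$day_of_year, y = abs(.data$cumsum))) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$change_doy, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Day of year", y = "|cumulative sign score|",
                  title = sprintf("Change point: day %d", object$change_doy)) +
    ggplot2::theme_minimal()
}

#' Plot a utilization distribution
#'
#' Filled density raster in the local projected frame, with optional
#' probability-contour outlines.
#'
#' @param object A [kde_ud()] grid.
#' @param levels Contour levels (percent) to overlay; `NULL` for none.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ud_grid <- function(object, levels = c(50, 95), ...) {
  df <- tidyr::expand_grid(xi = seq_along(object$x), yi = seq_along(object$y)) %>%
    dplyr::mutate(x = object$x[.data$xi], y = object$y[.data$yi],
                  density = object$z[cbind(.data$xi, .data$yi)])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East (km)", y = "North (km)", fill = "density / km²") +
    ggplot2::theme_minimal()
  for (l in levels %||% numeric(0)) {
    pc <- probability_contour(object, l)
    for (seg in pc$outline) {
      p <- p + ggplot2::annotate("path", x = seg$x, y = seg$y,
                                 colour = "white", linewidth = 0.3)
    }
  }
  p
}

#' Plot a daily pooled-distance series
#'
#' @param pooled Output of [pooled_daily_distance()].
#' @param changepoint Optional [cumulative_sign_changepoint()] result whose
#'   estimated day is marked.
#' @return A ggplot.
#' @export
plot_pooled_distance <- function(pooled, changepoint = NULL) {
  p <- ggplot2::ggplot(pooled, ggplot2::aes(.data$day_of_year, .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Day of year", y = "Pooled distance to river mouth (km)") +
    ggplot2::theme_minimal()
  if (!is.null(changepoint)) {
    p <- p + ggplot2::geom_vline(xintercept = changepoint$change_doy,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
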