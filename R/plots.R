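# ggplot2 autoplot methods for the package's result types.

#' Plot a drying curve
#'
#' @param object A `drying_curve` tibble.
#' @param what `"mc"` (moisture content), `"temp"` (seed temperature) or
#'   `"aw"` (surface water activity).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drying_curve <- function(object, what = c("mc", "temp", "aw"), ...) {
  what <- match.arg(what)
  df <- tibble::as_tibble(object)
  df$hours <- df$time_s / 3600
  switch(what,
    mc = ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$mc_wb)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (h)", y = "Moisture content (wet basis)"),
    temp = ggplot2::ggplot(df, ggplot2::aes(.data$hours,
                                            .data$temp_seed_K - 273.15)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (h)", y = "Seed temperature (deg C)"),
    aw = ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$aw_surface)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (h)", y = "Surface water activity")
  )
}

#' Plot an isotherm fit
#'
#' Fitted sorption isotherm (equilibrium moisture vs water activity) overlaid
#' on the fitted data points.
#'
#' @param object A `chi_fit`.
#' @param ... Unused.
#' @export
autoplot.chi_fit <- function(object, ...) {
  p <- object$params; p$chi_ws <- object$chi_ws
  T_K <- object$data$temp_K[1]
  aw_grid <- seq(0.02, 0.98, by = 0.02)
  curve <- tibble::tibble(
    aw = aw_grid,
    mc_wb = vapply(aw_grid, function(a) {
      tryCatch(equilibrium_moisture(a, T_K, object$comp, p),
               error = function(e) NA_real_)
    }, numeric(1))
  )
  ggplot2::ggplot(object$data, ggplot2::aes(.data$aw, .data$mc_wb)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, na.rm = TRUE) +
    ggplot2::labs(x = "Water activity", y = "Moisture content (wet basis)")
}

#' Plot a model/experiment comparison
#'
#' @param object A `pe_result`.
#' @param ... Unused.
#' @export
autoplot.pe_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$residuals,
                            c("mc_exp", "mc_model"),
                            names_to = "series", values_to = "mc")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 3600, .data$mc,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Moisture content (wet basis)",
                  subtitle = sprintf("PE = %.2f %%", object$PE))
}

#' Plot a mixing-entropy time series
#'
#' @param object An `entropy_ts` tibble.
#' @param ... Unused.
#' @export
autoplot.entropy_ts <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$entropy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (s)", y = "Mixing entropy S")
}

#' Plot grid colour fractions as a heat map
#'
#' @param object A `grid_fractions` tibble.
#' @param ... Unused.
#' @export
autoplot.grid_fractions <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$x_white)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), na.value = "grey50") +
    ggplot2::labs(x = NULL, y = NULL, fill = "White\nfraction")
}
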