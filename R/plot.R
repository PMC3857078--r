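#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a release profile
#'
#' Flux against time for reservoir profiles (with the steady-state flux as
#' a dashed reference) or fraction released for matrix profiles (with the
#' complete-release line).
#'
#' @param object A `release_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_profile <- function(object, ...) {
  dev <- attr(object, "device")
  df <- tibble::as_tibble(object)
  if ("flux_ug_cm2_h" %in% names(df) && dev$kind == "reservoir") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$flux_ug_cm2_h)) +
      ggplot2::geom_hline(
        yintercept = steady_state_flux(dev),
        linetype = "dashed", colour = "grey50"
      ) +
      ggplot2::labs(
        x = "time (h)", y = expression(flux ~ (mu * g / cm^2 / h)),
        title = "Skin flux, reservoir device"
      )
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$fraction)) +
      ggplot2::geom_hline(
        yintercept = 1, linetype = "dashed",
        colour = "grey50"
      ) +
      ggplot2::labs(
        x = "time (h)", y = "fraction released",
        title = "Fraction released, matrix device"
      )
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8)
}

#' Plot concentration snapshots of a PDE solution
#'
#' Concentration against depth at a handful of snapshot times, with the
#' vehicle layer at negative depth and the skin at positive depth.
#'
#' @param object A `pde_solution`.
#' @param n_times Number of snapshot times to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pde_solution <- function(object, n_times = 6, ...) {
  conc <- pde_concentrations(object)
  keep <- unique(round(seq(1, length(object$snapshot_times),
    length.out = n_times
  )))
  uh <- time_unit_hours(object$device)
  df <- purrr::map_dfr(keep, function(j) {
    tibble::tibble(
      x_cm = c(object$x1, object$x2),
      conc = c(conc$C1[, j], conc$C2[, j]),
      layer = rep(c("vehicle", "skin"), c(length(object$x1), length(object$x2))),
      time_h = object$snapshot_times[j] * uh
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x_cm, .data$conc,
    colour = factor(signif(.data$time_h, 3)),
    group = interaction(.data$time_h, .data$layer)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "depth (cm; vehicle < 0 < skin)",
      y = expression(concentration ~ (mu * g / cm^3)),
      colour = "time (h)"
    )
}

#' @importFrom rlang .data
NULL
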