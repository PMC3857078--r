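#' Closed-form effective time constant of a reservoir device
#'
#' Dimensionless first-moment relaxation time of the skin flux of a
#' reservoir (membrane + skin) device toward its steady state:
#' \deqn{\tau_{eff} = \frac{14\beta(p+3)(3p+1)k_m
#'   + \left[p(7p+30)+75\right]k_m^2 + \beta^2\left[15p(5p+2)+7\right]}
#'   {60 p (\beta + k_m)\left[\beta + (p+3)k_m + 3\beta p\right]}}
#' For identical layers (`beta = p = km = 1`) this degenerates to `7/15`,
#' the single-slab value for a membrane of dimensionless thickness 2.
#'
#' @param groups A `tdds_groups` object or a device.
#' @return Dimensionless `tau_eff`; multiply by `lb^2/D2` (see
#'   [dimensionalize_teff()]) for clock time.
#' @examples
#' tau_eff_reservoir(tdds_groups(1, 1, 1)) # 7/15
#' @export
tau_eff_reservoir <- function(groups) {
  g <- as_groups(groups)
  b <- g$beta
  p <- g$p
  km <- g$km
  num <- 14 * b * (p + 3) * (3 * p + 1) * km +
    (p * (7 * p + 30) + 75) * km^2 +
    b^2 * (15 * p * (5 * p + 2) + 7)
  den <- 60 * p * (b + km) * (b + (p + 3) * km + 3 * b * p)
  num / den
}

#' Closed-form effective time constant of a matrix device
#'
#' Dimensionless first-moment relaxation time of the fraction released from
#' a monolithic matrix toward complete release:
#' \deqn{\tau_{eff} = \frac{20\beta(5p+4)k_m + 120 k_m^2
#'   + \beta^2\left[5p(5p+4)+16\right]}
#'   {20\beta p\left[6k_m + \beta(3p+2)\right]}}
#' For `beta = p = km = 1` this equals `361/220` exactly.
#'
#' @inheritParams tau_eff_reservoir
#' @return Dimensionless `tau_eff`.
#' @examples
#' tau_eff_matrix(tdds_groups(1, 1, 1)) # 361/220
#' @export
tau_eff_matrix <- function(groups) {
  g <- as_groups(groups)
  b <- g$beta
  p <- g$p
  km <- g$km
  num <- 20 * b * (5 * p + 4) * km + 120 * km^2 +
    b^2 * (5 * p * (5 * p + 4) + 16)
  den <- 20 * b * p * (6 * km + b * (3 * p + 2))
  num / den
}

#' Convert a dimensionless time constant to clock time
#'
#' Applies `t_eff = tau_eff * lb^2 / D2` and the 98%-completion convention
#' `response time = 4 t_eff` (a first-order response is 63.2% complete after
#' one time constant and 98% complete after four).
#'
#' @param tau_eff Dimensionless effective time constant.
#' @param device The [tdds_device()] supplying `lb`, `D2` and the time unit.
#' @return A `tdds_teff` object; see [time_constants()].
#' @export
dimensionalize_teff <- function(tau_eff, device) {
  validate_device(device)
  t_eff_h <- tau_eff * device$lb^2 / device$D2 * time_unit_hours(device)
  structure(
    list(
      tau_eff = tau_eff,
      t_eff_h = t_eff_h,
      response_time_h = 4 * t_eff_h,
      fraction_at_teff = 0.632,
      fraction_at_response = 0.98,
      method = "closed_form",
      device = device
    ),
    class = "tdds_teff"
  )
}

#' Effective time constant and response time of a device
#'
#' The headline summary of a device's dynamics: the dimensionless and
#' dimensional effective time constants, the 98% response time
#' (`4 t_eff`), and the long-time quantity the response approaches (steady
#' flux for a reservoir, total releasable mass for a matrix).
#'
#' @param device A [tdds_device()].
#' @param method `"closed_form"` (default) evaluates the analytic
#'   `tau_eff` formulas; `"operator"` applies the generic first-moment
#'   operator [effective_time_constant()] to the device's transform — the
#'   two agree to ~1e-7 relative and the operator route is useful as an
#'   internal consistency check.
#' @return A `tdds_teff` object with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' time_constants(tdds_fixture("metoprolol_tdds1")) # t_eff ~2.15 h
#' time_constants(tdds_fixture("ata_tdds2")) # t_eff ~114 h
#' @export
time_constants <- function(device, method = c("closed_form", "operator")) {
  method <- match.arg(method)
  validate_device(device)
  g <- dimensionless_groups(device)
  tau <- if (method == "closed_form") {
    if (device$kind == "reservoir") tau_eff_reservoir(g) else tau_eff_matrix(g)
  } else {
    tf <- if (device$kind == "reservoir") {
      flux_ratio_transform(g)
    } else {
      fraction_transform(g)
    }
    effective_time_constant(tf)
  }
  out <- dimensionalize_teff(tau, device)
  out$method <- method
  if (device$kind == "reservoir") {
    out$steady_flux <- steady_state_flux(device)
  } else {
    out$m_inf_ug <- total_releasable(device)
  }
  out
}

#' @export
print.tdds_teff <- function(x, ...) {
  cat(sprintf(
    "<tdds_teff: %s device (%s)>\n  tau_eff        = %.6g (dimensionless)\n  t_eff          = %.6g h   (response ~63.2%% complete)\n  response time  = %.6g h   (4 t_eff, ~98%% complete)\n",
    x$device$kind, x$method, x$tau_eff, x$t_eff_h, x$response_time_h
  ))
  if (!is.null(x$steady_flux)) {
    cat(sprintf("  steady flux    = %.6g ug/cm^2/h\n", x$steady_flux))
  }
  if (!is.null(x$m_inf_ug)) {
    cat(sprintf("  releasable     = %.6g ug\n", x$m_inf_ug))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effective-time-constant summary
#'
#' @param x A `tdds_teff` object from [time_constants()].
#' @param ... Unused.
#' @return A tibble with one row per quantity (`term`, `estimate`, `unit`).
#' @export
tidy.tdds_teff <- function(x, ...) {
  rows <- tibble::tibble(
    term = c("tau_eff", "t_eff", "response_time"),
    estimate = c(x$tau_eff, x$t_eff_h, x$response_time_h),
    unit = c("1", "h", "h")
  )
  if (!is.null(x$steady_flux)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      term = "steady_flux", estimate = x$steady_flux, unit = "ug/cm^2/h"
    ))
  }
  if (!is.null(x$m_inf_ug)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      term = "m_inf", estimate = x$m_inf_ug, unit = "ug"
    ))
  }
  rows
}

#' One-row summary of an effective-time-constant fit
#'
#' @param x A `tdds_teff` object.
#' @param ... Unused.
#' @return A one-row tibble with the device kind, dimensionless groups,
#'   time constants and the long-time quantity.
#' @export
glance.tdds_teff <- function(x, ...) {
  g <- dimensionless_groups(x$device)
  tibble::tibble(
    kind = x$device$kind,
    beta = g$beta,
    p = g$p,
    km = g$km,
    tau_eff = x$tau_eff,
    t_eff_h = x$t_eff_h,
    response_time_h = x$response_time_h,
    steady_flux_ug_cm2_h = if (is.null(x$steady_flux)) NA_real_ else x$steady_flux,
    m_inf_ug = if (is.null(x$m_inf_ug)) NA_real_ else x$m_inf_ug,
    method = x$method
  )
}
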