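# dimensionless time below which profiles are clamped to zero: inversion of
# the s^{-1/2}-type transforms converges slowly as tau -> 0 while the true
# response is transcendentally small there
TAU_CLAMP <- 1e-6

new_release_profile <- function(data, device, provenance) {
  structure(
    data,
    device = device,
    provenance = provenance,
    class = c("release_profile", class(data))
  )
}

#' Time-domain flux profile of a reservoir device
#'
#' Dimensional skin flux `J(t) = (C0 D2 / lb) J(tau)` at the requested
#' times, by numerical inversion of the flux transform (default) or from the
#' finite-difference solver.
#'
#' @param device A reservoir [tdds_device()].
#' @param times Times in hours, strictly positive.
#' @param method `"laplace"` (numerical inversion, default) or `"pde"`
#'   (interpolated from [solve_pde()]).
#' @param inversion Inversion backend, see [invert_laplace()].
#' @param grid Optional [pde_grid()] when `method = "pde"`.
#' @return A `release_profile` tibble with columns `time_h`,
#'   `flux_ug_cm2_h` and `cumulative_ug` (trapezoidal, times `A`).
#' @examples
#' flux_profile(tdds_fixture("metoprolol_tdds1"), times = c(2.15, 8.6, 24))
#' @export
flux_profile <- function(device, times, method = c("laplace", "pde"),
                         inversion = c("talbot", "euler"), grid = NULL) {
  method <- match.arg(method)
  validate_device(device)
  if (device$kind != "reservoir") {
    stop(
      "flux_profile() expects a reservoir device; ",
      "use fraction_profile() for a matrix device",
      call. = FALSE
    )
  }
  check_times(times)
  g <- dimensionless_groups(device)
  jss <- steady_state_flux(device) # ug/cm^2/h
  if (method == "laplace") {
    tau <- times / g$time_scale_h
    ratio <- numeric(length(tau))
    live <- tau >= TAU_CLAMP
    if (any(live)) {
      ratio[live] <- invert_laplace(
        flux_ratio_transform(g), tau[live],
        method = match.arg(inversion)
      )
    }
    flux <- jss * ratio
    prov <- "laplace_inversion"
  } else {
    sol <- solve_pde(device, grid = grid %||% pde_grid(
      t_end = max(times) / time_unit_hours(device)
    ))
    fs <- flux_series(sol)
    flux <- stats::approx(fs$time_h, fs$flux_ug_cm2_h, times, rule = 2)$y
    prov <- "pde_oracle"
  }
  cum <- cumtrapz_from_zero(times, flux) * device$A
  new_release_profile(
    tibble::tibble(time_h = times, flux_ug_cm2_h = flux, cumulative_ug = cum),
    device, prov
  )
}

#' Fraction-released profile of a matrix device
#'
#' Fraction of the releasable dose `M(t)/M_inf` at the requested times, by
#' numerical inversion of the fraction transform (default) or from the
#' finite-difference solver, together with the cumulative amount
#' `fraction * A * la * C0`.
#'
#' @param device A matrix [tdds_device()].
#' @inheritParams flux_profile
#' @return A `release_profile` tibble with columns `time_h`, `fraction`
#'   and `cumulative_ug`.
#' @examples
#' fraction_profile(tdds_fixture("ata_tdds2"), times = c(115, 461.4))
#' @export
fraction_profile <- function(device, times, method = c("laplace", "pde"),
                             inversion = c("talbot", "euler"), grid = NULL) {
  method <- match.arg(method)
  validate_device(device)
  if (device$kind != "matrix") {
    stop(
      "fraction_profile() expects a matrix device; ",
      "use flux_profile() for a reservoir device",
      call. = FALSE
    )
  }
  check_times(times)
  g <- dimensionless_groups(device)
  if (method == "laplace") {
    tau <- times / g$time_scale_h
    frac <- numeric(length(tau))
    live <- tau >= TAU_CLAMP
    if (any(live)) {
      frac[live] <- invert_laplace(
        fraction_transform(g), tau[live],
        method = match.arg(inversion)
      )
    }
    prov <- "laplace_inversion"
  } else {
    sol <- solve_pde(device, grid = grid %||% pde_grid(
      t_end = max(times) / time_unit_hours(device)
    ))
    cs <- cumulative_series(sol)
    frac <- stats::approx(cs$time_h, cs$fraction, times, rule = 2)$y
    prov <- "pde_oracle"
  }
  new_release_profile(
    tibble::tibble(
      time_h = times, fraction = frac,
      cumulative_ug = frac * total_releasable(device)
    ),
    device, prov
  )
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L ||
    any(!is.finite(times)) || any(times <= 0)) {
    stop("'times' must be a non-empty vector of positive finite hours",
      call. = FALSE
    )
  }
  invisible(times)
}

# trapezoidal cumulative integral assuming f(0) = 0
cumtrapz_from_zero <- function(t, f) {
  tt <- c(0, t)
  ff <- c(0, f)
  cumsum(c(0, diff(tt) * (utils::head(ff, -1) + utils::tail(ff, -1)) / 2))[-1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time to release a given fraction of the dose
#'
#' Inverts the monotone fraction-released profile of a matrix device by
#' bisection on the bracket `[1e-3, 20] * t_eff`.
#'
#' @param device A matrix [tdds_device()].
#' @param fraction Target fraction in (0, 1).
#' @param inversion Inversion backend.
#' @param tol Relative tolerance on the returned time.
#' @return Time in hours.
#' @examples
#' time_to_fraction(tdds_fixture("ata_tdds2"), 0.98) # ~455 h
#' @export
time_to_fraction <- function(device, fraction, inversion = c("talbot", "euler"),
                             tol = 1e-4) {
  validate_device(device)
  if (device$kind != "matrix") {
    stop("time_to_fraction() expects a matrix device", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
    !is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  inversion <- match.arg(inversion)
  g <- dimensionless_groups(device)
  tf <- fraction_transform(g)
  t_eff_h <- tau_eff_matrix(g) * g$time_scale_h
  f_at <- function(th) {
    tau <- th / g$time_scale_h
    if (tau < TAU_CLAMP) 0 else invert_laplace(tf, tau, method = inversion)
  }
  lo <- 1e-3 * t_eff_h
  hi <- 20 * t_eff_h
  if (f_at(lo) > fraction || f_at(hi) < fraction) {
    stop("time_to_fraction(): target fraction outside the bracketed range",
      call. = FALSE
    )
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f_at(mid) < fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Elasticities of the effective time constant
#'
#' Logarithmic sensitivities `d ln(t_eff) / d ln(theta)` of the dimensional
#' effective time constant with respect to the physical device parameters,
#' by central differencing of the closed-form `t_eff` on a relative step.
#' An elasticity of -1 for `D2`, say, means a 1% faster skin diffusivity
#' shortens the response time by 1%. When the skin controls the dynamics
#' (`beta -> 0`, `km` moderate) the elasticities approach `-1` for `D2` and
#' `+2` for `lb` (the `lb^2/D2` scaling); joint rescaling of `D1` and `D2`
#' rescales time, so their elasticities always sum to -1.
#'
#' @param device A [tdds_device()].
#' @param parameters Subset of `c("D1", "D2", "la", "lb", "km")`.
#' @param rel_step Relative perturbation used in the central difference.
#' @return A tibble with columns `parameter` and `elasticity`.
#' @examples
#' teff_sensitivity(tdds_fixture("ata_tdds2"))
#' @export
teff_sensitivity <- function(device,
                             parameters = c("D1", "D2", "la", "lb", "km"),
                             rel_step = 1e-3) {
  validate_device(device)
  bad <- setdiff(parameters, c("D1", "D2", "la", "lb", "km"))
  if (length(bad) > 0) {
    stop(
      "unknown parameter(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  t_eff_of <- function(dev) {
    g <- dimensionless_groups(dev)
    tau <- if (dev$kind == "reservoir") {
      tau_eff_reservoir(g)
    } else {
      tau_eff_matrix(g)
    }
    tau * g$time_scale_h
  }
  purrr::map_dfr(parameters, function(pn) {
    up <- device
    dn <- device
    up[[pn]] <- device[[pn]] * exp(rel_step)
    dn[[pn]] <- device[[pn]] * exp(-rel_step)
    tibble::tibble(
      parameter = pn,
      elasticity = (log(t_eff_of(up)) - log(t_eff_of(dn))) / (2 * rel_step)
    )
  })
}
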