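#' Describe a two-layer transdermal delivery device
#'
#' A device is a planar two-layer composite: layer 1 is the vehicle (the
#' rate-controlling polymer membrane of a reservoir patch, or the drug-loaded
#' film of a monolithic matrix) occupying `-la <= x <= 0`, layer 2 is the skin
#' occupying `0 <= x <= lb`. Transport in each layer follows Fick's second law
#' with diffusivities `D1` and `D2`; the interface enforces flux continuity
#' and the partition equilibrium `C1(0, t) = km * C2(0, t)`; the receiver side
#' `x = lb` is a perfect sink.
#'
#' Two device kinds are supported:
#' * `"reservoir"`: constant donor concentration `C0` held at `x = -la`
#'   (infinite source), both layers initially drug-free; the flux through the
#'   skin rises to a non-zero steady state.
#' * `"matrix"`: layer 1 uniformly loaded at `C0` with a sealed (zero-flux)
#'   backing at `x = -la`; release is transient and the fraction released
#'   tends to 1.
#'
#' @param kind `"reservoir"` or `"matrix"`.
#' @param D1,D2 Diffusivities of layer 1 (vehicle) and layer 2 (skin), in
#'   cm^2 per `time_unit`. Both must use the same time unit.
#' @param la,lb Layer thicknesses in cm.
#' @param km Dimensionless vehicle/skin partition coefficient at the
#'   interface.
#' @param C0 Donor (reservoir) or initial loading (matrix) concentration in
#'   ug/cm^3.
#' @param A Application area in cm^2; defaults to 1 so per-area quantities
#'   are the primary outputs.
#' @param time_unit Unit of time in `D1` and `D2`: `"s"` or `"h"`.
#'
#' @return An object of class `tdds_device`.
#' @seealso [tdds_fixture()] for the two bundled literature parameter sets,
#'   [dimensionless_groups()], [time_constants()], [flux_profile()],
#'   [fraction_profile()].
#' @examples
#' dev <- tdds_device("reservoir",
#'   D1 = 4.4e-5, D2 = 2.2e-8, la = 0.12, lb = 0.038,
#'   km = 1, C0 = 38000, time_unit = "s"
#' )
#' dev
#' @export
tdds_device <- function(kind = c("reservoir", "matrix"),
                        D1, D2, la, lb, km, C0,
                        A = 1, time_unit = c("s", "h")) {
  kind <- match.arg(kind)
  time_unit <- match.arg(time_unit)
  dev <- structure(
    list(
      kind = kind, D1 = D1, D2 = D2, la = la, lb = lb,
      km = km, C0 = C0, A = A, time_unit = time_unit
    ),
    class = "tdds_device"
  )
  validate_device(dev)
  dev
}

validate_device <- function(dev) {
  check_pos <- function(field, allow_zero = FALSE) {
    x <- dev[[field]]
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (x > 0 || (allow_zero && x >= 0))
    if (!ok) {
      stop(sprintf(
        "invalid device parameter '%s': must be a %s finite number",
        field, if (allow_zero) "non-negative" else "positive"
      ), call. = FALSE)
    }
  }
  for (f in c("D1", "D2", "la", "lb", "km", "A")) check_pos(f)
  check_pos("C0", allow_zero = TRUE)
  invisible(dev)
}

#' @export
print.tdds_device <- function(x, ...) {
  cat(sprintf(
    "<tdds_device: %s>\n  D1 = %g cm^2/%s (vehicle)   D2 = %g cm^2/%s (skin)\n  la = %g cm   lb = %g cm   km = %g\n  C0 = %g ug/cm^3   A = %g cm^2\n",
    x$kind, x$D1, x$time_unit, x$D2, x$time_unit,
    x$la, x$lb, x$km, x$C0, x$A
  ))
  invisible(x)
}

#' Bundled literature device parameter sets
#'
#' Two fixed parameter sets used throughout the package's validation suite.
#'
#' `"metoprolol_tdds1"` is a reservoir patch delivering metoprolol through
#' hairless-rat skin: a 0.12 cm polymer membrane (`D1 = 4.4e-5` cm^2/s)
#' against 0.038 cm of skin (`D2 = 2.2e-8` cm^2/s), `km = 1`, donor
#' concentration 0.038 g/cm^3 (stored as 38000 ug/cm^3). Note that the
#' source literature also quotes 0.036 g/cm^3 for the same experiment; the
#' 0.038 value is the one consistent with the reported steady-state flux of
#' 79.2 ug/cm^2/h and is used here.
#'
#' `"ata_tdds2"` is a monolithic matrix releasing alpha-tocopherol acetate
#' (ATA) from a 0.56 cm isopropyl-myristate donor layer (`D1 = 2.27e-3`
#' cm^2/h) through 0.005 cm of cadaver skin (`D2 = 4.30e-7` cm^2/h),
#' `km = 7.81e-3`, loading 50000 ug/cm^3.
#'
#' @param name `"metoprolol_tdds1"` or `"ata_tdds2"`.
#' @return A [tdds_device()] object.
#' @examples
#' tdds_fixture("metoprolol_tdds1")
#' @export
tdds_fixture <- function(name = c("metoprolol_tdds1", "ata_tdds2")) {
  name <- match.arg(name)
  switch(name,
    metoprolol_tdds1 = tdds_device(
      kind = "reservoir",
      D1 = 4.4e-5, D2 = 2.2e-8, la = 0.12, lb = 0.038,
      km = 1, C0 = 38000, A = 1, time_unit = "s"
    ),
    ata_tdds2 = tdds_device(
      kind = "matrix",
      D1 = 2.27e-3, D2 = 4.30e-7, la = 0.56, lb = 0.005,
      km = 7.81e-3, C0 = 50000, A = 1, time_unit = "h"
    )
  )
}

# hours per device time unit
time_unit_hours <- function(dev) if (dev$time_unit == "s") 1 / 3600 else 1

#' Dimensionless groups of the two-layer problem
#'
#' Nondimensionalises a device into the three groups that fully determine
#' its dynamic shape, plus the time scale that converts dimensionless time
#' back to clock time:
#' \deqn{\beta = \frac{D_2 l_a}{D_1 l_b}, \qquad
#'       p = \frac{D_1 l_b^2}{D_2 l_a^2}, \qquad
#'       \tau = \frac{D_2}{l_b^2}\, t .}
#' `beta` compares the diffusional resistances of the two layers and `p`
#' their diffusion rates on the scaled coordinates; the identity
#' `beta * p = lb / la` holds exactly.
#'
#' @param device A [tdds_device()].
#' @return A `tdds_groups` object with fields `beta`, `p`, `km` and
#'   `time_scale` (`lb^2/D2`, in the device's time unit; also carried in
#'   hours as `time_scale_h`).
#' @examples
#' dimensionless_groups(tdds_fixture("metoprolol_tdds1"))
#' @export
dimensionless_groups <- function(device) {
  validate_device(device)
  ts <- device$lb^2 / device$D2
  tdds_groups(
    beta = device$D2 * device$la / (device$D1 * device$lb),
    p = device$D1 * device$lb^2 / (device$D2 * device$la^2),
    km = device$km,
    time_scale = ts,
    time_scale_h = ts * time_unit_hours(device)
  )
}

#' Construct dimensionless groups directly
#'
#' Mainly useful for parameter sweeps over the dimensionless space without
#' constructing a dimensional device.
#'
#' @param beta,p,km Positive dimensionless groups.
#' @param time_scale Optional time scale `lb^2/D2` (any unit); `NA` for a
#'   purely dimensionless object.
#' @param time_scale_h The same time scale expressed in hours.
#' @return A `tdds_groups` object.
#' @export
tdds_groups <- function(beta, p, km, time_scale = NA_real_,
                        time_scale_h = time_scale) {
  for (nm in c("beta", "p", "km")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("invalid group '%s': must be a positive finite number", nm),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      beta = beta, p = p, km = km,
      time_scale = time_scale, time_scale_h = time_scale_h
    ),
    class = "tdds_groups"
  )
}

#' @export
print.tdds_groups <- function(x, ...) {
  cat(sprintf(
    "<tdds_groups> beta = %g, p = %g, km = %g, time scale = %g%s\n",
    x$beta, x$p, x$km, x$time_scale,
    if (is.finite(x$time_scale_h)) sprintf(" (%g h)", x$time_scale_h) else ""
  ))
  invisible(x)
}

#' Steady-state transdermal flux of a reservoir device
#'
#' The long-time flux through the skin of a reservoir device, from the
#' series-resistance form
#' \deqn{j_{ss} = \frac{C_0}{k_m l_b / D_2 + l_a / D_1}
#'             = \frac{C_0 D_2}{l_b (k_m + \beta)} .}
#' A matrix device has no steady flux (release is transient) and raises an
#' error.
#'
#' @param device A reservoir [tdds_device()].
#' @return Flux in ug/cm^2/h.
#' @examples
#' steady_state_flux(tdds_fixture("metoprolol_tdds1")) # ~79.1 ug/cm^2/h
#' @export
steady_state_flux <- function(device) {
  validate_device(device)
  if (device$kind != "reservoir") {
    stop(
      "steady_state_flux() is only defined for reservoir devices: ",
      "a matrix device does not attain a steady flux",
      call. = FALSE
    )
  }
  g <- dimensionless_groups(device)
  per_unit <- device$C0 * device$D2 / (device$lb * (device$km + g$beta))
  per_unit / time_unit_hours(device)
}

#' Total releasable drug mass of a matrix device
#'
#' The mass eventually released from a monolithic matrix equals the loaded
#' mass, `M_inf = A * la * C0` (mass conservation; all loaded drug exits
#' through the perfect sink).
#'
#' @param device A matrix [tdds_device()].
#' @return Mass in ug.
#' @examples
#' total_releasable(tdds_fixture("ata_tdds2")) # 28000 ug for A = 1 cm^2
#' @export
total_releasable <- function(device) {
  validate_device(device)
  if (device$kind != "matrix") {
    stop(
      "total_releasable() is only defined for matrix devices: ",
      "a reservoir device releases without bound",
      call. = FALSE
    )
  }
  device$A * device$la * device$C0
}
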