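#' Reproduce the published benchmark values for both bundled devices
#'
#' Runs the full reproduction suite against the two bundled parameter sets
#' and compares each computed quantity with its published benchmark value:
#' the metoprolol reservoir system's dimensionless groups (`beta`, `p`),
#' effective time constant (2.15 h), response time (8.60 h), steady flux
#' (79.2 ug/cm^2/h) and flux at 8.60 h (77.62 ug/cm^2/h); and the ATA
#' matrix system's effective time constant (115.3 h), 98% release time
#' (461.4 h) and fraction released at 461.4 h (98%). Optionally repeats the
#' dynamic checks with the finite-difference solver and reports the
#' closed-form / moment-operator identity residuals.
#'
#' @param pde Also run the finite-difference cross-checks (a few seconds).
#' @param inversion Inversion backend for the dynamic checks.
#' @return A tibble with columns `check`, `computed`, `reported`,
#'   `tol_rel` and `pass`.
#' @examples
#' \donttest{
#' validate_reproduction(pde = FALSE)
#' }
#' @export
validate_reproduction <- function(pde = TRUE,
                                  inversion = c("talbot", "euler")) {
  inversion <- match.arg(inversion)
  rows <- list()
  add <- function(check, computed, reported, tol_rel) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, computed = computed, reported = reported,
      tol_rel = tol_rel,
      pass = abs(computed - reported) <= tol_rel * abs(reported)
    )
  }

  res <- tdds_fixture("metoprolol_tdds1")
  g1 <- dimensionless_groups(res)
  add("reservoir beta", g1$beta, 1.58e-3, 0.005)
  add("reservoir p", g1$p, 200.5, 0.005)
  tc1 <- time_constants(res)
  add("reservoir t_eff (h)", tc1$t_eff_h, 2.15, 0.01)
  add("reservoir response time (h)", tc1$response_time_h, 8.60, 0.01)
  add("reservoir steady flux (ug/cm^2/h)", tc1$steady_flux, 79.2, 0.005)
  f86 <- flux_profile(res, times = 8.60, inversion = inversion)
  add("reservoir flux at 8.60 h (ug/cm^2/h)", f86$flux_ug_cm2_h, 77.62, 0.01)

  mat <- tdds_fixture("ata_tdds2")
  tc2 <- time_constants(mat)
  add("matrix t_eff (h)", tc2$t_eff_h, 115.3, 0.02)
  add("matrix 98% release time (h)", tc2$response_time_h, 461.4, 0.02)
  fr <- fraction_profile(mat, times = 461.4, inversion = inversion)
  add("matrix fraction at 461.4 h (%)", 100 * fr$fraction, 98, 0.0102)

  ## closed form vs moment operator (identity residuals)
  op1 <- time_constants(res, method = "operator")
  add("reservoir operator/closed-form identity", op1$tau_eff, tc1$tau_eff, 1e-6)
  op2 <- time_constants(mat, method = "operator")
  add("matrix operator/closed-form identity", op2$tau_eff, tc2$tau_eff, 1e-6)

  if (pde) {
    sol1 <- solve_pde(res)
    fs <- flux_series(sol1)
    add(
      "reservoir steady flux, PDE (ug/cm^2/h)",
      fs$flux_ug_cm2_h[nrow(fs)], 79.2, 0.005
    )
    add(
      "reservoir flux at 8.60 h, PDE (ug/cm^2/h)",
      stats::approx(fs$time_h, fs$flux_ug_cm2_h, 8.60)$y, 77.62, 0.01
    )
    sol2 <- solve_pde(mat)
    cs <- cumulative_series(sol2)
    add(
      "matrix fraction at 461.4 h, PDE (%)",
      100 * stats::approx(cs$time_h, cs$fraction, 461.4)$y, 98, 0.0102
    )
    add("matrix PDE first moment (h)", pde_effective_time(sol2),
      tc2$t_eff_h, 0.005)
  }

  dplyr::bind_rows(rows)
}
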