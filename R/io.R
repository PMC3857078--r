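DEVICE_KEYS <- c("kind", "D1", "D2", "la", "lb", "km", "C0", "A", "time_unit")
DEVICE_REQUIRED <- c("kind", "D1", "D2", "la", "lb", "km", "C0")

#' Read a device description from a JSON or YAML config file
#'
#' The format is auto-detected from the file extension (`.json` vs
#' `.yml`/`.yaml`). Accepted keys are exactly `kind`, `D1`, `D2`, `la`,
#' `lb`, `km`, `C0`, `A` (optional, default 1) and `time_unit` (optional,
#' default `"s"`); unknown keys are rejected so unit mistakes do not pass
#' silently.
#'
#' @param path Path to the config file.
#' @return A [tdds_device()].
#' @export
read_device_config <- function(path) {
  if (!file.exists(path)) {
    stop("device config not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config extension '", ext, "' (use .json or .yaml)",
      call. = FALSE
    )
  )
  device_from_list(raw)
}

device_from_list <- function(raw) {
  if (!is.list(raw)) stop("device config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), DEVICE_KEYS)
  if (length(unknown) > 0) {
    stop("unknown device config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(DEVICE_REQUIRED, names(raw))
  if (length(missing) > 0) {
    stop("missing device config key(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tdds_device(
    kind = raw$kind,
    D1 = as.numeric(raw$D1), D2 = as.numeric(raw$D2),
    la = as.numeric(raw$la), lb = as.numeric(raw$lb),
    km = as.numeric(raw$km), C0 = as.numeric(raw$C0),
    A = if (is.null(raw$A)) 1 else as.numeric(raw$A),
    time_unit = if (is.null(raw$time_unit)) "s" else raw$time_unit
  )
}

#' Write a device description to JSON or YAML
#'
#' @param device A [tdds_device()].
#' @param path Output path ending in `.json`, `.yml` or `.yaml`.
#' @return `path`, invisibly.
#' @export
write_device_config <- function(device, path) {
  validate_device(device)
  x <- unclass(device)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yml = ,
    yaml = yaml::write_yaml(x, path),
    stop("unsupported config extension '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Export a release profile as CSV
#'
#' Writes a comma-separated file with a header row and the fixed column set
#' `time_h, flux_ug_cm2_h, cumulative_ug, fraction` ('.' decimal mark,
#' locale-independent); columns that do not apply to the device kind are
#' left empty.
#'
#' @param profile A `release_profile` from [flux_profile()] or
#'   [fraction_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  out <- data.frame(
    time_h = profile$time_h,
    flux_ug_cm2_h = if ("flux_ug_cm2_h" %in% names(profile)) {
      profile$flux_ug_cm2_h
    } else {
      NA_real_
    },
    cumulative_ug = profile$cumulative_ug,
    fraction = if ("fraction" %in% names(profile)) {
      profile$fraction
    } else {
      NA_real_
    }
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
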