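#' Sensor chip geometry
#'
#' Describes the fixed geometry of the electrothermal sensing microchip: a
#' platinum microheater at the centre of a 1 x 0.5 mm active region,
#' surrounded by three resistance temperature detectors (RTDs) and a pair of
#' concentric circular interdigitated electrodes (IDEs), with a thermal
#' isolation trench etched around the heater. The two IDE diameters set the
#' geometric factor that converts a measured surface resistance into a sheet
#' resistivity; the electrode cross-sectional area enters the bulk
#' resistivity estimate.
#'
#' @param d1_um Outer diameter of the inner IDE electrode, in micrometres.
#' @param d2_um Inner diameter of the outer IDE electrode, in micrometres.
#'   Must exceed `d1_um`.
#' @param electrode_area_m2 Cross-sectional area (m^2) used in the bulk
#'   resistivity relation `rho_B = R_B * A / l`. Defaults to the disc area of
#'   the outer electrode, `pi * (d2 / 2)^2`. The forward simulator and the
#'   inverse estimator share this value, so parameter recovery does not
#'   depend on the absolute choice.
#' @param active_region_mm Length-2 numeric, extent of the active sensing
#'   region in mm.
#' @param chip_extent_mm Length-2 numeric, overall chip dimensions in mm.
#' @param trench_depth_um Depth of the thermal isolation trench, micrometres.
#'
#' @return An object of class `chip_geometry`.
#' @examples
#' chip <- chip_geometry()
#' geometric_factor(chip)
#' @export
chip_geometry <- function(d1_um = 130,
                          d2_um = 140,
                          electrode_area_m2 = pi * (d2_um / 2 * 1e-6)^2,
                          active_region_mm = c(1, 0.5),
                          chip_extent_mm = c(12, 7),
                          trench_depth_um = 350) {
  if (!is.numeric(d1_um) || !is.numeric(d2_um) || d1_um <= 0 || d2_um <= d1_um) {
    stop("invalid geometry: electrode diameters must satisfy d2 > d1 > 0",
         call. = FALSE)
  }
  if (electrode_area_m2 <= 0) {
    stop("invalid geometry: electrode_area_m2 must be positive", call. = FALSE)
  }
  structure(
    list(
      d1_um = d1_um,
      d2_um = d2_um,
      electrode_area_m2 = electrode_area_m2,
      active_region_mm = active_region_mm,
      chip_extent_mm = chip_extent_mm,
      trench_depth_um = trench_depth_um
    ),
    class = "chip_geometry"
  )
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("<chip_geometry>\n")
  cat(sprintf("  IDE diameters D1 = %g um, D2 = %g um (factor %.3f)\n",
              x$d1_um, x$d2_um, geometric_factor(x)))
  cat(sprintf("  electrode area  = %.4g m^2\n", x$electrode_area_m2))
  cat(sprintf("  active region   = %g x %g mm, chip %g x %g mm, trench %g um\n",
              x$active_region_mm[1], x$active_region_mm[2],
              x$chip_extent_mm[1], x$chip_extent_mm[2], x$trench_depth_um))
  invisible(x)
}

#' Geometric factor of the concentric interdigitated electrodes
#'
#' For concentric circular electrodes with gap between diameters `D1` (outer
#' diameter of the inner electrode) and `D2` (inner diameter of the outer
#' electrode), the sheet resistivity of a film contacting both electrodes is
#' `rho_S = 2 * pi / log(D2 / D1) * R_s`. This function returns the
#' dimensionless multiplier `2 * pi / log(D2 / D1)`; with the default chip
#' geometry (130/140 um) it equals 84.8 to three significant figures.
#'
#' The factor is scale invariant: it depends only on the diameter ratio.
#'
#' @param geometry A [chip_geometry()].
#' @return Positive scalar multiplier applied to surface resistance.
#' @export
geometric_factor <- function(geometry = chip_geometry()) {
  stopifnot(inherits(geometry, "chip_geometry"))
  ratio <- geometry$d2_um / geometry$d1_um
  if (!is.finite(ratio) || ratio <= 1) {
    stop("invalid geometry: log(D2/D1) must be positive", call. = FALSE)
  }
  2 * pi / log(ratio)
}

#' RTD calibration
#'
#' Linear resistance-temperature law for a thin-film platinum resistance
#' temperature detector, `R(T) = R0 * (1 + alpha * (T - T0))`. A single
#' first-order temperature coefficient of resistance (TCR) is used; the
#' default `alpha = 2.2e-3` per degree Celsius is the value measured for the
#' fabricated platinum film.
#'
#' @param r0_ohm Resistance at the reference temperature, ohms.
#' @param t0_c Reference temperature, degrees Celsius.
#' @param alpha_per_c Temperature coefficient of resistance, 1/degC.
#' @return An object of class `rtd_calibration`.
#' @examples
#' cal <- rtd_calibration(r0_ohm = 100, t0_c = 25)
#' temperature_to_resistance(37, cal)
#' @export
rtd_calibration <- function(r0_ohm = 100, t0_c = 25, alpha_per_c = 2.2e-3) {
  if (r0_ohm <= 0) stop("invalid calibration: r0_ohm must be positive", call. = FALSE)
  if (alpha_per_c <= 0) stop("invalid calibration: alpha_per_c must be positive", call. = FALSE)
  structure(
    list(r0_ohm = r0_ohm, t0_c = t0_c, alpha_per_c = alpha_per_c),
    class = "rtd_calibration"
  )
}

#' @export
print.rtd_calibration <- function(x, ...) {
  cat(sprintf("<rtd_calibration> R0 = %g ohm at %g degC, alpha = %g /degC\n",
              x$r0_ohm, x$t0_c, x$alpha_per_c))
  invisible(x)
}

#' Convert an RTD resistance reading to temperature
#'
#' Inverts the linear RTD law: `T = T0 + (R / R0 - 1) / alpha`. Vectorised
#' over `r_ohm`; round-trips with [temperature_to_resistance()] to machine
#' precision.
#'
#' @param r_ohm Measured RTD resistance(s), ohms; must be positive.
#' @param calib An [rtd_calibration()].
#' @return Temperature(s) in degrees Celsius.
#' @export
rtd_resistance_to_temperature <- function(r_ohm, calib = rtd_calibration()) {
  stopifnot(inherits(calib, "rtd_calibration"))
  if (any(!is.finite(r_ohm)) || any(r_ohm <= 0)) {
    stop("invalid measurement: RTD resistance must be positive and finite",
         call. = FALSE)
  }
  calib$t0_c + (r_ohm / calib$r0_ohm - 1) / calib$alpha_per_c
}

#' Forward RTD law: temperature to resistance
#'
#' `R = R0 * (1 + alpha * (T - T0))`; monotone increasing in temperature.
#'
#' @param t_c Temperature(s), degrees Celsius.
#' @inheritParams rtd_resistance_to_temperature
#' @return Resistance(s) in ohms.
#' @export
temperature_to_resistance <- function(t_c, calib = rtd_calibration()) {
  stopifnot(inherits(calib, "rtd_calibration"))
  calib$r0_ohm * (1 + calib$alpha_per_c * (t_c - calib$t0_c))
}

#' Fit an RTD calibration from temperature/resistance pairs
#'
#' Ordinary least squares of resistance on temperature. The fitted line is
#' reparameterised about the chosen reference temperature `t0_c`:
#' `R0 = R(t0)` and `alpha = slope / R0`. On exactly linear input the
#' generating coefficients are recovered to machine precision.
#'
#' @param temperature_c Temperatures of the calibration points, degC.
#' @param resistance_ohm Measured resistances at those temperatures, ohms.
#' @param t0_c Reference temperature for the returned calibration.
#' @return An [rtd_calibration()].
#' @export
fit_rtd_calibration <- function(temperature_c, resistance_ohm, t0_c = 25) {
  if (length(temperature_c) != length(resistance_ohm)) {
    stop("input error: temperature and resistance lengths differ", call. = FALSE)
  }
  if (length(unique(temperature_c)) < 2) {
    stop("degenerate fit: need at least two distinct temperatures", call. = FALSE)
  }
  fit <- stats::lm(resistance_ohm ~ temperature_c)
  slope <- unname(stats::coef(fit)[2])
  r0 <- unname(stats::coef(fit)[1]) + slope * t0_c
  if (r0 <= 0 || slope <= 0) {
    stop("degenerate fit: fitted RTD line implies nonpositive R0 or alpha",
         call. = FALSE)
  }
  rtd_calibration(r0_ohm = r0, t0_c = t0_c, alpha_per_c = slope / r0)
}

#' Microheater power from its drive voltage and current
#'
#' `Q = V * I`, the Joule power delivered by the heater driver. Vectorised.
#'
#' @param v_volt Heater voltage(s), volts; nonnegative.
#' @param i_amp Heater current(s), amperes; nonnegative.
#' @return Power in watts.
#' @export
heater_power <- function(v_volt, i_amp) {
  if (any(v_volt < 0) || any(i_amp < 0)) {
    stop("invalid measurement: heater voltage and current must be nonnegative",
         call. = FALSE)
  }
  v_volt * i_amp
}
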