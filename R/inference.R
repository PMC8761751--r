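#' Bulk resistivity from a through-tissue resistance
#'
#' `rho_B = R_B * A / l` for a block of thickness `l` measured through its
#' bulk with electrode cross-section `A`. Computed in SI (ohm m); use
#' [ohm_m_to_ohm_cm()] for the conventional reporting unit.
#'
#' @param r_bulk_ohm Measured bulk resistance, ohms.
#' @param electrode_area_m2 Electrode cross-sectional area, m^2.
#' @param thickness_m Tissue thickness, m.
#' @return Bulk resistivity in ohm m. Vectorised.
#' @export
bulk_resistivity <- function(r_bulk_ohm, electrode_area_m2, thickness_m) {
  if (any(r_bulk_ohm <= 0) || any(electrode_area_m2 <= 0) || any(thickness_m <= 0)) {
    stop("invalid measurement: resistance, area and thickness must be positive",
         call. = FALSE)
  }
  r_bulk_ohm * electrode_area_m2 / thickness_m
}

#' @rdname bulk_resistivity
#' @param rho_ohm_m Resistivity in ohm m.
#' @export
ohm_m_to_ohm_cm <- function(rho_ohm_m) rho_ohm_m * 100

#' Surface (sheet) resistivity from an IDE surface resistance
#'
#' `rho_S = g * R_s` where `g = 2 * pi / log(D2/D1)` is the concentric-IDE
#' geometric factor ([geometric_factor()]); 84.8 for the default chip.
#'
#' @param r_surf_ohm Measured surface resistance, ohms.
#' @param geometry A [chip_geometry()].
#' @return Sheet resistivity in ohm per square. Vectorised.
#' @export
surface_resistivity <- function(r_surf_ohm, geometry = chip_geometry()) {
  if (any(r_surf_ohm <= 0)) {
    stop("invalid measurement: surface resistance must be positive", call. = FALSE)
  }
  geometric_factor(geometry) * r_surf_ohm
}

#' Triangulated sink temperature from the three RTD readings
#'
#' Converts each RTD resistance to temperature via the linear calibration and
#' returns the unweighted arithmetic mean of the available readings. If fewer
#' than three readings are valid (positive and finite) the mean of the valid
#' ones is returned with a warning; with no valid reading a sensor-failure
#' error is raised.
#'
#' @param rtd_ohm Numeric vector of RTD resistances (normally length 3).
#' @param calib An [rtd_calibration()].
#' @return Sink temperature, degC.
#' @export
sink_temperature <- function(rtd_ohm, calib = rtd_calibration()) {
  ok <- is.finite(rtd_ohm) & rtd_ohm > 0
  if (!any(ok)) {
    stop("sensor failure: no valid RTD reading", call. = FALSE)
  }
  if (sum(ok) < length(rtd_ohm)) {
    warning(sprintf("only %d of %d RTD readings valid; using their mean",
                    sum(ok), length(rtd_ohm)), call. = FALSE)
  }
  mean(rtd_resistance_to_temperature(rtd_ohm[ok], calib))
}

#' Steady-state thermal conductivity from a one-dimensional heat balance
#'
#' With the tissue heated from one face and the opposite face held at the
#' sink temperature, the ex vivo bioheat equation reduces to steady
#' conduction and `k = Q * l / (A * dT)`, where `Q` is the heater power, `l`
#' the tissue thickness, `A` the heat-transfer contact area and
#' `dT = t_source - t_sink` the steady temperature drop across the sample.
#'
#' @param q_w Heater power, W; positive.
#' @param thickness_m Tissue thickness, m.
#' @param contact_area_m2 Heat-transfer area, m^2.
#' @param t_source_c Heated-face temperature, degC.
#' @param t_sink_c Sink-face temperature, degC; must be below `t_source_c`.
#' @return Thermal conductivity in W m^-1 K^-1. Vectorised.
#' @export
thermal_conductivity <- function(q_w, thickness_m, contact_area_m2,
                                 t_source_c, t_sink_c) {
  if (any(q_w <= 0)) {
    stop("invalid measurement: heater power must be positive", call. = FALSE)
  }
  dt <- t_source_c - t_sink_c
  if (any(dt <= 0)) {
    stop("no gradient: source temperature must exceed sink temperature",
         call. = FALSE)
  }
  q_w * thickness_m / (contact_area_m2 * dt)
}

#' Invert raw measurement records into an electrothermal profile
#'
#' Builds the per-sample profile of bulk resistivity, surface resistivity and
#' thermal conductivity across the temperature ramp from a set of raw
#' measurement records of a single sample. Surface resistivity is averaged
#' over the two chips; heater power comes from [heater_power()]; the
#' temperature drop is the heater source temperature minus the triangulated
#' RTD sink temperature ([sink_temperature()]).
#'
#' Records with a missing or nonpositive observable yield `NA` for the
#' affected parameter at that setpoint; the remaining parameters are still
#' computed.
#'
#' @param records Tibble of measurement rows for one sample (measurement CSV
#'   schema).
#' @param chip A [chip_geometry()].
#' @param calib An [rtd_calibration()].
#' @param geometry One-row tibble with `thickness_mm` and `contact_area_m2`
#'   (see [sample_geometry()]).
#' @return A tibble sorted by setpoint: `temperature_c`, `rho_b_ohm_cm`,
#'   `rho_s_ohm_sq`, `k_w_m_k`, `delta_t_k`, `q_w`.
#' @export
build_profile <- function(records, chip = chip_geometry(),
                          calib = rtd_calibration(),
                          geometry = sample_geometry()) {
  if (nrow(records) < 1) stop("input error: no measurement records", call. = FALSE)
  if (length(unique(records$sample_id)) > 1) {
    stop("input error: records mix multiple sample ids", call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$setpoint_c)
  l_m <- geometry$thickness_mm * 1e-3

  one <- function(row) {
    rho_b <- tryCatch(
      ohm_m_to_ohm_cm(bulk_resistivity(row$r_bulk_ohm, chip$electrode_area_m2, l_m)),
      error = function(e) NA_real_)
    rho_s <- tryCatch(
      mean(surface_resistivity(c(row$r_surf1_ohm, row$r_surf2_ohm), chip)),
      error = function(e) NA_real_)
    thermal <- tryCatch({
      q <- heater_power(row$heater_v, row$heater_i)
      t_sink <- sink_temperature(c(row$rtd1_ohm, row$rtd2_ohm, row$rtd3_ohm), calib)
      dt <- row$t_source_c - t_sink
      k <- thermal_conductivity(q, l_m, geometry$contact_area_m2,
                                row$t_source_c, t_sink)
      c(k, dt, q)
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    tibble::tibble(
      sample_id = row$sample_id,
      temperature_c = row$setpoint_c,
      rho_b_ohm_cm = rho_b,
      rho_s_ohm_sq = rho_s,
      k_w_m_k = thermal[1],
      delta_t_k = thermal[2],
      q_w = thermal[3]
    )
  }
  dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) one(records[i, ])))
}

#' Invert a whole study of measurement records
#'
#' Applies [build_profile()] to every sample in a measurement table, using
#' each sample's own block geometry, and carries the sample metadata
#' (patient, group, preparation) through to the profiles.
#'
#' @param measurements Measurement tibble (one row per sample x setpoint).
#' @param geometry Tibble with one row per `sample_id` giving `thickness_mm`
#'   and `contact_area_m2`; typically the `truth` table of
#'   [generate_study()].
#' @inheritParams build_profile
#' @return A tibble of profile rows with sample metadata attached.
#' @export
build_profiles <- function(measurements, geometry,
                           chip = chip_geometry(),
                           calib = rtd_calibration()) {
  meta <- dplyr::distinct(measurements, .data$sample_id, .data$patient_id,
                          .data$group, .data$preparation)
  out <- lapply(split(measurements, measurements$sample_id), function(rec) {
    geo <- geometry[geometry$sample_id == rec$sample_id[1], ]
    if (nrow(geo) != 1) {
      stop("input error: missing or duplicated geometry for sample ",
           rec$sample_id[1], call. = FALSE)
    }
    build_profile(rec, chip = chip, calib = calib, geometry = geo)
  })
  dplyr::arrange(
    dplyr::left_join(dplyr::bind_rows(out), meta, by = "sample_id"),
    .data$sample_id, .data$temperature_c
  )
}
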