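#' Reference group parameters for the paired tumor/normal breast cohort
#'
#' Returns the group-level electrothermal parameters used as defaults by the
#' synthetic cohort generator: one row per preparation (deparaffinized FFPE
#' or formalin-fixed) and tissue group (tumor or adjacent normal), with the
#' mean and reported spread of bulk resistivity (ohm cm), surface resistivity
#' (ohm per square) and thermal conductivity (W m^-1 K^-1) at the two
#' endpoint tissue temperatures, 25 and 37 degrees Celsius. The `fold_*`
#' columns are the ratios of the 37 degC mean to the 25 degC mean.
#'
#' The spreads are the published standard errors of the group means; see
#' [sample_tissue_truth()] for how they are converted to per-sample
#' variability.
#'
#' @return A tibble with 4 rows (2 preparations x 2 groups).
#' @examples
#' default_group_parameters()
#' @export
default_group_parameters <- function() {
  tab <- tibble::tribble(
    ~preparation,     ~group,
    ~rho_b_25_mean, ~rho_b_25_spread, ~rho_b_37_mean, ~rho_b_37_spread,
    ~rho_s_25_mean, ~rho_s_25_spread, ~rho_s_37_mean, ~rho_s_37_spread,
    ~k_25_mean,     ~k_25_spread,     ~k_37_mean,     ~k_37_spread,

    "deparaffinized", "normal",
    148.42,  76.44,  456.09,  194.63,
    221.24,  74.71,  648.20,  419.44,
    0.456,   0.023,  0.470,   0.018,

    "deparaffinized", "tumor",
    411.25,  172.03, 1980.87, 185.00,
    753.05,  292.05, 3131.88, 638.18,
    0.207,   0.023,  0.255,   0.0255,

    "formalin_fixed", "normal",
    56.39,   10.40,  195.70,  62.19,
    160.50,  24.25,  484.97,  159.81,
    0.563,   0.028,  0.599,   0.022,

    "formalin_fixed", "tumor",
    224.125, 61.72,  991.40,  152.92,
    507.08,  162.19, 2095.07, 116.83,
    0.309,   0.020,  0.335,   0.0206
  )
  dplyr::mutate(
    tab,
    fold_rho_b = .data$rho_b_37_mean / .data$rho_b_25_mean,
    fold_rho_s = .data$rho_s_37_mean / .data$rho_s_25_mean,
    fold_k     = .data$k_37_mean / .data$k_25_mean
  )
}

#' Tissue block geometry
#'
#' Nominal cubical sample blocks are 5 x 5 x 3 mm (length x breadth x
#' height), cut with tolerances of +/- 0.15, 0.23 and 0.13 mm respectively.
#' The contact area for heat transfer is the 5 x 5 mm face pressed against
#' the chips; the thickness is the 3 mm heat/current path between the two
#' indenter chips.
#'
#' @param side_x_mm,side_y_mm In-plane block sides, mm.
#' @param thickness_mm Block thickness along the measurement axis, mm.
#' @return A one-row tibble with the dimensions and derived
#'   `contact_area_m2`.
#' @export
sample_geometry <- function(side_x_mm = 5, side_y_mm = 5, thickness_mm = 3) {
  if (any(c(side_x_mm, side_y_mm, thickness_mm) <= 0)) {
    stop("invalid geometry: block dimensions must be positive", call. = FALSE)
  }
  tibble::tibble(
    side_x_mm = side_x_mm,
    side_y_mm = side_y_mm,
    thickness_mm = thickness_mm,
    contact_area_m2 = side_x_mm * side_y_mm * 1e-6
  )
}

#' Study configuration for the synthetic cohort generator
#'
#' Encodes the measurement protocol and study design: by default 4 patients
#' per preparation (deparaffinized and formalin-fixed), paired tumor and
#' adjacent-normal blocks, 3 technical repeats per block (48 samples in
#' total), and a temperature ramp from 25 to 37 degC in 3 degC steps. The
#' ramp is capped at 37 degC because collagen is thermally unstable beyond
#' that temperature.
#'
#' @param patients_per_preparation Number of patients per preparation arm.
#' @param repeats_per_block Technical repeats cut from each tumor/normal
#'   block.
#' @param preparations Character vector, subset of
#'   `c("deparaffinized", "formalin_fixed")`.
#' @param setpoints_c Heater setpoints in degC, all within `[25, 37]`.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise applied to each raw observable (resistances, heater
#'   voltage and current, RTD temperature readings). `0` gives noiseless
#'   records that invert exactly to the generating truth.
#' @param ambient_c Temperature of the passive (sink) side of the sample,
#'   degC. Must be below the lowest setpoint so a steady-state gradient
#'   exists at every setpoint.
#' @param endpoint_correlation Correlation, on the log scale, between a
#'   sample's parameter values at 25 and 37 degC. The two endpoints are
#'   measured on the same physical block, so they are strongly correlated;
#'   default 0.8.
#' @param repeat_cv Within-specimen coefficient of variation of technical
#'   repeats: repeats cut from the same block share a specimen-level draw
#'   and scatter around it with this CV (default 0.15, typical bench-level
#'   repeatability); the group-level marginal moments are preserved.
#' @param sem_n Number of samples per group cell assumed when converting the
#'   published standard errors of [default_group_parameters()] into
#'   per-sample standard deviations (SD = spread * sqrt(sem_n)); the study
#'   design gives 12 (4 patients x 3 repeats).
#' @param geometry_tolerance_mm Length-3 cutting tolerances (x, y, thickness)
#'   around the nominal 5 x 5 x 3 mm block.
#' @param seed Integer seed fixing every random draw of the generator.
#' @param chip A [chip_geometry()].
#' @param calib An [rtd_calibration()].
#' @param group_parameters Group parameter table in the layout of
#'   [default_group_parameters()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(patients_per_preparation = 4,
                         repeats_per_block = 3,
                         preparations = c("deparaffinized", "formalin_fixed"),
                         setpoints_c = seq(25, 37, by = 3),
                         noise_cv = 0.02,
                         ambient_c = 20,
                         endpoint_correlation = 0.8,
                         repeat_cv = 0.15,
                         sem_n = 12,
                         geometry_tolerance_mm = c(0.15, 0.23, 0.13),
                         seed = 1L,
                         chip = chip_geometry(),
                         calib = rtd_calibration(),
                         group_parameters = default_group_parameters()) {
  preparations <- match.arg(preparations,
                            c("deparaffinized", "formalin_fixed"),
                            several.ok = TRUE)
  if (patients_per_preparation < 1 || repeats_per_block < 1) {
    stop("invalid config: counts must be at least 1", call. = FALSE)
  }
  if (any(setpoints_c < 25) || any(setpoints_c > 37)) {
    stop("protocol error: setpoints must lie within [25, 37] degC",
         call. = FALSE)
  }
  if (ambient_c >= min(setpoints_c)) {
    stop("invalid config: ambient_c must be below the lowest setpoint",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("invalid config: noise_cv must be nonnegative", call. = FALSE)
  if (repeat_cv < 0) stop("invalid config: repeat_cv must be nonnegative", call. = FALSE)
  if (abs(endpoint_correlation) > 1) {
    stop("invalid config: endpoint_correlation must be in [-1, 1]", call. = FALSE)
  }
  structure(
    list(
      patients_per_preparation = as.integer(patients_per_preparation),
      repeats_per_block = as.integer(repeats_per_block),
      preparations = preparations,
      setpoints_c = sort(setpoints_c),
      noise_cv = noise_cv,
      ambient_c = ambient_c,
      endpoint_correlation = endpoint_correlation,
      repeat_cv = repeat_cv,
      sem_n = sem_n,
      geometry_tolerance_mm = geometry_tolerance_mm,
      seed = as.integer(seed),
      chip = chip,
      calib = calib,
      group_parameters = group_parameters
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  %d patient(s) x %s, %d repeats/block, setpoints %s degC\n",
              x$patients_per_preparation,
              paste(x$preparations, collapse = " + "),
              x$repeats_per_block,
              paste(x$setpoints_c, collapse = ", ")))
  cat(sprintf("  noise_cv = %g, ambient = %g degC, seed = %d\n",
              x$noise_cv, x$ambient_c, x$seed))
  invisible(x)
}

# log-scale moments of a moment-matched lognormal, split into block-level
# and repeat-level components: repeats cut from the same specimen share the
# block draw and scatter around it with coefficient of variation repeat_cv.
.lognormal_components <- function(mean, sd, repeat_cv) {
  if (mean <= 0) stop("invalid parameters: mean must be positive", call. = FALSE)
  if (sd < 0) stop("invalid parameters: spread must be nonnegative", call. = FALSE)
  s_tot <- sqrt(log(1 + (sd / mean)^2))
  s_w <- min(sqrt(log(1 + repeat_cv^2)), s_tot)
  list(meanlog = log(mean) - s_tot^2 / 2,
       s_block = sqrt(s_tot^2 - s_w^2),
       s_repeat = s_w)
}

#' Draw ground-truth tissue parameters for technical repeats of one specimen
#'
#' Samples per-repeat electrothermal ground truth from a hierarchical,
#' moment-matched lognormal model of the group distribution. For each
#' parameter the values at the 25 and 37 degC endpoints are drawn as a
#' correlated bivariate lognormal whose marginal means and standard
#' deviations match the group table (the reported spreads are standard
#' errors, scaled by `sqrt(sem_n)` to per-sample SDs); the per-sample fold
#' factor is the ratio of the two draws. The `n` repeats share a
#' specimen-level (block) draw and scatter around it with coefficient of
#' variation `repeat_cv`, reflecting that technical repeats are cut from the
#' same tissue; the marginal moments are unchanged by the split. Block
#' dimensions are drawn uniformly within the cutting tolerances.
#'
#' A zero spread collapses the distribution so every draw equals the mean.
#'
#' @param params One row of [default_group_parameters()] (or same layout).
#' @param n Number of technical repeats to draw for the specimen.
#' @param sem_n,endpoint_correlation,repeat_cv,geometry_tolerance_mm See
#'   [study_config()].
#' @return A tibble of `n` ground-truth rows: `rho_b_25` (ohm cm),
#'   `rho_s_25` (ohm/sq), `k_25` (W m^-1 K^-1), fold factors to 37 degC, and
#'   block geometry.
#' @export
sample_tissue_truth <- function(params,
                                n = 1,
                                sem_n = 12,
                                endpoint_correlation = 0.8,
                                repeat_cv = 0.15,
                                geometry_tolerance_mm = c(0.15, 0.23, 0.13)) {
  stopifnot(nrow(params) == 1)
  r <- endpoint_correlation
  draw_pair <- function(m25, s25, m37, s37) {
    c25 <- .lognormal_components(m25, s25 * sqrt(sem_n), repeat_cv)
    c37 <- .lognormal_components(m37, s37 * sqrt(sem_n), repeat_cv)
    u1 <- stats::rnorm(1); u2 <- r * u1 + sqrt(1 - r^2) * stats::rnorm(1)
    e1 <- stats::rnorm(n); e2 <- r * e1 + sqrt(1 - r^2) * stats::rnorm(n)
    draw <- function(cc, u, e, m) {
      if (cc$s_block == 0 && cc$s_repeat == 0) return(rep(m, n))
      exp(cc$meanlog + cc$s_block * u + cc$s_repeat * e)
    }
    v25 <- draw(c25, u1, e1, m25)
    v37 <- draw(c37, u2, e2, m37)
    list(v25 = v25, fold = v37 / v25)
  }
  rb <- draw_pair(params$rho_b_25_mean, params$rho_b_25_spread,
                  params$rho_b_37_mean, params$rho_b_37_spread)
  rs <- draw_pair(params$rho_s_25_mean, params$rho_s_25_spread,
                  params$rho_s_37_mean, params$rho_s_37_spread)
  kk <- draw_pair(params$k_25_mean, params$k_25_spread,
                  params$k_37_mean, params$k_37_spread)
  nom <- sample_geometry()
  tol <- geometry_tolerance_mm
  sx <- stats::runif(n, nom$side_x_mm - tol[1], nom$side_x_mm + tol[1])
  sy <- stats::runif(n, nom$side_y_mm - tol[2], nom$side_y_mm + tol[2])
  th <- stats::runif(n, nom$thickness_mm - tol[3], nom$thickness_mm + tol[3])
  tibble::tibble(
    group = params$group,
    preparation = params$preparation,
    rho_b_25 = rb$v25, fold_rho_b = rb$fold,
    rho_s_25 = rs$v25, fold_rho_s = rs$fold,
    k_25 = kk$v25, fold_k = kk$fold,
    side_x_mm = sx, side_y_mm = sy, thickness_mm = th,
    contact_area_m2 = sx * sy * 1e-6
  )
}

# true parameter values at an intermediate setpoint: geometric (log-linear)
# interpolation between the 25/37 endpoints for resistivities, linear for k
.true_at <- function(truth, t_c) {
  frac <- (t_c - 25) / 12
  list(
    rho_b = truth$rho_b_25 * truth$fold_rho_b^frac,
    rho_s = truth$rho_s_25 * truth$fold_rho_s^frac,
    k = truth$k_25 * (1 + (truth$fold_k - 1) * frac)
  )
}

# precalibrated heater drive voltage for a target temperature: Joule power
# scales as V^2, and the required power scales with the temperature lift
.heater_voltage_map <- function(t_c, ambient_c, v_ref = 2) {
  v_ref * sqrt((t_c - ambient_c) / (37 - ambient_c))
}

#' Forward-simulate raw measurement records for one tissue block
#'
#' Runs the measurement physics forward at every setpoint of the protocol:
#'
#' * bulk resistance `R_B = rho_B(T) * l / A_electrode`;
#' * surface resistance on each chip `R_s = rho_S(T) / g` with `g` the IDE
#'   geometric factor;
#' * steady-state heater power `Q = k(T) * A_contact * (T - T_ambient) / l`,
#'   split into a precalibrated drive voltage and the matching current;
#' * three sink-side RTD resistance readings at the ambient-side steady
#'   temperature.
#'
#' Between the 25 and 37 degC endpoints, resistivities follow geometric
#' (log-linear) interpolation `rho(T) = rho(25) * fold^((T - 25)/12)` and
#' thermal conductivity interpolates linearly. Multiplicative Gaussian noise
#' with coefficient of variation `noise_cv` is applied independently to each
#' raw observable (both resistances per chip, heater voltage and current, and
#' each RTD temperature reading). With `noise_cv = 0` the inverse pipeline
#' recovers the generating truth exactly.
#'
#' @param truth One ground-truth row from [sample_tissue_truth()], optionally
#'   carrying `sample_id` / `patient_id` metadata.
#' @param config A [study_config()].
#' @return A tibble of measurement records, one row per setpoint, in the
#'   measurement CSV schema (see [write_measurements()]).
#' @export
forward_measurements <- function(truth, config = study_config()) {
  stopifnot(inherits(config, "study_config"), nrow(truth) == 1)
  if (any(config$setpoints_c < 25) || any(config$setpoints_c > 37)) {
    stop("protocol error: setpoints must lie within [25, 37] degC", call. = FALSE)
  }
  chip <- config$chip
  calib <- config$calib
  cv <- config$noise_cv
  noisy <- function(x) x * (1 + cv * stats::rnorm(length(x)))

  l_m <- truth$thickness_mm * 1e-3
  a_contact <- truth$contact_area_m2
  g <- geometric_factor(chip)

  rows <- lapply(config$setpoints_c, function(t_set) {
    tr <- .true_at(truth, t_set)
    r_bulk <- (tr$rho_b / 100) * l_m / chip$electrode_area_m2  # ohm cm -> ohm m
    r_surf <- tr$rho_s / g
    t_sink <- config$ambient_c
    q <- tr$k * a_contact * (t_set - t_sink) / l_m
    v <- .heater_voltage_map(t_set, config$ambient_c)
    i <- q / v
    rtd_t <- noisy(rep(t_sink, 3))
    tibble::tibble(
      sample_id = if ("sample_id" %in% names(truth)) truth$sample_id else "S1",
      patient_id = if ("patient_id" %in% names(truth)) truth$patient_id else "P1",
      group = truth$group,
      preparation = truth$preparation,
      setpoint_c = t_set,
      r_bulk_ohm = noisy(r_bulk),
      r_surf1_ohm = noisy(r_surf),
      r_surf2_ohm = noisy(r_surf),
      heater_v = noisy(v),
      heater_i = noisy(i),
      rtd1_ohm = temperature_to_resistance(rtd_t[1], calib),
      rtd2_ohm = temperature_to_resistance(rtd_t[2], calib),
      rtd3_ohm = temperature_to_resistance(rtd_t[3], calib),
      t_source_c = t_set
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate a full synthetic study cohort
#'
#' Builds the complete study: for each preparation arm and patient, a paired
#' tumor and adjacent-normal block, each cut into technical repeats, with
#' ground truth drawn by [sample_tissue_truth()] and raw records simulated by
#' [forward_measurements()] at every setpoint. With the default configuration
#' this yields 48 samples (24 tumor + 24 normal across 8 patients) and 240
#' measurement records.
#'
#' All randomness flows from `config$seed`; the same seed reproduces the
#' cohort bitwise.
#'
#' @param config A [study_config()].
#' @return A list with elements `truth` (one row per sample) and
#'   `measurements` (one row per sample x setpoint).
#' @examples
#' study <- generate_study(study_config(patients_per_preparation = 1,
#'                                      repeats_per_block = 1,
#'                                      preparations = "formalin_fixed"))
#' nrow(study$truth)
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  pars <- config$group_parameters
  prep_code <- c(deparaffinized = "DP", formalin_fixed = "FF")

  truth_rows <- list()
  meas_rows <- list()
  for (prep in config$preparations) {
    for (p in seq_len(config$patients_per_preparation)) {
      patient_id <- sprintf("%s%d", prep_code[[prep]], p)
      for (grp in c("tumor", "normal")) {
        row <- pars[pars$preparation == prep & pars$group == grp, ]
        if (nrow(row) != 1) {
          stop("invalid config: group_parameters must have one row per ",
               "preparation x group", call. = FALSE)
        }
        truth <- sample_tissue_truth(
          row, n = config$repeats_per_block,
          sem_n = config$sem_n,
          endpoint_correlation = config$endpoint_correlation,
          repeat_cv = config$repeat_cv,
          geometry_tolerance_mm = config$geometry_tolerance_mm
        )
        truth$patient_id <- patient_id
        truth$sample_id <- sprintf("%s-%s-R%d", patient_id,
                                   toupper(substr(grp, 1, 1)),
                                   seq_len(config$repeats_per_block))
        for (j in seq_len(nrow(truth))) {
          meas_rows[[length(meas_rows) + 1]] <-
            forward_measurements(truth[j, ], config)
        }
        truth_rows[[length(truth_rows) + 1]] <- truth
      }
    }
  }
  truth <- dplyr::relocate(dplyr::bind_rows(truth_rows),
                           "sample_id", "patient_id", "group", "preparation")
  list(truth = truth, measurements = dplyr::bind_rows(meas_rows))
}
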