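#' @importFrom rlang .data
NULL

.measurement_columns <- c(
  "sample_id", "patient_id", "group", "preparation", "setpoint_c",
  "r_bulk_ohm", "r_surf1_ohm", "r_surf2_ohm", "heater_v", "heater_i",
  "rtd1_ohm", "rtd2_ohm", "rtd3_ohm", "t_source_c"
)
.measurement_numeric <- .measurement_columns[5:14]

.pkg_version <- function() {
  as.character(utils::packageVersion("electrotherm"))
}

# stable hash of a plain-list configuration (for provenance headers)
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

.provenance_lines <- function(seed = NULL, config = NULL) {
  c(sprintf("# electrotherm %s", .pkg_version()),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash=%s", .config_hash(config)))
}

# CSV with '#' provenance comment lines; deterministic bytes for fixed input
.write_csv_provenance <- function(df, path, seed = NULL, config = NULL) {
  body <- readr::format_csv(df)
  writeLines(c(.provenance_lines(seed, config), sub("\n$", "", body)), path)
  invisible(path)
}

#' Write measurement records to CSV
#'
#' Writes the raw measurement table in the package's measurement CSV schema
#' (RFC-4180, '.' decimal separator), preceded by `#` comment lines recording
#' the package version, seed and configuration hash.
#'
#' @param measurements Measurement tibble (see [forward_measurements()]).
#' @param path Output file path.
#' @param seed,config Optional provenance: the generator seed and the
#'   [study_config()] that produced the records.
#' @return The path, invisibly.
#' @export
write_measurements <- function(measurements, path, seed = NULL, config = NULL) {
  if (!identical(names(measurements), .measurement_columns)) {
    stop("schema error: measurement columns must be exactly: ",
         paste(.measurement_columns, collapse = ", "), call. = FALSE)
  }
  .write_csv_provenance(measurements, path, seed = seed, config = config)
}

#' Read measurement records from CSV
#'
#' Reads a measurement CSV written by [write_measurements()] (provenance
#' comment lines are skipped). The header must match the schema exactly.
#' Rows with a wrong field count or non-numeric values in numeric columns
#' are rejected with a warning naming the offending file line numbers; valid
#' rows are still returned.
#'
#' @param path Input file path.
#' @return A typed measurement tibble (possibly empty).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    stop("schema error: file has no header line", call. = FALSE)
  }
  header <- strsplit(data_lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, .measurement_columns)) {
    stop("schema error: header does not match the measurement schema",
         call. = FALSE)
  }
  if (length(data_lines) == 1) {
    empty <- stats::setNames(
      c(replicate(4, character(0), simplify = FALSE),
        replicate(10, numeric(0), simplify = FALSE)),
      .measurement_columns)
    return(tibble::as_tibble(empty))
  }
  fields <- strsplit(data_lines[-1], ",", fixed = TRUE)
  rows_line_no <- line_no[-1]
  n_fields <- lengths(fields)
  ok <- n_fields == length(.measurement_columns)
  parsed <- NULL
  if (any(ok)) {
    mat <- do.call(rbind, fields[ok])
    colnames(mat) <- .measurement_columns
    parsed <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
    numeric_ok <- rep(TRUE, nrow(parsed))
    for (col in .measurement_numeric) {
      val <- suppressWarnings(as.numeric(parsed[[col]]))
      numeric_ok <- numeric_ok & !is.na(val)
      parsed[[col]] <- val
    }
    if (any(!numeric_ok)) {
      warning("parse error: rejected line(s) ",
              paste(rows_line_no[ok][!numeric_ok], collapse = ", "),
              " (non-numeric value in a numeric column)", call. = FALSE)
      parsed <- parsed[numeric_ok, ]
    }
  }
  if (any(!ok)) {
    warning("parse error: rejected line(s) ",
            paste(rows_line_no[!ok], collapse = ", "),
            " (wrong field count)", call. = FALSE)
  }
  if (is.null(parsed)) {
    stop("parse error: no valid data rows", call. = FALSE)
  }
  parsed
}

#' Read a run configuration from a YAML file
#'
#' Parses a structured configuration with the top-level blocks `study`
#' (fields of [study_config()], with `chip` and `calib` as nested blocks of
#' [chip_geometry()] / [rtd_calibration()] arguments) and `stats`
#' (`alpha`, `fold_threshold`). Unknown keys at any level are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `study` (a [study_config()]) and `stats`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("schema error: unknown key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(cfg, c("study", "stats"), "config")
  study_args <- cfg$study %||% list()
  check_keys(study_args,
             setdiff(names(formals(study_config)), "group_parameters"),
             "study block")
  if (!is.null(study_args$chip)) {
    check_keys(study_args$chip, names(formals(chip_geometry)), "chip block")
    study_args$chip <- do.call(chip_geometry, study_args$chip)
  }
  if (!is.null(study_args$calib)) {
    check_keys(study_args$calib, names(formals(rtd_calibration)), "calib block")
    study_args$calib <- do.call(rtd_calibration, study_args$calib)
  }
  stats_args <- cfg$stats %||% list()
  check_keys(stats_args, c("alpha", "fold_threshold"), "stats block")
  list(
    study = do.call(study_config, study_args),
    stats = utils::modifyList(list(alpha = 0.05, fold_threshold = 3.8),
                              stats_args)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
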