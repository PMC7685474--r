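#' Read a fractogram CSV
#'
#' Expects the dialect `time_min, uv_au, dri_riu, ls_032, ls_043, ...` with
#' detector angles (degrees, zero-padded) encoded in the light-scattering
#' column names. Any of the detector columns may be absent; unknown columns
#' are preserved. Time must be strictly increasing.
#'
#' @param path Path to the CSV file.
#'
#' @return A fractogram tibble with attributes `angles` (degrees) and
#'   `missing_detectors` (character vector naming absent standard columns).
#' @export
read_fractogram <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        name_repair = "minimal", progress = FALSE)
  names(df) <- trimws(sub("^\ufeff", "", names(df)))
  if (!"time_min" %in% names(df)) {
    abort("Fractogram file lacks the required `time_min` column.",
          class = "af4saxs_format_error")
  }
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Time column is not strictly increasing (first offence at row %d).",
                  bad[1] + 1),
          class = "af4saxs_format_error")
  }
  ls <- .ls_columns(df)
  missing <- setdiff(c("uv_au", "dri_riu"), names(df))
  if (length(ls$cols) == 0) missing <- c(missing, "ls_*")
  if (length(missing) > 0) {
    inform(paste0("Fractogram is missing detector column(s): ",
                  paste(missing, collapse = ", ")))
  }
  attr(df, "angles") <- ls$angles
  attr(df, "missing_detectors") <- missing
  class(df) <- c("fractogram", class(df))
  df
}

#' Write a fractogram CSV
#'
#' @param fractogram A fractogram tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fractogram <- function(fractogram, path) {
  readr::write_csv(fractogram, path)
  invisible(path)
}

#' Read a 1-D SAXS curve
#'
#' Whitespace-delimited three-column text (`q`, `I`, `sigma`), `#`-prefixed
#' comment/header lines and blank lines ignored -- the de facto `.dat`
#' dialect. Units are auto-detected: a grid whose maximum is below 1 is taken
#' to be in 1/Angstrom and converted to 1/nm (logged via a message). A sigma
#' column of zeros is replaced by 1% of the intensity with a warning; negative
#' intensities are kept (they are masked in log-space fits downstream).
#'
#' @param path Path to the file.
#' @return A [scattering_curve()] tibble; attribute `unit_converted` records
#'   whether the Angstrom -> nm conversion was applied.
#' @export
read_saxs_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\ufeff", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    abort("SAXS file contains no data lines.", class = "af4saxs_format_error")
  }
  con <- textConnection(lines[keep])
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = FALSE, colClasses = "numeric"),
    error = function(e) abort(paste0("Cannot parse SAXS curve: ",
                                     conditionMessage(e)),
                              class = "af4saxs_format_error")
  )
  if (ncol(df) < 3) {
    abort("SAXS curve needs at least three columns (q, I, sigma).",
          class = "af4saxs_format_error")
  }
  q <- df[[1]]; i <- df[[2]]; s <- df[[3]]
  converted <- FALSE
  if (max(q) < 1) {
    q <- q * 10
    converted <- TRUE
    inform("q grid maximum < 1: interpreting units as 1/Angstrom and converting to 1/nm.")
  }
  if (all(s == 0)) {
    warn("Sigma column is all zeros; substituting 1% of |I|.",
         class = "af4saxs_sigma_warning")
    s <- pmax(abs(i) * 0.01, 1e-12)
  }
  out <- scattering_curve(q, i, s)
  attr(out, "unit_converted") <- converted
  out
}

#' Write a 1-D SAXS curve
#'
#' @param curve A data frame with `q`, `intensity`, `sigma`.
#' @param path Output path.
#' @param header Comment line written at the top.
#' @return The path, invisibly.
#' @export
write_saxs_curve <- function(curve, path, header = "q(1/nm) I sigma") {
  lines <- c(paste0("# ", header),
             sprintf("%.10g %.10g %.10g", curve$q, curve$intensity, curve$sigma))
  writeLines(lines, path)
  invisible(path)
}

#' Read an instrument configuration file
#'
#' Structured YAML with per-stage sections (`channel`, `flows`, `solvent`,
#' plus free-form analysis sections). Returns ready-made model objects.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#'
#' @return A list with `geometry`, `flows`, `solvent` objects and the raw
#'   config under `raw`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  ch <- cfg$channel %||% list()
  fl <- cfg$flows %||% list()
  so <- cfg$solvent %||% list()
  geometry <- channel_geometry(
    length_cm = ch$length_cm %||% 26.5,
    inlet_width_cm = ch$inlet_width_cm %||% 2.2,
    outlet_width_cm = ch$outlet_width_cm %||% 0.6,
    spacer_um = ch$spacer_um %||% 350,
    thickness_scale = ch$thickness_scale %||% 1,
    focus_cm = ch$focus_cm %||% 2
  )
  flows <- flow_conditions(
    detector_ml_min = fl$detector_ml_min %||% 1.0,
    crossflow_ml_min = fl$crossflow_ml_min %||% 4.5,
    duration_min = fl$duration_min %||% 30
  )
  solvent <- solvent_conditions(
    temperature_K = so$temperature_K %||% 298.15,
    viscosity_Pa_s = so$viscosity_Pa_s %||% 8.9e-4,
    refractive_index = so$refractive_index %||% 1.331,
    laser_nm = so$laser_nm %||% 658
  )
  list(geometry = geometry, flows = flows, solvent = solvent, raw = cfg)
}
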