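#' @name actinload-io
#' @title CSV input/output with schema validation
#'
#' @description All interchange uses headered CSV (UTF-8, '.' decimal).
#' Readers validate the schema and report any missing column by name;
#' writers can prepend `#`-comment provenance lines (package version and
#' seed), which the readers skip.
#'
#' Schemas:
#' * AFM trace: `time_s,height_um,stress_pa`
#' * intensity trace: `time_s,channel,density` (optional `network`)
#' * molecule tracks: `track_id,frame,time_s,x_um,y_um,intensity`
#' * quench curves: `time_s,donor_intensity,condition`
#' * rate table: `stress_pa,channel,per_network_rate,per_filament_rate`
NULL

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf(
      "Malformed %s: missing column%s %s.",
      what, if (length(missing) > 1L) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

validate_afm_trace <- function(trace) {
  check_schema(trace, c("time_s", "height_um", "stress_pa"), "AFM trace")
  if (nrow(trace) == 0L) abort("AFM trace is empty.")
  if (any(diff(trace$time_s) <= 0)) {
    abort("AFM trace `time_s` must be strictly increasing.")
  }
  if (any(!is.finite(trace$height_um))) abort("`height_um` must be finite.")
  if (any(trace$stress_pa < 0)) abort("`stress_pa` must be non-negative.")
  invisible(trace)
}

validate_intensity_trace <- function(intensity) {
  check_schema(intensity, c("time_s", "channel", "density"), "intensity trace")
  if (any(intensity$density < 0)) {
    abort("`density` must be non-negative (background subtracted).")
  }
  invisible(intensity)
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read a force-clamp trace CSV
#' @param path CSV file with columns `time_s,height_um,stress_pa`.
#' @return Validated tibble.
#' @rdname actinload-io
#' @export
read_afm_trace <- function(path) {
  validate_afm_trace(read_csv_quiet(path))
}

#' Read a TIRF intensity-trace CSV
#' @rdname actinload-io
#' @export
read_intensity_traces <- function(path) {
  validate_intensity_trace(read_csv_quiet(path))
}

#' Read a single-molecule track table CSV
#' @rdname actinload-io
#' @export
read_track_table <- function(path) {
  df <- read_csv_quiet(path)
  check_schema(
    df, c("track_id", "frame", "time_s", "x_um", "y_um", "intensity"),
    "track table"
  )
  if (any(df$intensity < 0)) abort("Track `intensity` must be non-negative.")
  dplyr::mutate(df,
    track_id = as.integer(.data$track_id),
    frame = as.integer(.data$frame)
  )
}

#' Read donor-quench curves CSV
#' @rdname actinload-io
#' @export
read_quench_curves <- function(path) {
  df <- read_csv_quiet(path)
  check_schema(df, c("time_s", "donor_intensity", "condition"), "quench curve")
  df
}

#' Write a table as CSV with a provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (optional).
#' @return `path`, invisibly.
#' @rdname actinload-io
#' @export
write_table_csv <- function(x, path, seed = NULL) {
  hdr <- c(
    sprintf("# actinload %s", as.character(utils::packageVersion("actinload"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed)
  )
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a structured run log
#'
#' Every analysis run can emit a plain-text provenance block: stage name,
#' package version, seed, parameters, and any tables passed in
#' (`key = value` lines and embedded CSV blocks).
#'
#' @param path Output path.
#' @param stage Stage name (e.g. `"analyze-flux"`).
#' @param params Named list of scalar parameters.
#' @param tables Named list of data frames to embed.
#' @param seed Seed, if any.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, stage, params = list(), tables = list(),
                          seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("stage: %s", stage), con)
  writeLines(sprintf(
    "package: actinload %s",
    as.character(utils::packageVersion("actinload"))
  ), con)
  writeLines(sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  if (!is.null(seed)) writeLines(sprintf("seed: %s", seed), con)
  if (length(params)) {
    writeLines("params:", con)
    for (nm in names(params)) {
      writeLines(sprintf("  %s: %s", nm, format(params[[nm]])), con)
    }
  }
  for (nm in names(tables)) {
    writeLines(sprintf("table: %s", nm), con)
    writeLines(readr::format_csv(tables[[nm]]), con)
  }
  invisible(path)
}

#' Validate a run configuration list
#'
#' Rejects unknown keys so typos in config files surface immediately.
#'
#' @param config Named list.
#' @param allowed Character vector of permitted keys.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config, allowed) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown config key%s: %s.",
      if (length(unknown) > 1L) "s" else "",
      paste0("`", unknown, "`", collapse = ", ")
    ))
  }
  invisible(config)
}

#' Run the flux-analysis pipeline on trace files
#'
#' Thin end-to-end wrapper: reads an AFM trace and an intensity-trace CSV,
#' detects steady segments, averages channel densities per segment,
#' computes per-network and (given a barbed-end series) per-filament
#' rates, and writes the rate table plus a run log.
#'
#' @param afm_path,intensity_path Input CSVs.
#' @param out_path Output rate-table CSV.
#' @param barbed_ends Optional tibble `stress`, `e_rel`.
#' @param reference_stress Reference load, Pa.
#' @param min_duration,stress_tol,r2_min Segment-detection thresholds, see
#'   [find_steady_segments()].
#' @param log_path Optional run-log path.
#' @return The rate table, invisibly.
#' @export
analyze_flux_files <- function(afm_path, intensity_path, out_path,
                               barbed_ends = NULL, reference_stress = 25,
                               min_duration = 60, stress_tol = NULL,
                               r2_min = 0.99, log_path = NULL) {
  trace <- read_afm_trace(afm_path)
  intensity <- read_intensity_traces(intensity_path)
  if ("network" %in% names(intensity)) {
    intensity <- dplyr::filter(intensity, .data$network == "loaded")
  }
  segments <- find_steady_segments(trace,
    min_duration = min_duration,
    stress_tol = stress_tol, r2_min = r2_min
  )
  dens <- segment_densities(intensity, segments)
  rates <- per_network_rate(dens, reference_stress = reference_stress)
  if (!is.null(barbed_ends)) {
    rates <- per_filament_rate(rates, barbed_ends)
  } else {
    rates$per_filament_rate <- NA_real_
  }
  out <- dplyr::rename(rates, stress_pa = "stress")
  write_table_csv(out, out_path)
  if (!is.null(log_path)) {
    write_run_log(log_path, "analyze-flux",
      params = list(
        reference_stress = reference_stress, min_duration = min_duration,
        r2_min = r2_min
      ),
      tables = list(segments = segments)
    )
  }
  invisible(out)
}
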