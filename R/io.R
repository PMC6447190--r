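trial_cols <- c("participant", "condition", "level", "block",
                "change_interval", "correct")

#' Write trial records to CSV
#'
#' Comma-separated, UTF-8, header row: the single tabular interchange
#' format used by the package (matching typical psychophysics deposits).
#'
#' @param trials Trial tibble containing at least the canonical columns
#'   `participant`, `condition`, `level`, `block`, `change_interval`,
#'   `correct`.
#' @param path Output file path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  readr::write_csv(trials, path)
  invisible(trials)
}

#' Read trial records from CSV
#'
#' Validates the header and the row contents: `level`, `block`,
#' `change_interval` and `correct` must be integers, `change_interval`
#' in {1, 2} and `correct` binary. Malformed rows are reported with their
#' line numbers; an empty file yields an empty tibble with a warning.
#'
#' @param path CSV file path.
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  ))
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    warn("Empty trial file; returning an empty table.")
    return(tibble(participant = character(), condition = character(),
                  level = integer(), block = integer(),
                  change_interval = integer(), correct = integer()))
  }
  missing <- setdiff(trial_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Trial file is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      lines <- which(!ok) + 1L  # + header line
      abort(paste0("Malformed ", what, " on line(s) ",
                   paste(head(lines, 10), collapse = ", "),
                   if (sum(!ok) > 10) " ..." else "", "."))
    }
  }
  int_ok <- function(x) is.numeric(x) & !is.na(x) & x == round(x)
  bad_row(int_ok(raw$level) & raw$level >= 1, "level")
  bad_row(int_ok(raw$block) & raw$block >= 1, "block")
  bad_row(int_ok(raw$change_interval) & raw$change_interval %in% c(1, 2),
          "change_interval")
  bad_row(int_ok(raw$correct) & raw$correct %in% c(0, 1), "correct (must be 0/1)")
  dplyr::mutate(
    raw,
    level = as.integer(.data$level),
    block = as.integer(.data$block),
    change_interval = as.integer(.data$change_interval),
    correct = as.integer(.data$correct)
  )
}

#' Default run configuration
#'
#' The full set of tunable constants: viewing geometry, design parameters,
#' the published speed constants kept for replication, fit options and
#' statistics options. Round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @return A nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(
    list(
      geometry = list(
        viewing_distance_cm = 97,
        ipd_cm = 6.5,
        refresh_hz = 85,
        half_separation_cm = 3
      ),
      design = list(
        duration_s = 1,
        change_time_s = 0.5,
        static_lead_s = 0.25,
        blocks = 3,
        trials_per_level = 10,
        fast_standard_cms = 40, fast_step_cms = 5,
        slow_standard_cms = 20, slow_step_cms = 2.5
      ),
      published_retina_speeds = list(
        fast_standard = 47.6, fast_max = c(7.6, 87.4),
        fast_control_max = c(7.7, 87.5),
        slow_standard = 22.3, slow_max = c(4.6, 40.0),
        slow_control_max = c(4.6, 40.1)
      ),
      training_speeds = list(
        standard = 283.4, hard = c(212.6, 354.1), easy = c(70.9, 495.3)
      ),
      fit = list(guess = 0.5, lapse = 0),
      stats = list(ci_level = 0.95, cauchy_scale = 0.5)
    ),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` list (see [default_config()]).
#' @param path Output file path.
#' @return `config`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' Read and validate a run configuration from YAML
#'
#' Unknown top-level or nested keys are rejected (they usually indicate a
#' typo), and missing keys are filled from [default_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  user <- yaml::read_yaml(path)
  defaults <- unclass(default_config())
  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top) > 0) {
    abort(paste0("Unknown config key(s): ",
                 paste(unknown_top, collapse = ", "), "."))
  }
  for (section in names(user)) {
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown) > 0) {
      abort(paste0("Unknown config key(s) in '", section, "': ",
                   paste(unknown, collapse = ", "), "."))
    }
    defaults[[section]][names(user[[section]])] <- user[[section]]
  }
  structure(defaults, class = "run_config")
}

#' Viewing geometry from a run configuration
#'
#' @param config A `run_config` list.
#' @return A [viewing_geometry()].
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  viewing_geometry(g$viewing_distance_cm, g$ipd_cm, g$refresh_hz,
                   g$half_separation_cm)
}
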