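#' Electrotaxis channel geometry
#'
#' Describes the rectangular cross-section of the plating channel through
#' which all current flows. The cross-sectional area (orthogonal to current
#' flow) is `height * width`; `length` is informational only.
#'
#' @param height_m Channel height in metres (must be > 0).
#' @param width_m Channel width in metres (must be > 0).
#' @param length_m Channel length in metres (informational; default 19 mm).
#'
#' @return An object of class `channel_geometry`: a list with `height_m`,
#'   `width_m`, `length_m` and the derived `cross_section_area_m2`.
#' @examples
#' channel_geometry() # the default 202 um x 5 mm channel
#' @export
channel_geometry <- function(height_m = 202e-6, width_m = 5e-3, length_m = 19e-3) {
  if (!is.numeric(height_m) || length(height_m) != 1 || !is.finite(height_m) ||
      height_m <= 0 || width_m <= 0 || length_m <= 0) {
    abort("channel dimensions must be strictly positive finite numbers",
          class = "spherotax_invalid_config")
  }
  structure(
    list(
      height_m = height_m, width_m = width_m, length_m = length_m,
      cross_section_area_m2 = height_m * width_m
    ),
    class = "channel_geometry"
  )
}

#' Field configuration: target field strength, medium conductivity, geometry
#'
#' @param target_field_V_m Desired field strength E in V/m (>= 0).
#' @param conductivity_S_m Medium conductivity sigma in S/m (> 0); the default
#'   1.5 S/m is a typical culture-medium value.
#' @param geometry A [channel_geometry()].
#'
#' @return An object of class `field_config`.
#' @export
field_config <- function(target_field_V_m, conductivity_S_m = 1.5,
                         geometry = channel_geometry()) {
  if (!inherits(geometry, "channel_geometry")) {
    abort("`geometry` must be a channel_geometry object",
          class = "spherotax_invalid_config")
  }
  if (!is.numeric(conductivity_S_m) || conductivity_S_m <= 0 ||
      !is.finite(conductivity_S_m)) {
    abort("conductivity must be a positive finite number",
          class = "spherotax_invalid_config")
  }
  if (!is.numeric(target_field_V_m) || target_field_V_m < 0 ||
      !is.finite(target_field_V_m)) {
    abort("target field strength must be a non-negative finite number",
          class = "spherotax_invalid_config")
  }
  structure(
    list(
      target_field_V_m = target_field_V_m,
      conductivity_S_m = conductivity_S_m,
      geometry = geometry
    ),
    class = "field_config"
  )
}

#' Set current for a desired field strength
#'
#' The current to dial in on the supply so that the channel carries field
#' strength E is, by Ohm's law for a uniform conductor,
#' \deqn{I_{set} = E \sigma A}
#' with E the field strength (V/m), sigma the medium conductivity (S/m) and
#' A the channel cross-sectional area (m^2).
#'
#' @param config A [field_config()].
#' @return Set current in amperes.
#' @examples
#' compute_set_current(field_config(100)) # 1.515e-4 A in the default channel
#' @export
compute_set_current <- function(config) {
  stopifnot(inherits(config, "field_config"))
  config$target_field_V_m * config$conductivity_S_m *
    config$geometry$cross_section_area_m2
}

#' Field strength implied by a measured current
#'
#' Inverse of [compute_set_current()]: E = I / (sigma A).
#'
#' @param current_A Measured current in amperes.
#' @param config A [field_config()] (its `target_field_V_m` is ignored).
#' @return Implied field strength in V/m.
#' @export
implied_field <- function(current_A, config) {
  stopifnot(inherits(config, "field_config"))
  denom <- config$conductivity_S_m * config$geometry$cross_section_area_m2
  if (denom <= 0) {
    abort("conductivity x area must be positive", class = "spherotax_domain_error")
  }
  current_A / denom
}

#' Read a current log CSV
#'
#' Expects a header `time_h,current_A` (amperes) or `time_h,current_uA`
#' (microamperes, converted on read).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `time_h` and `current_A`.
#' @export
read_current_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE)
  if ("current_uA" %in% names(log) && !"current_A" %in% names(log)) {
    log$current_A <- log$current_uA * 1e-6
    log$current_uA <- NULL
  }
  if (!all(c("time_h", "current_A") %in% names(log))) {
    abort("current log must have columns time_h and current_A (or current_uA)",
          class = "spherotax_invalid_input")
  }
  as_tibble(log[, c("time_h", "current_A")])
}

#' Field-drift quality control on a current log
#'
#' Converts each logged current to the field strength it implies and checks
#' the drift rate between consecutive records. Each consecutive pair is
#' scaled to a per-`window_h` rate, `|dE| * window_h / dt`; the experiment
#' fails QC when any pair exceeds `max_drift_per_window` (default 20 V/m per
#' 4 h). Failing experiments should be excluded from further analysis.
#'
#' @param log A data frame with columns `time_h` (strictly increasing) and
#'   `current_A` (non-negative), e.g. from [read_current_log()] or
#'   [simulate_current_log()].
#' @param config A [field_config()] giving conductivity and geometry.
#' @param max_drift_per_window Maximum tolerated drift, V/m per window
#'   (default 20).
#' @param window_h Window the drift rate is scaled to, in hours (default 4).
#' @param experiment_id Optional label carried into the report.
#'
#' @return An object of class `field_qc`; use [tidy()] for the per-interval
#'   table and [glance()] for the one-row verdict. Fields: `pass`,
#'   `worst_drift` (V/m per window), `worst_interval` (start/end hours),
#'   `intervals` (tibble).
#' @export
check_field_drift <- function(log, config, max_drift_per_window = 20,
                              window_h = 4, experiment_id = NA_character_) {
  stopifnot(inherits(config, "field_config"))
  if (!is.data.frame(log) || !all(c("time_h", "current_A") %in% names(log))) {
    abort("`log` must have columns time_h and current_A",
          class = "spherotax_invalid_input")
  }
  if (nrow(log) < 2) {
    abort("a current log needs at least 2 records to assess drift",
          class = "spherotax_insufficient_data")
  }
  if (any(diff(log$time_h) <= 0)) {
    abort("log times must be strictly increasing",
          class = "spherotax_invalid_input")
  }
  if (any(log$current_A < 0)) {
    abort("currents must be non-negative", class = "spherotax_invalid_input")
  }

  field <- implied_field(log$current_A, config)
  n <- nrow(log)
  intervals <- tibble(
    t_start_h = log$time_h[-n],
    t_end_h = log$time_h[-1],
    field_start_V_m = field[-n],
    field_end_V_m = field[-1]
  ) %>%
    mutate(
      dt_h = .data$t_end_h - .data$t_start_h,
      drift_per_window = abs(.data$field_end_V_m - .data$field_start_V_m) *
        window_h / .data$dt_h,
      exceeds = .data$drift_per_window > max_drift_per_window
    )

  worst <- which.max(intervals$drift_per_window)
  structure(
    list(
      pass = !any(intervals$exceeds),
      worst_drift = intervals$drift_per_window[worst],
      worst_interval = c(intervals$t_start_h[worst], intervals$t_end_h[worst]),
      max_drift_per_window = max_drift_per_window,
      window_h = window_h,
      experiment_id = experiment_id,
      intervals = intervals
    ),
    class = "field_qc"
  )
}

#' @export
print.field_qc <- function(x, ...) {
  cat(sprintf(
    "Field-drift QC%s: %s (worst drift %.3g V/m per %g h, limit %g; interval %g-%g h)\n",
    if (is.na(x$experiment_id)) "" else paste0(" [", x$experiment_id, "]"),
    if (x$pass) "PASS" else "FAIL",
    x$worst_drift, x$window_h, x$max_drift_per_window,
    x$worst_interval[1], x$worst_interval[2]
  ))
  invisible(x)
}

#' @rdname check_field_drift
#' @param x A `field_qc` object.
#' @param ... Unused.
#' @method tidy field_qc
#' @export
tidy.field_qc <- function(x, ...) x$intervals

#' @rdname check_field_drift
#' @method glance field_qc
#' @export
glance.field_qc <- function(x, ...) {
  tibble(
    experiment_id = x$experiment_id,
    pass = x$pass,
    worst_drift_per_window = x$worst_drift,
    window_h = x$window_h,
    max_drift_per_window = x$max_drift_per_window,
    n_intervals = nrow(x$intervals)
  )
}
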