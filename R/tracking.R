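#' Field axis unit vector
#'
#' The axis of the applied electric field as a unit vector pointing toward
#' the cathode. The package convention (matching images acquired with the
#' anode at the left) is that x increases toward the cathode, so the default
#' axis is (1, 0). The orthogonal axis is the field axis rotated +90
#' degrees: (-uy, ux).
#'
#' @param ux,uy Components of the cathode-pointing axis.
#' @return A `field_axis` object (named numeric of length 2), normalized.
#' @export
field_axis <- function(ux = 1, uy = 0) {
  nrm <- sqrt(ux^2 + uy^2)
  if (!is.finite(nrm) || nrm == 0) {
    abort("field axis must be a nonzero vector", class = "spherotax_invalid_config")
  }
  structure(c(ux = ux / nrm, uy = uy / nrm), class = "field_axis")
}

orthogonal_axis <- function(axis) {
  structure(c(ux = -axis[["uy"]], uy = axis[["ux"]]), class = "field_axis")
}

validate_tracks <- function(tracks) {
  req <- c("cell_id", "time_h", "x_um", "y_um")
  if (!is.data.frame(tracks) || !all(req %in% names(tracks))) {
    abort("tracks must have columns cell_id, time_h, x_um, y_um",
          class = "spherotax_invalid_input")
  }
  if (nrow(tracks) == 0) {
    abort("empty track table", class = "spherotax_empty_input")
  }
  counts <- table(tracks$cell_id)
  if (any(counts < 2)) {
    abort(paste0("every track needs >= 2 points; offending cell(s): ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "spherotax_insufficient_track")
  }
  bad <- tracks %>%
    group_by(.data$cell_id) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort(paste0("track times must be strictly increasing; offending cell(s): ",
                 paste(bad$cell_id[!bad$ok], collapse = ", ")),
          class = "spherotax_degenerate_segment")
  }
  invisible(tracks)
}

#' Per-segment scalar projections onto the field axis
#'
#' For each consecutive pair of positions in each track, computes the scalar
#' projection |A| cos(theta) of the segment vector A onto the
#' cathode-pointing unit axis: the signed displacement toward the cathode
#' over that segment. Zero-length segments (a cell that did not move) are
#' retained with projection 0.
#'
#' @param tracks Tibble of track points: `cell_id`, `time_h`, `x_um`, `y_um`.
#'   One or many cells.
#' @param axis A [field_axis()] (default: cathode toward +x).
#' @return A tibble with one row per segment: `cell_id`, `t_start_h`,
#'   `t_end_h`, `dt_h`, `proj_um` (cathode-positive), `ortho_um` (projection
#'   on the +90-degree rotated axis).
#' @export
segment_projections <- function(tracks, axis = field_axis()) {
  validate_tracks(tracks)
  ortho <- orthogonal_axis(axis)
  tracks %>%
    group_by(.data$cell_id) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    mutate(
      dx = .data$x_um - lag(.data$x_um),
      dy = .data$y_um - lag(.data$y_um),
      t_start_h = lag(.data$time_h)
    ) %>%
    filter(!is.na(.data$dx)) %>%
    dplyr::reframe(
      t_start_h = .data$t_start_h,
      t_end_h = .data$time_h,
      dt_h = .data$time_h - .data$t_start_h,
      proj_um = .data$dx * axis[["ux"]] + .data$dy * axis[["uy"]],
      ortho_um = .data$dx * ortho[["ux"]] + .data$dy * ortho[["uy"]]
    )
}

#' Mean time-normalized projected migration rate per cell
#'
#' Each segment's projected displacement is normalized by the segment
#' duration and the per-segment rates are averaged within each cell,
#' yielding a cathode-directed speed in um/h.
#'
#' @inheritParams segment_projections
#' @return A tibble: `cell_id`, `mean_projected_rate_um_h`, `n_segments`.
#' @export
mean_projected_rate <- function(tracks, axis = field_axis()) {
  segs <- segment_projections(tracks, axis)
  if (any(segs$dt_h <= 0)) {
    abort("zero-duration segment", class = "spherotax_degenerate_segment")
  }
  segs %>%
    group_by(.data$cell_id) %>%
    summarise(
      mean_projected_rate_um_h = mean(.data$proj_um / .data$dt_h),
      n_segments = n(),
      .groups = "drop"
    )
}

#' Net displacement along and orthogonal to the field
#'
#' Projects (last point - first point) of each track onto the
#' cathode-pointing axis and onto its +90-degree rotation. By telescoping
#' this equals the sum of the per-segment projections.
#'
#' @inheritParams segment_projections
#' @return A tibble: `cell_id`, `net_cathodal_um`, `net_orthogonal_um`,
#'   `duration_h`.
#' @export
net_displacement <- function(tracks, axis = field_axis()) {
  validate_tracks(tracks)
  ortho <- orthogonal_axis(axis)
  tracks %>%
    group_by(.data$cell_id) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(
      net_cathodal_um = (last(.data$x_um) - first(.data$x_um)) * axis[["ux"]] +
        (last(.data$y_um) - first(.data$y_um)) * axis[["uy"]],
      net_orthogonal_um = (last(.data$x_um) - first(.data$x_um)) * ortho[["ux"]] +
        (last(.data$y_um) - first(.data$y_um)) * ortho[["uy"]],
      duration_h = last(.data$time_h) - first(.data$time_h),
      .groups = "drop"
    )
}

#' Per-cell track metrics and cohort summary
#'
#' Combines [mean_projected_rate()] and [net_displacement()] into one
#' per-cell table; the cohort-level mean, SD, SEM and n of each metric are
#' available through [glance()].
#'
#' @inheritParams segment_projections
#' @return A tibble of class `track_cohort`, one row per cell:
#'   `cell_id`, `mean_projected_rate_um_h`, `net_cathodal_um`,
#'   `net_orthogonal_um`, `duration_h`, `n_segments`.
#' @export
cohort_metrics <- function(tracks, axis = field_axis()) {
  per_cell <- mean_projected_rate(tracks, axis) %>%
    left_join(net_displacement(tracks, axis), by = "cell_id") %>%
    select("cell_id", "mean_projected_rate_um_h", "net_cathodal_um",
           "net_orthogonal_um", "duration_h", "n_segments")
  class(per_cell) <- c("track_cohort", class(per_cell))
  per_cell
}

#' @rdname cohort_metrics
#' @param x A `track_cohort` tibble.
#' @param ... Unused.
#' @return For `glance()`: one row per metric with `mean`, `sd`, `sem`, `n`.
#' @method glance track_cohort
#' @export
glance.track_cohort <- function(x, ...) {
  metrics <- c("mean_projected_rate_um_h", "net_cathodal_um", "net_orthogonal_um")
  purrr::map_dfr(metrics, function(m) {
    v <- x[[m]]
    tibble(metric = m, mean = mean(v), sd = sd(v),
           sem = sd(v) / sqrt(length(v)), n = length(v))
  })
}

#' Read a track table CSV
#'
#' @param path CSV with header `cell_id,time_h,x_um,y_um`.
#' @return A track tibble.
#' @export
read_tracks <- function(path) {
  tracks <- readr::read_csv(path, show_col_types = FALSE)
  validate_tracks(tracks)
  as_tibble(tracks)
}

#' Read an ImageJ Manual Tracking export
#'
#' ImageJ's Manual Tracking plugin exports track number, slice and pixel
#' coordinates; this converts them to the package's track format using the
#' pixel size and frame interval.
#'
#' @param path CSV/TSV export containing columns named (case-insensitively)
#'   `Track n0` or `track`, `Slice n0` or `slice`, `X` and `Y`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param frame_interval_h Time between slices in hours.
#' @return A track tibble (`cell_id`, `time_h`, `x_um`, `y_um`).
#' @export
read_imagej_tracks <- function(path, pixel_size_um, frame_interval_h) {
  raw <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(raw))))
  pick <- function(keys) {
    hit <- which(nm %in% keys)
    if (length(hit) == 0) {
      abort(paste0("ImageJ export lacks a column matching: ",
                   paste(keys, collapse = "/")),
            class = "spherotax_invalid_input")
    }
    raw[[hit[1]]]
  }
  out <- tibble(
    cell_id = as.character(pick(c("trackn0", "track", "trackno"))),
    time_h = (as.numeric(pick(c("slicen0", "slice", "sliceno"))) - 1) *
      frame_interval_h,
    x_um = as.numeric(pick("x")) * pixel_size_um,
    y_um = as.numeric(pick("y")) * pixel_size_um
  )
  validate_tracks(out)
  out
}
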