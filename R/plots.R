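#' Plot cell tracks centred at their origins
#'
#' The classic wind-rose style track plot: every track is translated to
#' start at the origin, with the cathode toward +x, so a cathodally biased
#' cohort fans to the right.
#'
#' @param tracks Track tibble (`cell_id`, `time_h`, `x_um`, `y_um`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  validate_tracks(tracks)
  centred <- tracks %>%
    group_by(.data$cell_id) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    mutate(x_um = .data$x_um - first(.data$x_um),
           y_um = .data$y_um - first(.data$y_um)) %>%
    ungroup()
  ggplot(centred, aes(.data$x_um, .data$y_um, group = .data$cell_id)) +
    geom_path(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    coord_equal() +
    labs(x = "toward cathode (µm)", y = "orthogonal (µm)",
         title = "Cell tracks (origin-centred)") +
    theme_minimal()
}

#' @describeIn cohort_metrics Jittered per-cell net displacements along and
#'   orthogonal to the field.
#' @param object A `track_cohort` tibble.
#' @method autoplot track_cohort
#' @export
autoplot.track_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("net_cathodal_um", "net_orthogonal_um"),
    names_to = "axis", values_to = "displacement_um"
  )
  ggplot(long, aes(.data$axis, .data$displacement_um)) +
    geom_jitter(width = 0.12, alpha = 0.7) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = NULL, y = "net displacement (µm)",
         title = "Per-cell net displacement") +
    theme_minimal()
}

#' @describeIn analyze_series Frontier shifts and biases over time for each
#'   aggregate.
#' @param object A `spheroid_series` tibble.
#' @param ... Unused.
#' @method autoplot spheroid_series
#' @export
autoplot.spheroid_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("shift_cathodal_um", "shift_anodal_um", "shift_orthogonal_um",
      "shift_orthogonal_prime_um", "cathodal_bias_um", "orthogonal_bias_um"),
    names_to = "metric", values_to = "um"
  )
  ggplot(long, aes(.data$time_h, .data$um, colour = .data$aggregate_id)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "time (h)", y = "µm",
         title = "Frontier shifts and directional biases") +
    theme_minimal()
}

#' @describeIn frontier_comparison Adjusted post-hoc p-values per frontier
#'   with the star convention.
#' @param object A `frontier_comparison` object.
#' @method autoplot frontier_comparison
#' @export
autoplot.frontier_comparison <- function(object, ...) {
  if (is.null(object$contrasts)) {
    abort("no contrasts to plot; rerun with contrasts = TRUE",
          class = "spherotax_invalid_input")
  }
  ggplot(object$contrasts,
         aes(.data$frontier, .data$estimate, fill = .data$contrast)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "contrast estimate (µm)",
         title = "Pairwise condition contrasts by frontier",
         subtitle = "Holm-Šidák adjusted") +
    theme_minimal()
}
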