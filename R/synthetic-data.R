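#' Simulate biased-random-walk cell tracks
#'
#' Each cell takes steps of `drift_um_h * dt_h` along the cathode axis (+x)
#' plus isotropic Gaussian noise per axis, emulating single cells migrating
#' under a DC field. Defaults emulate a 2 h tracking experiment at the
#' cohort size and drift magnitude typical of a strongly electrotactic
#' line; set `drift_um_h = 0` for an unstimulated control cohort.
#'
#' @param n_cells Number of cells (default 20).
#' @param drift_um_h Drift speed toward the cathode in um/h (default 13;
#'   0 or negative allowed).
#' @param step_noise_sd Per-axis Gaussian step noise SD in um (default 2).
#' @param dt_h Time between positions in hours (default 0.25).
#' @param duration_h Total tracked duration in hours (default 2).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `tracks` (tibble `cell_id`, `time_h`, `x_um`, `y_um`) and
#'   `truth` (the generating parameters, including the expected net
#'   cathodal displacement `drift_um_h * duration_h`).
#' @export
simulate_tracks <- function(n_cells = 20, drift_um_h = 13, step_noise_sd = 2,
                            dt_h = 0.25, duration_h = 2, seed = 1) {
  if (dt_h <= 0 || duration_h < dt_h || n_cells < 1) {
    abort("need dt_h > 0, duration_h >= dt_h and n_cells >= 1",
          class = "spherotax_invalid_config")
  }
  n_steps <- round(duration_h / dt_h)
  tracks <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      dx <- drift_um_h * dt_h + rnorm(n_steps, 0, step_noise_sd)
      dy <- rnorm(n_steps, 0, step_noise_sd)
      tibble(
        cell_id = sprintf("cell_%03d", i),
        time_h = seq(0, by = dt_h, length.out = n_steps + 1),
        x_um = c(0, cumsum(dx)),
        y_um = c(0, cumsum(dy))
      )
    })
  })
  list(
    tracks = tracks,
    truth = list(
      drift_um_h = drift_um_h, step_noise_sd = step_noise_sd,
      dt_h = dt_h, duration_h = duration_h, n_cells = n_cells,
      expected_net_cathodal_um = drift_um_h * duration_h, seed = seed
    )
  )
}

# even-odd scanline fill of a closed polygon given in 0-based pixel
# coordinates (x = column, y = row); pixel centres at integer coordinates
rasterize_polygon <- function(xv, yv, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  x2 <- c(xv[-1], xv[1])
  y2 <- c(yv[-1], yv[1])
  for (r in seq_len(nr)) {
    yr <- r - 1
    cross <- (yv <= yr & y2 > yr) | (y2 <= yr & yv > yr)
    if (!any(cross)) next
    xs <- sort(xv[cross] + (yr - yv[cross]) * (x2[cross] - xv[cross]) /
                 (y2[cross] - yv[cross]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(0, ceiling(xs[i]))
      c2 <- min(nc - 1, floor(xs[i + 1]))
      if (c2 >= c1) mask[r, (c1:c2) + 1] <- TRUE
    }
  }
  mask
}

#' Simulate a spheroid invasion time-lapse with known frontier truth
#'
#' Renders an aggregate as an ellipse whose four frontier positions evolve
#' analytically: at time t the half-width along the field axis is
#' `r0 + g t`, the half-height is `r0 + (g - retraction) t`, and the centre
#' sits `bias t` toward the cathode, so the noise-free cathodal bias at t is
#' exactly `2 * bias * t` and the orthogonal bias is 0. Per-vertex radial
#' boundary noise (um scale), an optional global frame translation, corner
#' fiducial marks and pixel intensity noise emulate the nuisances of real
#' tiled microscopy. Positive `field_bias_um_h` gives a cathodally invading
#' phenotype; a negative value with a positive retraction rate gives an
#' anodal, shrinking phenotype.
#'
#' @param initial_radius_um Aggregate radius at t = 0 (default 100).
#' @param isotropic_growth_um_h Outward growth rate on all sides, um/h
#'   (default 2).
#' @param field_bias_um_h Centre drift toward the cathode, um/h (default
#'   1.4; the noise-free cathodal bias at time t is 2 x this x t).
#' @param orthogonal_retraction_um_h Retraction rate of the orthogonal
#'   half-axis, um/h, >= 0 (default 0).
#' @param boundary_noise_sd_um Radial SD of per-vertex boundary noise
#'   (default 2).
#' @param global_translation_px Per-frame drift of the whole field of view,
#'   `c(dx, dy)` pixels per frame (default c(0, 0)).
#' @param pixel_size_um Pixel size (default 2).
#' @param frame_times_h Acquisition times in hours (default c(0, 8, 24)).
#' @param fiducial_marks Draw bright corner marks that move with the frame
#'   (default TRUE).
#' @param intensity_noise_sd Pixel intensity noise SD on a 0-1 scale
#'   (default 0.02).
#' @param n_vertices Polygon vertices for the boundary (default 360).
#' @param seed Integer seed.
#' @return A list: `images` (list of [timepoint_image()]), `truth` with
#'   `frontiers` (analytic noise-free frontier positions per frame, in the
#'   frame-1 coordinate system) and `bias` (analytic `cathodal_bias_um`,
#'   `orthogonal_bias_um`, `proportional_area_change` per later frame),
#'   `fiducial_region` (a left-edge strip containing two marks, suitable for
#'   [register_timepoints()]; registering on it rather than the whole image
#'   keeps the aggregate's own electrotactic translation out of the
#'   alignment), and the generating parameters.
#' @export
simulate_spheroid_series <- function(initial_radius_um = 100,
                                     isotropic_growth_um_h = 2,
                                     field_bias_um_h = 1.4,
                                     orthogonal_retraction_um_h = 0,
                                     boundary_noise_sd_um = 2,
                                     global_translation_px = c(0, 0),
                                     pixel_size_um = 2,
                                     frame_times_h = c(0, 8, 24),
                                     fiducial_marks = TRUE,
                                     intensity_noise_sd = 0.02,
                                     n_vertices = 360,
                                     seed = 1) {
  if (initial_radius_um <= 0 || pixel_size_um <= 0 ||
      any(diff(frame_times_h) <= 0)) {
    abort("need positive radius and pixel size, increasing frame times",
          class = "spherotax_invalid_config")
  }
  r0 <- initial_radius_um
  g <- isotropic_growth_um_h
  b <- field_bias_um_h
  rho <- orthogonal_retraction_um_h
  half_w <- r0 + g * frame_times_h
  half_h <- r0 + (g - rho) * frame_times_h
  if (any(half_w <= 0) || any(half_h <= 0)) {
    abort("frontier box collapses under these rates",
          class = "spherotax_degenerate_parameters")
  }
  n_frames <- length(frame_times_h)
  off_px <- cbind(
    dx = global_translation_px[1] * (seq_len(n_frames) - 1),
    dy = global_translation_px[2] * (seq_len(n_frames) - 1)
  )
  pad_um <- 4 * boundary_noise_sd_um
  ext_x <- max(half_w + abs(b) * frame_times_h) + pad_um +
    max(abs(off_px[, "dx"])) * pixel_size_um
  ext_y <- max(half_h) + pad_um + max(abs(off_px[, "dy"])) * pixel_size_um
  margin_px <- 30L
  half_cols <- ceiling(ext_x / pixel_size_um) + margin_px
  half_rows <- ceiling(ext_y / pixel_size_um) + margin_px
  nc <- 2L * half_cols + 1L
  nr <- 2L * half_rows + 1L
  c0 <- half_cols # 0-based centre column
  r0_px <- half_rows

  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  inset <- 8L
  sz <- 4L
  # left-edge strip holding two corner marks; registering on it keeps the
  # aggregate's own electrotactic translation out of the alignment estimate
  fiducial_region <- if (fiducial_marks) {
    list(rows = c(1L, nr),
         cols = c(1L, inset + sz + 1L + max(abs(off_px[, "dx"])) + 8L))
  } else {
    NULL
  }
  images <- withr::with_seed(seed, {
    purrr::map(seq_len(n_frames), function(k) {
      t <- frame_times_h[k]
      eps <- rnorm(n_vertices, 0, boundary_noise_sd_um)
      cx_px <- c0 + b * t / pixel_size_um + off_px[k, "dx"]
      cy_px <- r0_px + off_px[k, "dy"]
      xv <- cx_px + (half_w[k] + eps) / pixel_size_um * cos(theta)
      yv <- cy_px + (half_h[k] + eps) / pixel_size_um * sin(theta)
      mask <- rasterize_polygon(xv, yv, nr, nc)
      img <- matrix(0.15, nr, nc)
      img[mask] <- 0.85
      if (fiducial_marks) {
        corners <- rbind(
          c(inset, inset), c(inset, nc - inset - sz),
          c(nr - inset - sz, inset), c(nr - inset - sz, nc - inset - sz)
        )
        for (i in seq_len(nrow(corners))) {
          rr <- corners[i, 1] + off_px[k, "dy"] + 0:sz
          cc <- corners[i, 2] + off_px[k, "dx"] + 0:sz
          rr <- rr[rr >= 1 & rr <= nr]
          cc <- cc[cc >= 1 & cc <= nc]
          img[rr, cc] <- 1
        }
      }
      img <- img + matrix(rnorm(nr * nc, 0, intensity_noise_sd), nr, nc)
      timepoint_image(pmin(pmax(img, 0), 1), pixel_size_um, t)
    })
  })

  truth_frontiers <- tibble(
    time_h = frame_times_h,
    cathodal_um = c0 * pixel_size_um + b * frame_times_h + half_w,
    anodal_um = c0 * pixel_size_um + b * frame_times_h - half_w,
    orthogonal_um = r0_px * pixel_size_um + half_h,
    orthogonal_prime_um = r0_px * pixel_size_um - half_h
  )
  truth_bias <- tibble(
    time_h = frame_times_h[-1],
    cathodal_bias_um = 2 * b * frame_times_h[-1],
    orthogonal_bias_um = 0,
    proportional_area_change =
      (half_w[-1] * half_h[-1] - half_w[1] * half_h[1]) /
      (half_w[1] * half_h[1])
  )
  list(
    images = images,
    truth = list(
      frontiers = truth_frontiers,
      bias = truth_bias,
      fiducial_region = fiducial_region,
      params = list(
        initial_radius_um = r0, isotropic_growth_um_h = g,
        field_bias_um_h = b, orthogonal_retraction_um_h = rho,
        boundary_noise_sd_um = boundary_noise_sd_um,
        global_translation_px = global_translation_px,
        pixel_size_um = pixel_size_um, frame_times_h = frame_times_h,
        seed = seed
      )
    )
  )
}

#' Simulate differential-expression tables with planted structure
#'
#' Generates transcript-level DE tables with a planted set of significant
#' genes whose q-values and fold changes lie strictly past the standard
#' cutoffs (FDR < 0.05, |fold change| >= 2), gene-symbol collisions
#' (multiple transcripts per gene), and optionally a second table whose
#' fold changes correlate with the first at a chosen level.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_transcripts Number of transcripts, >= `n_genes`; the excess is
#'   assigned to random genes as symbol collisions (default 1200).
#' @param frac_significant Fraction of genes planted as significant
#'   (default 0.1).
#' @param effect_sd Spread of significant log2 fold changes beyond the
#'   minimum magnitude (default 1.5).
#' @param paired Also generate a correlated second table (default FALSE).
#' @param cross_correlation Target Pearson correlation of significant-gene
#'   fold changes between the paired tables (default 0.94).
#' @param seed Integer seed.
#' @return A list: `tables` (list of one or two DE tibbles `a`, `b`) and
#'   `truth` (`significant_genes`, parameters).
#' @export
simulate_de_tables <- function(n_genes = 1000, n_transcripts = 1200,
                               frac_significant = 0.1, effect_sd = 1.5,
                               paired = FALSE, cross_correlation = 0.94,
                               seed = 1) {
  if (n_transcripts < n_genes || frac_significant < 0 || frac_significant > 1) {
    abort("need n_transcripts >= n_genes and frac_significant in [0, 1]",
          class = "spherotax_invalid_config")
  }
  withr::with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    n_sig <- round(frac_significant * n_genes)
    sig_genes <- sample(genes, n_sig)
    is_sig <- setNames(genes %in% sig_genes, genes)

    gene_stats <- function(fc_override = NULL) {
      fc <- numeric(n_genes)
      q <- numeric(n_genes)
      sig <- is_sig
      fc[sig] <- sample(c(-1, 1), sum(sig), TRUE) *
        (1.2 + abs(rnorm(sum(sig), 0, effect_sd)))
      fc[!sig] <- runif(sum(!sig), -0.9, 0.9)
      if (!is.null(fc_override)) fc[sig] <- fc_override
      q[sig] <- runif(sum(sig), 1e-6, 0.04)
      q[!sig] <- runif(sum(!sig), 0.06, 1)
      p <- q * runif(n_genes, 0.2, 1)
      tibble(gene_symbol = genes, log2_fold_change = fc,
             p_value = p, q_value = q)
    }

    to_transcripts <- function(gs) {
      extra <- sample(seq_len(n_genes), n_transcripts - n_genes, replace = TRUE)
      idx <- c(seq_len(n_genes), extra)
      tb <- gs[idx, ]
      # collision transcripts: same gene, strictly larger p so the primary
      # transcript always wins the collapse
      dup <- duplicated(idx)
      tb$p_value[dup] <- pmin(1, tb$p_value[dup] * runif(sum(dup), 1.5, 3))
      tb$transcript_id <- sprintf("TX%05d", seq_len(n_transcripts))
      select(tb, "transcript_id", "gene_symbol", "log2_fold_change",
             "p_value", "q_value")
    }

    gs_a <- gene_stats()
    tables <- list(a = to_transcripts(gs_a))
    if (paired) {
      fc_a_sig <- gs_a$log2_fold_change[is_sig]
      sd_a <- sd(fc_a_sig)
      fc_b_sig <- cross_correlation * fc_a_sig +
        sqrt(1 - cross_correlation^2) * rnorm(length(fc_a_sig), 0, sd_a)
      gs_b <- gene_stats(fc_override = fc_b_sig)
      tables$b <- to_transcripts(gs_b)
    }
    list(
      tables = tables,
      truth = list(
        significant_genes = sort(sig_genes),
        n_genes = n_genes, n_transcripts = n_transcripts,
        frac_significant = frac_significant,
        cross_correlation = if (paired) cross_correlation else NA_real_,
        seed = seed
      )
    )
  })
}

#' Simulate a current log with controlled field drift
#'
#' Produces a multimeter-style log whose implied field strength starts at
#' the configured target and drifts linearly at `drift_per_window` V/m per
#' `window_h` hours, with optional Gaussian current noise — for exercising
#' [check_field_drift()].
#'
#' @param config A [field_config()] giving the starting field, conductivity
#'   and geometry.
#' @param drift_per_window Linear field drift in V/m per window (default 0).
#' @param window_h Drift reference window in hours (default 4).
#' @param noise_sd_A Gaussian current noise SD in amperes (default 0).
#' @param duration_h Log duration in hours (default 24).
#' @param dt_h Interval between checks in hours (default 4).
#' @param seed Integer seed.
#' @return A tibble `time_h`, `current_A`.
#' @export
simulate_current_log <- function(config, drift_per_window = 0, window_h = 4,
                                 noise_sd_A = 0, duration_h = 24, dt_h = 4,
                                 seed = 1) {
  stopifnot(inherits(config, "field_config"))
  if (dt_h <= 0 || duration_h < dt_h) {
    abort("need dt_h > 0 and duration_h >= dt_h",
          class = "spherotax_invalid_config")
  }
  times <- seq(0, duration_h, by = dt_h)
  field <- config$target_field_V_m + drift_per_window * times / window_h
  area <- config$geometry$cross_section_area_m2
  withr::with_seed(seed, {
    current <- field * config$conductivity_S_m * area +
      rnorm(length(times), 0, noise_sd_A)
  })
  tibble(time_h = times, current_A = pmax(current, 0))
}
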