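#' Calibrated time-lapse image of an invading aggregate
#'
#' Wraps a grayscale pixel matrix with its calibration. The package
#' convention, matching acquisition with the anode at the left of the image,
#' is: column index increases toward the cathode (the field axis), row index
#' is the orthogonal axis. Pixel coordinates are 0-based pixel centres and
#' convert to micrometres by multiplying with `pixel_size_um`.
#'
#' @param pixels Numeric matrix of intensities (rows = orthogonal axis,
#'   columns = field axis, cathode at high column index).
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param time_h Acquisition time in hours.
#' @return An object of class `timepoint_image`.
#' @export
timepoint_image <- function(pixels, pixel_size_um, time_h = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0) {
    abort("`pixels` must be a non-empty numeric matrix",
          class = "spherotax_invalid_input")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel size must be positive", class = "spherotax_invalid_input")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, time_h = time_h),
    class = "timepoint_image"
  )
}

#' @export
print.timepoint_image <- function(x, ...) {
  cat(sprintf("timepoint_image: %d x %d px, %.3g um/px, t = %g h\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$time_h))
  invisible(x)
}

# Separable Gaussian blur with replicate (clamped-index) borders.
# Symmetric pairs are added innermost so that mirroring the image mirrors
# the result bit-for-bit — the frontier metrics rely on that exactness.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- max(1L, ceiling(3 * sigma))
  w <- exp(-(0:radius)^2 / (2 * sigma^2))
  w <- w / (w[1] + 2 * sum(w[-1]))
  blur_rows <- function(m) {
    n <- nrow(m)
    out <- w[1] * m
    for (j in seq_len(radius)) {
      lo <- pmax(seq_len(n) - j, 1L)
      hi <- pmin(seq_len(n) + j, n)
      out <- out + w[j + 1] * (m[lo, , drop = FALSE] + m[hi, , drop = FALSE])
    }
    out
  }
  t(blur_rows(t(blur_rows(x))))
}

# translate a matrix by (dx columns, dy rows), zero/constant fill
translate_matrix <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_rows <- seq_len(nr) - dy
  src_cols <- seq_len(nc) - dx
  ok_r <- src_rows >= 1 & src_rows <= nr
  ok_c <- src_cols >= 1 & src_cols <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[src_rows[ok_r], src_cols[ok_c], drop = FALSE]
  }
  out
}

# Pearson correlation of the overlap of ref and moving displaced by (dx, dy)
ncc_at_shift <- function(ref, mov, dx, dy) {
  nr <- nrow(ref); nc <- ncol(ref)
  r_rows <- max(1, 1 + dy):min(nr, nr + dy)
  r_cols <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(r_rows) < 2 || length(r_cols) < 2) return(-Inf)
  a <- ref[r_rows - dy, r_cols - dx]
  b <- mov[r_rows, r_cols]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Translation-only registration of two timepoint images
#'
#' Estimates the integer-pixel translation that best aligns `moving` onto
#' `reference`, without any scaling or rotation, by locating the peak of the
#' FFT cross-correlation (restricted to shifts leaving at least
#' `min_overlap` fractional overlap) and then re-scoring the top candidate
#' peaks with the exact normalized cross-correlation over the overlap
#' region. When a `fiducial_region` is given (e.g. registration marks), only
#' that window drives the estimate; the translation is applied to the full
#' image.
#'
#' @param reference,moving [timepoint_image()] objects of identical size and
#'   pixel size.
#' @param fiducial_region Optional rectangle
#'   `list(rows = c(r1, r2), cols = c(c1, c2))` (1-based, inclusive) used to
#'   estimate the shift.
#' @param max_shift Optional cap on |dx| and |dy| in pixels.
#' @param min_overlap Minimum fractional overlap between the images after
#'   shifting (default 0.25).
#' @return A list of class `registration`: `dx`, `dy` (the translation in
#'   pixels applied to `moving` to align it: positive `dx` moves content
#'   toward higher columns), `ncc` (normalized cross-correlation at the
#'   optimum), and `aligned` (the translated `timepoint_image`, zero-filled).
#' @export
register_timepoints <- function(reference, moving, fiducial_region = NULL,
                                max_shift = NULL, min_overlap = 0.25) {
  stopifnot(inherits(reference, "timepoint_image"),
            inherits(moving, "timepoint_image"))
  if (!isTRUE(all.equal(reference$pixel_size_um, moving$pixel_size_um))) {
    abort("images must share a pixel size", class = "spherotax_invalid_input")
  }
  if (!all(dim(reference$pixels) == dim(moving$pixels))) {
    abort("images must share dimensions", class = "spherotax_invalid_input")
  }
  ref <- reference$pixels
  mov <- moving$pixels
  if (!is.null(fiducial_region)) {
    rr <- fiducial_region$rows; cc <- fiducial_region$cols
    ref_w <- ref[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    mov_w <- mov[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  } else {
    ref_w <- ref
    mov_w <- mov
  }
  nr <- nrow(ref_w); nc <- ncol(ref_w)

  # circular cross-correlation of mean-removed windows
  fa <- fft(ref_w - mean(ref_w))
  fb <- fft(mov_w - mean(mov_w))
  cc_mat <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / (nr * nc)

  # shift grid with wrap-around converted to signed displacements
  dys <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr, seq_len(nr) - 1)
  dxs <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc, seq_len(nc) - 1)
  overlap <- outer(pmax(nr - abs(dys), 0), pmax(nc - abs(dxs), 0)) / (nr * nc)
  admissible <- overlap >= min_overlap
  if (!is.null(max_shift)) {
    admissible <- admissible &
      outer(abs(dys) <= max_shift, abs(dxs) <= max_shift)
  }
  if (!any(admissible)) {
    abort("no admissible overlap for registration",
          class = "spherotax_registration_failure")
  }
  cc_mat[!admissible] <- -Inf

  n_cand <- min(5L, sum(is.finite(cc_mat)))
  ord <- order(cc_mat, decreasing = TRUE)[seq_len(n_cand)]
  best <- c(score = -Inf, dx = 0, dy = 0)
  for (idx in ord) {
    dy <- dys[(idx - 1) %% nr + 1]
    dx <- dxs[(idx - 1) %/% nr + 1]
    score <- ncc_at_shift(ref_w, mov_w, dx, dy)
    if (score > best[["score"]]) best <- c(score = score, dx = dx, dy = dy)
  }
  if (!is.finite(best[["score"]])) {
    abort("registration window carries no usable structure",
          class = "spherotax_registration_failure")
  }
  # moving sits at +d relative to reference; aligning applies -d
  dx_align <- -best[["dx"]]
  dy_align <- -best[["dy"]]
  aligned <- timepoint_image(
    translate_matrix(mov, dx_align, dy_align, fill = 0),
    moving$pixel_size_um, moving$time_h
  )
  structure(
    list(dx = dx_align, dy = dy_align, ncc = best[["score"]], aligned = aligned),
    class = "registration"
  )
}

#' Segment the aggregate from a timepoint image
#'
#' Gaussian smoothing, global Otsu threshold, binary closing, then retention
#' of the largest connected foreground component. The frontier convention is
#' conservative: thin protrusions such as trailing pseudopodia or immobile
#' cells that remain attached to the main component are part of the mask;
#' detached satellite objects are excluded by the largest-component rule.
#'
#' @param image A [timepoint_image()].
#' @param smoothing_sigma Gaussian smoothing SD in pixels (default 2).
#' @param min_area_px Components smaller than this are discarded before the
#'   largest-component selection (default 50).
#' @param close_radius Radius in pixels of the disc structuring element used
#'   for binary closing (default 2).
#' @return An object of class `aggregate_mask`: list with `mask` (logical
#'   matrix), `pixel_size_um`, `time_h`, `area_px`, `touches_border`.
#' @export
segment_aggregate <- function(image, smoothing_sigma = 2, min_area_px = 50,
                              close_radius = 2) {
  stopifnot(inherits(image, "timepoint_image"))
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) == 0) {
    abort("image has zero intensity variance", class = "spherotax_segmentation_failure")
  }
  norm <- (px - rng[1]) / (rng[2] - rng[1])
  sm <- gaussian_blur(norm, smoothing_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) {
    abort("empty foreground after thresholding",
          class = "spherotax_segmentation_failure")
  }
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    bin <- EBImage::closing(EBImage::Image(bin * 1), brush) > 0.5
    bin <- matrix(as.logical(bin), nrow(px), ncol(px))
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) {
    abort("no component reaches the minimum area",
          class = "spherotax_segmentation_failure")
  }
  largest <- keep[which.max(areas[keep])]
  mask <- lab == largest
  structure(
    list(
      mask = mask,
      pixel_size_um = image$pixel_size_um,
      time_h = image$time_h,
      area_px = sum(mask),
      touches_border = any(mask[1, ]) || any(mask[nrow(mask), ]) ||
        any(mask[, 1]) || any(mask[, ncol(mask)])
    ),
    class = "aggregate_mask"
  )
}

#' Extract the four field-aligned frontiers of a mask
#'
#' The frontiers are the extreme extents of the aggregate along the field
#' axis and its orthogonal: cathodal = maximal column extent, anodal =
#' minimal column extent, orthogonal = maximal row extent, orthogonal-prime
#' = minimal row extent, all as 0-based pixel-centre coordinates converted
#' to micrometres.
#'
#' @param mask An `aggregate_mask` from [segment_aggregate()], or a logical
#'   matrix (then `pixel_size_um` and `time_h` must be supplied).
#' @param pixel_size_um,time_h Calibration when `mask` is a bare matrix.
#' @return A one-row tibble: `cathodal_um`, `anodal_um`, `orthogonal_um`,
#'   `orthogonal_prime_um`, `time_h`.
#' @export
extract_frontiers <- function(mask, pixel_size_um = NULL, time_h = NULL) {
  if (inherits(mask, "aggregate_mask")) {
    pixel_size_um <- mask$pixel_size_um
    time_h <- mask$time_h
    m <- mask$mask
  } else {
    m <- mask
    if (is.null(pixel_size_um)) {
      abort("pixel_size_um required for a bare mask",
            class = "spherotax_invalid_input")
    }
    if (is.null(time_h)) time_h <- NA_real_
  }
  if (!any(m)) {
    abort("empty mask has no frontiers", class = "spherotax_empty_mask")
  }
  idx <- which(m, arr.ind = TRUE)
  tibble(
    cathodal_um = (max(idx[, "col"]) - 1) * pixel_size_um,
    anodal_um = (min(idx[, "col"]) - 1) * pixel_size_um,
    orthogonal_um = (max(idx[, "row"]) - 1) * pixel_size_um,
    orthogonal_prime_um = (min(idx[, "row"]) - 1) * pixel_size_um,
    time_h = time_h
  )
}

#' Outward shifts of the four frontiers between two times
#'
#' Outward is positive on every side: the cathodal and orthogonal frontiers
#' move outward by increasing, the anodal and orthogonal-prime frontiers by
#' decreasing. Retraction of a frontier therefore yields a negative shift.
#'
#' @param f0,ft One-row frontier tibbles from [extract_frontiers()] at the
#'   initial and later time (`ft$time_h > f0$time_h`).
#' @return A one-row tibble: `shift_cathodal_um`, `shift_anodal_um`,
#'   `shift_orthogonal_um`, `shift_orthogonal_prime_um`, `time_h`.
#' @export
frontier_shifts <- function(f0, ft) {
  if (!is.na(ft$time_h) && !is.na(f0$time_h) && ft$time_h <= f0$time_h) {
    abort("ft must be later than f0", class = "spherotax_invalid_input")
  }
  if ("aggregate_id" %in% names(f0) && "aggregate_id" %in% names(ft) &&
      !identical(f0$aggregate_id, ft$aggregate_id)) {
    abort("frontier sets belong to different aggregates",
          class = "spherotax_invalid_input")
  }
  tibble(
    shift_cathodal_um = ft$cathodal_um - f0$cathodal_um,
    shift_anodal_um = f0$anodal_um - ft$anodal_um,
    shift_orthogonal_um = ft$orthogonal_um - f0$orthogonal_um,
    shift_orthogonal_prime_um = f0$orthogonal_prime_um - ft$orthogonal_prime_um,
    time_h = ft$time_h
  )
}

#' Cathodal/orthogonal bias and bounding-box area change
#'
#' Cathodal bias is the outward shift of the cathodal frontier minus the
#' outward shift of the anodal frontier; orthogonal bias is the analogous
#' difference between the orthogonal and orthogonal-prime frontiers. The
#' bounding box formed by the four frontiers gives the aggregate size; its
#' change is reported as a proportion of the initial box,
#' (A_t - A_0) / A_0, so retraction reads as negative.
#'
#' @param shifts A one-row tibble from [frontier_shifts()].
#' @param f0,ft The frontier tibbles the shifts were computed from.
#' @return A one-row tibble combining the shifts with `cathodal_bias_um`,
#'   `orthogonal_bias_um`, `bbox_area_t0_um2`, `bbox_area_t_um2`,
#'   `proportional_area_change`.
#' @export
bias_metrics <- function(shifts, f0, ft) {
  a0 <- (f0$cathodal_um - f0$anodal_um) *
    (f0$orthogonal_um - f0$orthogonal_prime_um)
  at <- (ft$cathodal_um - ft$anodal_um) *
    (ft$orthogonal_um - ft$orthogonal_prime_um)
  if (a0 <= 0) {
    abort("degenerate initial bounding box", class = "spherotax_degenerate_box")
  }
  dplyr::bind_cols(
    shifts,
    tibble(
      cathodal_bias_um = shifts$shift_cathodal_um - shifts$shift_anodal_um,
      orthogonal_bias_um = shifts$shift_orthogonal_um -
        shifts$shift_orthogonal_prime_um,
      bbox_area_t0_um2 = a0,
      bbox_area_t_um2 = at,
      proportional_area_change = (at - a0) / a0
    )
  )
}

#' End-to-end analysis of a spheroid time-lapse series
#'
#' Registers each later frame onto the first (translation only), segments
#' the aggregate in every registered frame, extracts the four frontiers and
#' reports shifts, biases and bounding-box area change for each later
#' timepoint relative to time 0, with registration and mask QC columns.
#'
#' @param images List of [timepoint_image()] objects in time order (>= 2).
#' @param register Apply translation registration to later frames
#'   (default TRUE).
#' @param fiducial_region Optional rectangle passed to
#'   [register_timepoints()].
#' @param smoothing_sigma,min_area_px,close_radius Passed to
#'   [segment_aggregate()].
#' @param aggregate_id Label for the aggregate (default "aggregate_1").
#' @return A tibble of class `spheroid_series`, one row per later timepoint,
#'   with the [bias_metrics()] columns plus `aggregate_id`, `reg_dx_px`,
#'   `reg_dy_px`, `mask_area_um2`, `touches_border`.
#' @export
analyze_series <- function(images, register = TRUE, fiducial_region = NULL,
                           smoothing_sigma = 2, min_area_px = 50,
                           close_radius = 2, aggregate_id = "aggregate_1") {
  if (!is.list(images) || length(images) < 2 ||
      !all(vapply(images, inherits, logical(1), "timepoint_image"))) {
    abort("`images` must be a list of >= 2 timepoint_image objects",
          class = "spherotax_invalid_input")
  }
  times <- vapply(images, `[[`, numeric(1), "time_h")
  if (any(diff(times) <= 0)) {
    abort("image times must be strictly increasing",
          class = "spherotax_invalid_input")
  }
  reference <- images[[1]]
  rows <- purrr::map(seq_along(images), function(i) {
    img <- images[[i]]
    if (register && i > 1) {
      reg <- register_timepoints(reference, img, fiducial_region = fiducial_region)
      img <- reg$aligned
      shift <- c(reg$dx, reg$dy)
    } else {
      shift <- c(0, 0)
    }
    mask <- segment_aggregate(img, smoothing_sigma = smoothing_sigma,
                              min_area_px = min_area_px,
                              close_radius = close_radius)
    list(frontiers = extract_frontiers(mask), shift = shift, mask = mask)
  })
  f0 <- rows[[1]]$frontiers
  out <- purrr::map_dfr(rows[-1], function(r) {
    ft <- r$frontiers
    met <- bias_metrics(frontier_shifts(f0, ft), f0, ft)
    dplyr::bind_cols(
      tibble(aggregate_id = aggregate_id),
      met,
      tibble(
        reg_dx_px = r$shift[1], reg_dy_px = r$shift[2],
        mask_area_um2 = r$mask$area_px * r$mask$pixel_size_um^2,
        touches_border = r$mask$touches_border
      )
    )
  })
  class(out) <- c("spheroid_series", class(out))
  out
}

#' Read timepoint images with a YAML sidecar
#'
#' Loads per-timepoint PNG or TIFF files (grayscale; colour images are
#' averaged over channels) with calibration from a YAML sidecar containing
#' `pixel_size_um`, `times_h` (one per image) and optionally
#' `orientation: anode_left` (the assumed convention; any other value is an
#' error).
#'
#' @param paths Character vector of image paths, in time order.
#' @param sidecar Path to the YAML sidecar.
#' @return A list of [timepoint_image()] objects.
#' @export
read_timepoint_images <- function(paths, sidecar) {
  meta <- yaml::read_yaml(sidecar)
  if (!is.null(meta$orientation) && !identical(meta$orientation, "anode_left")) {
    abort("only the anode_left orientation convention is supported",
          class = "spherotax_invalid_input")
  }
  if (length(meta$times_h) != length(paths)) {
    abort("sidecar times_h must match the number of images",
          class = "spherotax_invalid_input")
  }
  purrr::map2(paths, meta$times_h, function(p, t) {
    ext <- tolower(tools::file_ext(p))
    arr <- switch(ext,
      png = {
        if (!requireNamespace("png", quietly = TRUE)) {
          abort("the png package is required to read PNG images")
        }
        png::readPNG(p)
      },
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          abort("the tiff package is required to read TIFF images")
        }
        tiff::readTIFF(p)
      },
      abort(paste0("unsupported image format: ", ext),
            class = "spherotax_invalid_input")
    )
    if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
    timepoint_image(arr, meta$pixel_size_um, t)
  })
}
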