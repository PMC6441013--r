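disk_image <- function(radius_px = 20, size = 64, pixel_size = 2, time_h = 0,
                       speck = FALSE) {
  m <- matrix(0.1, size, size)
  ctr <- (size + 1) / 2
  for (r in seq_len(size)) for (cl in seq_len(size)) {
    if ((r - ctr)^2 + (cl - ctr)^2 <= radius_px^2) m[r, cl] <- 0.9
  }
  if (speck) m[4:5, 4:5] <- 0.9
  timepoint_image(m, pixel_size, time_h)
}

test_that("frontier extraction matches hand-computed extents", {
  one <- matrix(FALSE, 5, 6)
  one[3, 4] <- TRUE # 0-based (row 2, col 3)
  f <- extract_frontiers(one, pixel_size_um = 1)
  expect_equal(unlist(f[1, 1:4]),
               c(cathodal_um = 3, anodal_um = 3,
                 orthogonal_um = 2, orthogonal_prime_um = 2))

  sq <- matrix(TRUE, 5, 5)
  f2 <- extract_frontiers(sq, pixel_size_um = 2)
  expect_equal(unlist(f2[1, 1:4]),
               c(cathodal_um = 8, anodal_um = 0,
                 orthogonal_um = 8, orthogonal_prime_um = 0))

  expect_error(extract_frontiers(matrix(FALSE, 3, 3), pixel_size_um = 1),
               class = "spherotax_empty_mask")
})

test_that("frontier extraction agrees with the brute-force pixel scan", {
  set.seed(5)
  for (i in 1:20) {
    m <- random_mask(sample(3:64, 1), sample(3:64, 1))
    px <- runif(1, 0.5, 4)
    f <- extract_frontiers(m, pixel_size_um = px)
    expect_identical(
      unlist(f[1, c("cathodal_um", "anodal_um", "orthogonal_um",
                    "orthogonal_prime_um")], use.names = FALSE),
      unname(brute_force_frontiers(m, px))
    )
  }
})

test_that("registration recovers exact translations and flags no-overlap", {
  img <- disk_image()
  reg0 <- register_timepoints(img, img)
  expect_equal(c(reg0$dx, reg0$dy), c(0, 0))

  moved <- timepoint_image(translate_matrix_for_test(img$pixels, 7, -3, 0.1),
                           img$pixel_size_um, 1)
  reg <- register_timepoints(img, moved)
  expect_equal(c(reg$dx, reg$dy), c(-7, 3))
  # aligned image matches the reference away from the fill border
  expect_equal(reg$aligned$pixels[10:55, 10:55], img$pixels[10:55, 10:55])

  # a featureless fiducial window cannot anchor an alignment
  expect_error(
    register_timepoints(img, moved,
                        fiducial_region = list(rows = c(1, 6), cols = c(1, 6))),
    class = "spherotax_registration_failure"
  )
})

test_that("segmentation recovers a disk and drops sub-threshold specks", {
  img <- disk_image()
  mask <- segment_aggregate(img, smoothing_sigma = 1)
  truth <- disk_image()$pixels > 0.5
  # boundary may move by ~1 px from smoothing; interiors must agree
  expect_lt(sum(xor(mask$mask, truth)) / sum(truth), 0.15)
  f <- extract_frontiers(mask)
  expect_equal(f$cathodal_um, extract_frontiers(truth, 2)$cathodal_um,
               tolerance = 2 * img$pixel_size_um + 1e-9)

  with_speck <- disk_image(speck = TRUE)
  mask2 <- segment_aggregate(with_speck, smoothing_sigma = 1, min_area_px = 50)
  expect_false(any(mask2$mask[1:8, 1:8]))

  flat <- timepoint_image(matrix(0.5, 32, 32), 1)
  expect_error(segment_aggregate(flat), class = "spherotax_segmentation_failure")
})

test_that("frontier shifts are outward-positive on every side", {
  f0 <- tibble::tibble(cathodal_um = 100, anodal_um = 20, orthogonal_um = 90,
                       orthogonal_prime_um = 10, time_h = 0)
  expect_equal(unlist(frontier_shifts(f0, dplyr::mutate(f0, time_h = 8))[1, 1:4]),
               c(shift_cathodal_um = 0, shift_anodal_um = 0,
                 shift_orthogonal_um = 0, shift_orthogonal_prime_um = 0))

  grown <- tibble::tibble(cathodal_um = 110, anodal_um = 10, orthogonal_um = 100,
                          orthogonal_prime_um = 0, time_h = 8)
  expect_equal(unname(unlist(frontier_shifts(f0, grown)[1, 1:4])),
               rep(10, 4))

  moved <- dplyr::mutate(f0, cathodal_um = cathodal_um + 10,
                         anodal_um = anodal_um + 10, time_h = 8)
  sh <- frontier_shifts(f0, moved)
  expect_equal(sh$shift_cathodal_um, 10)
  expect_equal(sh$shift_anodal_um, -10)
  expect_equal(sh$shift_orthogonal_um, 0)

  expect_error(frontier_shifts(dplyr::mutate(f0, time_h = 9), grown),
               class = "spherotax_invalid_input")
})

test_that("bias metrics implement the frontier-difference definitions", {
  f0 <- tibble::tibble(cathodal_um = 50, anodal_um = -50, orthogonal_um = 50,
                       orthogonal_prime_um = -50, time_h = 0)
  ft <- tibble::tibble(cathodal_um = 60, anodal_um = -54, orthogonal_um = 53,
                       orthogonal_prime_um = -47, time_h = 8)
  bm <- bias_metrics(frontier_shifts(f0, ft), f0, ft)
  expect_equal(bm$cathodal_bias_um, 10 - 4)
  expect_equal(bm$orthogonal_bias_um, 3 - (-3))

  # pure translation toward the cathode by d: bias 2d, area unchanged
  d <- 12
  ft2 <- dplyr::mutate(f0, cathodal_um = cathodal_um + d,
                       anodal_um = anodal_um + d, time_h = 8)
  bm2 <- bias_metrics(frontier_shifts(f0, ft2), f0, ft2)
  expect_equal(bm2$cathodal_bias_um, 2 * d)
  expect_equal(bm2$proportional_area_change, 0)

  # 100 x 100 -> 120 x 100 box: +20% area
  ft3 <- dplyr::mutate(f0, cathodal_um = 70, time_h = 8)
  bm3 <- bias_metrics(frontier_shifts(f0, ft3), f0, ft3)
  expect_equal(bm3$proportional_area_change, 0.2)

  degen <- dplyr::mutate(f0, cathodal_um = -50)
  expect_error(bias_metrics(frontier_shifts(degen, ft),
                            degen, ft),
               class = "spherotax_degenerate_box")
})

test_that("series analysis recovers phenotypes end to end", {
  # cathodally invading phenotype with frame drift: bias within 2 px of truth
  u87 <- simulate_spheroid_series(global_translation_px = c(3, -2), seed = 7)
  res <- analyze_series(u87$images, fiducial_region = u87$truth$fiducial_region)
  px <- u87$truth$params$pixel_size_um
  expect_lt(max(abs(res$cathodal_bias_um - u87$truth$bias$cathodal_bias_um)),
            2 * px + 1e-9)
  expect_equal(res$reg_dx_px, c(-3, -6))
  expect_equal(res$reg_dy_px, c(2, 4))

  # anodally invading, retracting phenotype: negative bias and shrinkage
  daoy <- simulate_spheroid_series(field_bias_um_h = -1.4,
                                   orthogonal_retraction_um_h = 3,
                                   isotropic_growth_um_h = 0.5, seed = 3)
  res2 <- analyze_series(daoy$images,
                         fiducial_region = daoy$truth$fiducial_region)
  expect_true(all(res2$cathodal_bias_um < 0))
  expect_true(all(res2$proportional_area_change < 0))
})

test_that("a frame translation common to the scene cancels under registration", {
  sim <- simulate_spheroid_series(frame_times_h = c(0, 24), seed = 21)
  base <- analyze_series(sim$images, fiducial_region = sim$truth$fiducial_region)

  shifted_imgs <- purrr::imap(sim$images, function(img, k) {
    timepoint_image(
      translate_matrix_for_test(img$pixels, 2 * (k - 1), -(k - 1), 0.15),
      img$pixel_size_um, img$time_h
    )
  })
  shifted <- analyze_series(shifted_imgs,
                            fiducial_region = sim$truth$fiducial_region)
  px <- sim$truth$params$pixel_size_um
  expect_lt(max(abs(shifted$cathodal_bias_um - base$cathodal_bias_um)),
            px + 1e-9)
  expect_equal(shifted$reg_dx_px, -2)
  expect_equal(shifted$reg_dy_px, 1)
})

test_that("image files round-trip through the PNG reader with YAML sidecar", {
  skip_if_not_installed("png")
  dir <- withr::local_tempdir()
  sim <- simulate_spheroid_series(initial_radius_um = 40,
                                  frame_times_h = c(0, 8), seed = 2)
  paths <- file.path(dir, sprintf("t%d.png", seq_along(sim$images)))
  for (i in seq_along(paths)) png::writePNG(sim$images[[i]]$pixels, paths[i])
  sidecar <- file.path(dir, "meta.yaml")
  yaml::write_yaml(list(pixel_size_um = 2, times_h = c(0, 8),
                        orientation = "anode_left"), sidecar)
  imgs <- read_timepoint_images(paths, sidecar)
  expect_equal(length(imgs), 2)
  expect_equal(imgs[[2]]$time_h, 8)
  # 8-bit quantization: pixels within 1/255
  expect_lt(max(abs(imgs[[1]]$pixels - sim$images[[1]]$pixels)), 1 / 254)
})
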