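# Independent brute-force oracles used to cross-check the implementation.

# scan every foreground pixel explicitly (0-based centres, um)
brute_force_frontiers <- function(mask, pixel_size) {
  cath <- -Inf; anod <- Inf; orth <- -Inf; orthp <- Inf
  for (r in seq_len(nrow(mask))) {
    for (cl in seq_len(ncol(mask))) {
      if (mask[r, cl]) {
        cath <- max(cath, cl - 1)
        anod <- min(anod, cl - 1)
        orth <- max(orth, r - 1)
        orthp <- min(orthp, r - 1)
      }
    }
  }
  c(cathodal = cath, anodal = anod,
    orthogonal = orth, orthogonal_prime = orthp) * pixel_size
}

random_mask <- function(nr, nc, p = 0.3) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

# literal step-down Sidak: sorted adjusted values with a running maximum
brute_force_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    a <- 1 - (1 - p[ord[k]])^(m - k + 1)
    run <- max(run, a)
    adj_sorted[k] <- min(run, 1)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# literal step-up Benjamini-Hochberg: min over j >= k of p_(j) * m / j
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, ps[j] * m / j)
    adj_sorted[k] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

flip_image_lr <- function(img) {
  timepoint_image(img$pixels[, ncol(img$pixels):1, drop = FALSE],
                  img$pixel_size_um, img$time_h)
}

flip_image_tb <- function(img) {
  timepoint_image(img$pixels[nrow(img$pixels):1, , drop = FALSE],
                  img$pixel_size_um, img$time_h)
}

flip_region_lr <- function(region, nc) {
  list(rows = region$rows,
       cols = c(nc - region$cols[2] + 1, nc - region$cols[1] + 1))
}

flip_region_tb <- function(region, nr) {
  list(rows = c(nr - region$rows[2] + 1, nr - region$rows[1] + 1),
       cols = region$cols)
}

random_track <- function(id, n_points = 8) {
  tibble::tibble(
    cell_id = id,
    time_h = cumsum(runif(n_points, 0.1, 1)),
    x_um = cumsum(rnorm(n_points, 0, 5)),
    y_um = cumsum(rnorm(n_points, 0, 5))
  )
}

# independent translation used to construct registration test cases
translate_matrix_for_test <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      sr <- r - dy; sc <- cl - dx
      if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc) out[r, cl] <- m[sr, sc]
    }
  }
  out
}
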