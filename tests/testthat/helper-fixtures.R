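# Shared fixtures and independent oracles, all built in code.

# Noise-free optics for geometry-exact tests.
quiet_optics <- function(...) {
  synth_params(poisson_noise = FALSE, read_noise_sd = 0, ...)
}

# Render a stripe pattern of given orientation (radians from +x, y down):
# sinusoidal intensity varying perpendicular to the stripes.
stripe_image <- function(n = 128, angle, period_px = 12, pixel_size_um = 0.1) {
  x <- matrix(rep(0:(n - 1), each = n), n)
  y <- matrix(rep(0:(n - 1), times = n), n)
  perp <- -sin(angle) * x + cos(angle) * y
  micrograph(1 + 0.5 * cos(2 * pi * perp / period_px), pixel_size_um)
}

# 8-connected component count by explicit BFS (independent of the
# package's labelling).
component_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (idx in which(mask & !seen)) {
    if (seen[idx]) next
    count <- count + 1L
    stack <- idx
    seen[idx] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && !seen[j]) {
            seen[j] <- TRUE
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  count
}

# Distance (px) from every pixel to the nearest TRUE pixel of `mask`.
distance_to_mask <- function(mask) {
  t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(!mask)))))
}

# Rasterize ground-truth polylines onto the pixel grid.
rasterize_truth <- function(field, params = field$params) {
  nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
  psz <- params$pixel_size_um
  truth <- matrix(FALSE, nr, nc)
  for (fl in field$filaments) {
    for (i in seq_len(nrow(fl$xy) - 1L)) {
      t <- seq(0, 1, length.out = 60)
      xs <- fl$xy[i, 1] + t * (fl$xy[i + 1L, 1] - fl$xy[i, 1])
      ys <- fl$xy[i, 2] + t * (fl$xy[i + 1L, 2] - fl$xy[i, 2])
      rr <- pmin(pmax(round(ys / psz) + 1, 1), nr)
      cc <- pmin(pmax(round(xs / psz) + 1, 1), nc)
      truth[cbind(rr, cc)] <- TRUE
    }
  }
  truth
}

# Explicit-Euler finite-difference 2D diffusion of a disc bleach; returns
# the spot-mean trace at the requested times. Independent oracle for the
# spectral FRAP generator.
fd_frap_oracle <- function(D, radius, times, depth = 0.9, L = NULL, n = 160) {
  if (is.null(L)) L <- max(10 * radius, 5 * sqrt(4 * D * max(times)) + 4 * radius)
  dx <- L / n
  dt <- 0.2 * dx^2 / D # stability margin under dt <= dx^2 / (4 D)
  ax <- (seq_len(n) - 0.5) * dx - L / 2
  r2 <- outer(ax^2, ax^2, `+`)
  spot <- r2 <= radius^2
  u <- matrix(1, n, n)
  u[spot] <- 1 - depth
  lap <- function(m) {
    up <- m[c(1, 1:(n - 1)), ]; dn <- m[c(2:n, n), ]
    lf <- m[, c(1, 1:(n - 1))]; rt <- m[, c(2:n, n)]
    (up + dn + lf + rt - 4 * m) / dx^2
  }
  t_now <- 0
  res <- numeric(length(times)) # times assumed ascending
  for (i in seq_along(times)) {
    while (t_now < times[i] - 1e-12) {
      step <- min(dt, times[i] - t_now)
      u <- u + D * step * lap(u)
      t_now <- t_now + step
    }
    res[i] <- mean(u[spot])
  }
  res
}

# Single-aster inflow series for velocimetry checks.
make_single_aster_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- synth_params(image_size_px = c(128L, 128L), pixel_size_um = 0.2,
                      n_filaments = 60, length_um_mean = 5, length_um_sd = 1.5,
                      psf_sigma_um = 0.3, line_amplitude = 120,
                      background = 20, seed = seed)
    f <- sample_filament_field(p, compute_nodes = FALSE)
    cp <- contraction_params(n_frames = 22L, frame_interval_s = 10,
                             aster_centers = rbind(c(12.7, 12.7)),
                             v0_um_per_s = 0.08, capture_radius_um = 10,
                             mode = "global", seed = seed + 1000L)
    res <- generate_contraction_series(f, cp)
    cache[[key]] <- res
    res
  }
})

# One frozen contraction series per mode, shared across dynamics tests.
# Conditions match the synthetic contraction study design.
make_contraction_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(mode, seed = 11L) {
    key <- paste0(mode, seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- synth_params(image_size_px = c(128L, 128L), pixel_size_um = 0.2,
                      n_filaments = 60, length_um_mean = 5, length_um_sd = 1.5,
                      psf_sigma_um = 0.3, line_amplitude = 120,
                      background = 20, seed = seed)
    f <- sample_filament_field(p, compute_nodes = FALSE)
    cp <- contraction_params(
      n_frames = 22L, frame_interval_s = 10,
      aster_centers = rbind(c(6.4, 12.7), c(19, 12.7)),
      v0_um_per_s = 0.08, capture_radius_um = 10,
      mode = mode, seed = seed + 1000L
    )
    res <- generate_contraction_series(f, cp)
    cache[[key]] <- res
    res
  }
})
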