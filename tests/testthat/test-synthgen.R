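test_that("filament sampling respects counts, determinism and orientation concentration", {
  p0 <- quiet_optics(n_filaments = 0, seed = 1)
  f0 <- sample_filament_field(p0)
  expect_length(f0$filaments, 0)
  expect_equal(nrow(f0$node_coords), 0)

  p <- quiet_optics(n_filaments = 40, seed = 7)
  f1 <- sample_filament_field(p)
  f2 <- sample_filament_field(p)
  expect_identical(f1, f2)

  th <- vapply(f1$filaments, `[[`, numeric(1), "theta")
  expect_true(all(th >= 0 & th < pi))

  # high concentration about a single 30 degree director
  pk <- quiet_optics(n_filaments = 400, orientation_kappa = 1e6,
                     n_director_domains = 1, seed = 3)
  fk <- sample_filament_field(pk, compute_nodes = FALSE)
  thk <- vapply(fk$filaments, `[[`, numeric(1), "theta")
  dev <- Arg(exp(2i * (thk - fk$directors$angles[1]))) / 2
  expect_lt(sqrt(mean(dev^2)), 0.01)
})

test_that("ground-truth nodes lie on two distinct filaments and match a sampling oracle", {
  p <- quiet_optics(n_filaments = 25, length_um_mean = 8, seed = 11)
  f <- sample_filament_field(p)
  expect_gt(nrow(f$node_coords), 0)

  dist_to_polyline <- function(pt, xy) {
    dmin <- Inf
    for (i in seq_len(nrow(xy) - 1L)) {
      a <- xy[i, ]; b <- xy[i + 1L, ]
      ab <- b - a; ab2 <- sum(ab^2)
      t <- if (ab2 > 0) max(0, min(1, sum((pt - a) * ab) / ab2)) else 0
      dmin <- min(dmin, sqrt(sum((pt - (a + t * ab))^2)))
    }
    dmin
  }
  for (k in seq_len(nrow(f$node_coords))) {
    d <- vapply(f$filaments, function(fl) {
      dist_to_polyline(f$node_coords[k, ], fl$xy)
    }, numeric(1))
    expect_gte(sum(d < 1e-8), 2)
  }

  # independent oracle: dense sampling of filament pairs detects the same
  # number of crossings
  n_cross <- 0L
  for (i in seq_len(length(f$filaments) - 1L)) {
    for (j in (i + 1L):length(f$filaments)) {
      si <- f$filaments[[i]]$xy; sj <- f$filaments[[j]]$xy
      ti <- seq(0, 1, length.out = 400)
      pi_ <- cbind(approx(seq_len(nrow(si)), si[, 1], (nrow(si) - 1) * ti + 1)$y,
                   approx(seq_len(nrow(si)), si[, 2], (nrow(si) - 1) * ti + 1)$y)
      pj <- cbind(approx(seq_len(nrow(sj)), sj[, 1], (nrow(sj) - 1) * ti + 1)$y,
                  approx(seq_len(nrow(sj)), sj[, 2], (nrow(sj) - 1) * ti + 1)$y)
      dd <- outer(pi_[, 1], pj[, 1], `-`)^2 + outer(pi_[, 2], pj[, 2], `-`)^2
      if (min(dd) < (0.02)^2) n_cross <- n_cross + 1L
    }
  }
  # one node per crossing pair for straight filaments
  expect_equal(nrow(f$node_coords), n_cross)
})

test_that("rendering follows the optical model exactly in the noiseless limit", {
  p <- quiet_optics(image_size_px = c(48L, 48L), n_filaments = 0,
                    background = 10)
  f <- sample_filament_field(p)
  img <- render_micrograph(f, noise = FALSE)
  expect_true(all(img$pixels == 10))

  # multiplicity scales peak intensity linearly (zero background so the
  # peak is pure signal)
  p0 <- quiet_optics(image_size_px = c(48L, 48L), n_filaments = 0,
                     background = 0)
  mk <- function(mult) {
    fil <- list(filaments = list(list(
      xy = rbind(c(1, 2.35), c(3.8, 2.35)), theta = 0, multiplicity = mult
    )), params = p0)
    max(render_micrograph(fil, p0, noise = FALSE)$pixels)
  }
  expect_equal(mk(2) / mk(1), 2, tolerance = 1e-9)

  # cross-section of a horizontal ridge is the line-spread Gaussian
  ps <- quiet_optics(image_size_px = c(64L, 64L), n_filaments = 0,
                     background = 0, psf_sigma_um = 0.3, pixel_size_um = 0.1,
                     line_amplitude = 120)
  fil <- list(filaments = list(list(
    xy = rbind(c(0.5, 3.15), c(5.8, 3.15)), theta = 0, multiplicity = 1
  )), params = ps)
  im <- render_micrograph(fil, ps, noise = FALSE)
  y <- (seq_len(64) - 1) * 0.1
  expected <- 120 * exp(-(y - 3.15)^2 / (2 * 0.3^2))
  expect_lt(max(abs(im$pixels[, 30] - expected)), 1e-6)

  # noise is reproducible under a fixed seed and off by request
  pn <- synth_params(image_size_px = c(48L, 48L), n_filaments = 5, seed = 5)
  fn <- sample_filament_field(pn)
  expect_identical(render_micrograph(fn, seed = 9)$pixels,
                   render_micrograph(fn, seed = 9)$pixels)
  expect_true(all(render_micrograph(fn, seed = 9)$pixels >= 0))
})

test_that("true order parameter increases monotonically with concentration", {
  kappas <- c(0, 1, 2, 4, 8)
  n <- 10000L
  qs <- vapply(kappas, function(k) {
    p <- quiet_optics(image_size_px = c(64L, 64L), n_filaments = n,
                      orientation_kappa = k, n_director_domains = 1,
                      seed = 100 + k)
    true_order_parameter(sample_filament_field(p, compute_nodes = FALSE))
  }, numeric(1))
  # 2 SE of the resultant under weak order is about 2 / sqrt(2 n)
  expect_true(all(diff(qs) > -2 / sqrt(2 * n)))
  expect_true(all(diff(qs) > 0))
  expect_lt(qs[1], 0.02)
  expect_gt(qs[5], 0.9)
})

test_that("contraction kinematics: identity without flow, monotone collapse with it", {
  p <- quiet_optics(image_size_px = c(96L, 96L), pixel_size_um = 0.2,
                    n_filaments = 30, seed = 21)
  f <- sample_filament_field(p, compute_nodes = FALSE)

  cp_none <- contraction_params(n_frames = 4L, mode = "none",
                                bleach_rate_per_frame = 0, seed = 1)
  s_none <- generate_contraction_series(f, cp_none)
  expect_equal(s_none$actin$frames[, , 1], s_none$actin$frames[, , 4])
  expect_identical(s_none$label, "noncontracting")

  aster <- rbind(c(9.5, 9.5))
  cp_gl <- contraction_params(n_frames = 8L, frame_interval_s = 10,
                              aster_centers = aster, v0_um_per_s = 0.08,
                              capture_radius_um = 30, mode = "global", seed = 2)
  s_gl <- generate_contraction_series(f, cp_gl)
  mean_dist <- vapply(s_gl$geoms, function(g) {
    v <- do.call(rbind, lapply(g, `[[`, "xy"))
    mean(sqrt((v[, 1] - 9.5)^2 + (v[, 2] - 9.5)^2))
  }, numeric(1))
  expect_true(all(diff(mean_dist) <= 0))
  expect_lt(mean_dist[8], mean_dist[1])

  cp_pt <- contraction_params(n_frames = 4L, aster_centers = aster,
                              capture_radius_um = 30, mode = "partial", seed = 3)
  s_pt <- generate_contraction_series(f, cp_pt)
  right <- s_pt$flow[[1]]$x_um >= (95 * 0.2) / 2
  expect_true(all(s_pt$flow[[1]]$u_um_s[right] == 0))
  expect_true(all(s_pt$flow[[1]]$v_um_s[right] == 0))
  expect_gt(max(abs(s_pt$flow[[1]]$u_um_s[!right])), 0)
})

test_that("rendered intensity is conserved while filaments move without shrinking", {
  p <- quiet_optics(image_size_px = c(96L, 96L), pixel_size_um = 0.2,
                    n_filaments = 40, length_um_mean = 3, seed = 31)
  f <- sample_filament_field(p, compute_nodes = FALSE)
  # keep only filaments whose tails stay clear of the border for the whole
  # motion, so border clipping cannot leak intensity in or out
  margin <- 7 * p$psf_sigma_um + 0.6
  fov <- c(95, 95) * 0.2
  f$filaments <- Filter(function(fl) {
    all(fl$xy[, 1] > margin & fl$xy[, 1] < fov[1] - margin &
          fl$xy[, 2] > margin & fl$xy[, 2] < fov[2] - margin)
  }, f$filaments)
  expect_gt(length(f$filaments), 5)
  # a distant aster gives near-uniform inward flow, so filaments translate
  # without the transverse compression inherent to tight radial
  # convergence
  cp <- contraction_params(n_frames = 5L, frame_interval_s = 2,
                           aster_centers = rbind(c(60, 60)),
                           v0_um_per_s = 0.05, capture_radius_um = 200,
                           bleach_rate_per_frame = 0, mode = "global",
                           seed = 4)
  s <- generate_contraction_series(f, cp)
  totals <- apply(s$actin$frames, 3, function(m) sum(m - p$background))
  expect_lt(max(abs(totals - totals[1])) / totals[1], 0.01)
})

test_that("FRAP generator obeys its limits and matches a finite-difference oracle", {
  # fully immobile: no recovery beyond the bleach depth
  tr1 <- generate_frap_trace(3, 5, immobile_fraction = 1, frame_time_s = 0.5,
                             n_frames = 40L, bleach_depth = 0.8)
  post <- tr1$spot_intensity[tr1$bleach_index:length(tr1$spot_intensity)]
  expect_lt(max(abs(post - (1 - 0.8))), 0.02)

  # very fast diffusion: full recovery within the first frame interval
  tr2 <- generate_frap_trace(500, 2, immobile_fraction = 0, frame_time_s = 2,
                             n_frames = 10L)
  expect_gt(tr2$spot_intensity[tr2$bleach_index + 1L], 0.99)

  # spectral solution against explicit-Euler diffusion
  tr3 <- generate_frap_trace(3, 5, immobile_fraction = 0, frame_time_s = 1,
                             n_frames = 25L, bleach_depth = 0.9)
  times <- (0:24) * 1
  oracle <- fd_frap_oracle(3, 5, times, depth = 0.9)
  got <- tr3$spot_intensity[tr3$bleach_index:length(tr3$spot_intensity)]
  expect_lt(sqrt(mean((got - oracle)^2)), 0.01)
})

test_that("stepwise binding traces have exact plateaus and calibrated noise", {
  tr <- generate_rifs_trace(data.frame(duration_s = 100, dOT_nm = 4))
  expect_true(all(tr$dOT_nm == 4))

  tr2 <- generate_rifs_trace(data.frame(duration_s = c(100, 100),
                                        dOT_nm = c(0, 6)))
  expect_equal(mean(tr2$dOT_nm[101:200]) - mean(tr2$dOT_nm[1:100]), 6)

  tr3 <- generate_rifs_trace(data.frame(duration_s = 500, dOT_nm = 2),
                             noise_sd = 0.1, seed = 2)
  # chi-square 99% coverage band for the sample SD at n = 500
  expect_gt(sd(tr3$dOT_nm), 0.08)
  expect_lt(sd(tr3$dOT_nm), 0.12)
})
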