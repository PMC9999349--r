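test_that("2D correlation obeys its algebraic identities", {
  set.seed(1)
  a <- matrix(rnorm(64 * 64, 50, 5), 64)
  expect_equal(correlation_2d(a, a), 1)
  expect_equal(correlation_2d(a, max(a) - a), -1)
  b <- matrix(rnorm(64 * 64), 64)
  expect_equal(correlation_2d(a, b), correlation_2d(b, a))
  expect_equal(correlation_2d(2.5 * a + 7, b), correlation_2d(a, b))
  expect_error(correlation_2d(a, matrix(3, 64, 64)), "zero-variance")

  set.seed(2)
  n1 <- matrix(rnorm(256^2), 256); n2 <- matrix(rnorm(256^2), 256)
  expect_lt(abs(correlation_2d(n1, n2)), 0.02)
})

test_that("registration recovers imposed drift, with and without noise", {
  set.seed(3)
  base <- macnet:::gaussian_smooth(matrix(rnorm(128 * 128), 128), 2)
  drift <- function(m, k) {
    out <- matrix(mean(m), 128, 128)
    src_r <- 1:(128 - 3 * k); src_c <- (2 * k + 1):128
    out[src_r + 3 * k, src_c - 2 * k] <- m[src_r, src_c]
    out
  }
  frames <- lapply(0:3, function(k) drift(base, k))
  ts <- image_series(frames, 0.1, 5)
  reg <- register_series(ts)
  sh <- attr(reg, "shifts")
  # shifts are relative to the running registered reference, so a constant
  # per-frame drift accumulates
  expect_lt(max(abs(sh[, "dy"] - c(0, 3, 6, 9))), 0.2)
  expect_lt(max(abs(sh[, "dx"] - c(0, -2, -4, -6))), 0.2)

  # identical frames: zero shifts
  ts0 <- image_series(list(base, base, base), 0.1, 5)
  expect_true(all(abs(attr(register_series(ts0), "shifts")) < 1e-6))

  # 10% noise barely degrades the recovery
  set.seed(4)
  noisy <- lapply(0:3, function(k) {
    drift(base, k) + 0.1 * sd(base) * matrix(rnorm(128^2), 128)
  })
  regn <- register_series(image_series(noisy, 0.1, 5))
  shn <- attr(regn, "shifts")
  expect_lt(max(abs(shn[, "dy"] - c(0, 3, 6, 9))), 0.5)
  expect_lt(max(abs(shn[, "dx"] - c(0, -2, -4, -6))), 0.5)
})

test_that("lag-1 and cross-channel traces read out remodeling signatures", {
  still <- matrix(rep(macnet:::gaussian_smooth(matrix(rnorm(64^2), 64), 2), 4),
                  c(64, 64, 4))
  dim(still) <- c(64, 64, 4)
  ts <- image_series(still, 0.1, 10)
  expect_true(all(abs(lag1_trace(ts)$values - 1) < 1e-12))

  set.seed(5)
  wn <- array(rnorm(48 * 48 * 6), c(48, 48, 6))
  tw <- image_series(wn, 0.1, 10)
  expect_lt(max(abs(lag1_trace(tw)$values)), 0.1)

  # contracting generator series: dip then recovery
  s <- make_contraction_fixture("global")
  l1 <- lag1_trace(register_series(s$actin))
  i_min <- which.min(l1$values)
  expect_lt(i_min, length(l1$values))
  expect_gt(l1$values[length(l1$values)], min(l1$values))
  expect_gt(max(l1$values[1:3]) - min(l1$values), 0.05)

  # cross-channel: identical channels give 1, independent noise near 0
  expect_true(all(abs(crosschannel_trace(tw, tw)$values - 1) < 1e-12))
  set.seed(6)
  wn2 <- array(rnorm(48 * 48 * 6), c(48, 48, 6))
  cc0 <- crosschannel_trace(tw, image_series(wn2, 0.1, 10))
  expect_lt(max(abs(cc0$values)), 0.1)

  # myosin accumulation drives a rising actin-myosin correlation
  cc <- crosschannel_trace(s$actin, s$myosin)
  expect_gt(cor(seq_along(cc$values), cc$values, method = "spearman"), 0.8)
})

test_that("normalized intensity traces expose photobleaching", {
  const <- array(5, c(16, 16, 3))
  expect_equal(normalized_intensity_trace(image_series(const, 0.1, 1)),
               rep(1, 3))
  two <- array(c(rep(2, 256), rep(4, 256)), c(16, 16, 2))
  expect_equal(normalized_intensity_trace(image_series(two, 0.1, 1)),
               c(0.5, 1))

  p <- quiet_optics(image_size_px = c(96L, 96L), pixel_size_um = 0.2,
                    n_filaments = 30, background = 0, seed = 13)
  f <- sample_filament_field(p, compute_nodes = FALSE)
  cp <- contraction_params(n_frames = 10L, mode = "none",
                           bleach_rate_per_frame = 0.03, seed = 1)
  s <- generate_contraction_series(f, cp)
  tr <- normalized_intensity_trace(s$actin)
  rate <- 1 - exp(coef(lm(log(tr) ~ seq_along(tr)))[2])
  expect_lt(abs(rate - 0.03) / 0.03, 0.05)
})

test_that("PIV resolves translations and aster inflow", {
  set.seed(7)
  base <- macnet:::gaussian_smooth(matrix(rnorm(256 * 256), 256), 2)
  shifted <- matrix(0, 256, 256)
  shifted[4:256, ] <- base[1:253, ]
  ts <- image_series(list(base, shifted), 0.1, 10)
  vf <- piv(ts, lag_s = 10, window_px = c(64L, 32L))[[1]]
  v_px <- vf$v_um_s[vf$valid] * 10 / 0.1
  u_px <- vf$u_um_s[vf$valid] * 10 / 0.1
  expect_lt(max(abs(v_px - 3)), 0.2)
  expect_lt(max(abs(u_px)), 0.2)

  # identical frames: zero field
  ts0 <- image_series(list(base, base), 0.1, 10)
  vf0 <- piv(ts0, lag_s = 10, window_px = c(32L))[[1]]
  expect_lt(max(abs(c(vf0$u_um_s, vf0$v_um_s)[vf0$valid]) * 10 / 0.1), 0.1)

  # lag validation
  expect_error(piv(ts, lag_s = 7), "multiple")
  expect_error(piv(ts, lag_s = 10, window_px = 8L), ">= 16")

  # generator inflow onto one aster: vectors point at the center
  s <- make_single_aster_fixture()
  reg <- register_series(s$actin)
  vfs <- piv(reg, lag_s = 10, window_px = c(64L, 32L))
  pool <- do.call(rbind, vfs[1:3])
  ctr <- s$cparams$aster_centers[1, ]
  rx <- ctr[1] - pool$x_um
  ry <- ctr[2] - pool$y_um
  rn <- sqrt(rx^2 + ry^2)
  spd <- sqrt(pool$u_um_s^2 + pool$v_um_s^2)
  use <- pool$valid & rn < s$cparams$capture_radius_um & rn > 1 & spd > 0.02
  cosine <- (pool$u_um_s * rx + pool$v_um_s * ry) / (rn * spd)
  expect_gt(mean(cosine[use]), 0.8)
})

test_that("velocity distributions normalize and slow down late in contraction", {
  vf <- data.frame(x_um = rep(1:5, 5), y_um = rep(1:5, each = 5),
                   u_um_s = 0.3, v_um_s = 0.4, valid = TRUE)
  attr(vf, "time_s") <- 0
  class(vf) <- c("velocity_field", class(vf))
  d <- velocity_distribution(list(vf), 0)
  expect_equal(d$speed_um_s[which.max(d$density)], 0.5, tolerance = 0.05)
  dx <- diff(d$speed_um_s)[1]
  expect_equal(sum(d$density) * dx, 1, tolerance = 1e-3)

  s <- make_contraction_fixture("global")
  vfs <- piv(register_series(s$actin), lag_s = 10, window_px = c(32L))
  tt <- vapply(vfs, attr, numeric(1), "time_s")
  early <- velocity_distribution(vfs, tt[2])
  late <- velocity_distribution(vfs, tt[length(tt) - 1])
  mean_of <- function(dd) sum(dd$speed_um_s * dd$density) / sum(dd$density)
  expect_gt(mean_of(early), mean_of(late))
})

test_that("the three-way classifier labels its own generator modes", {
  classify_one <- function(mode) {
    s <- make_contraction_fixture(mode)
    reg <- register_series(s$actin)
    classify_contraction(lag1_trace(reg),
                         crosschannel_trace(s$actin, s$myosin),
                         piv(reg, lag_s = 10, window_px = c(32L)))
  }
  expect_identical(classify_one("global")$label, "contracting")
  expect_identical(classify_one("partial")$label, "partially_contracting")
  expect_identical(classify_one("none")$label, "noncontracting")

  short <- structure(list(values = rep(0.9, 3), times_s = 1:3,
                          mode = "lag1_same_channel"),
                     class = "correlation_trace")
  expect_error(classify_contraction(short, short, list()), "insufficient")
})
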