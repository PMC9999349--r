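skel_from <- function(mask, psz = 0.1) {
  structure(list(mask = mask, pixel_size_um = psz), class = "skeleton_image")
}

test_that("skeleton density is a pixel ratio", {
  expect_equal(skeleton_density(skel_from(matrix(TRUE, 5, 5))), 1)
  expect_equal(skeleton_density(skel_from(matrix(FALSE, 5, 5))), 0)
  m <- matrix(FALSE, 10, 10); m[4, 1:10] <- TRUE
  expect_equal(skeleton_density(skel_from(m)), 0.10)
})

test_that("node detection follows the >2-neighbor rule and merges clusters", {
  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  nd <- detect_nodes(skel_from(plus))
  expect_equal(nd$node_count, 1)
  expect_equal(nd$merged_node_coords[1, ], c(6, 6))

  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_equal(detect_nodes(skel_from(line))$node_count, 0)

  # un-thinned input warns
  blk <- matrix(FALSE, 6, 6); blk[2:4, 2:4] <- TRUE
  expect_warning(detect_nodes(skel_from(blk)), "thinned")

  # 50 random sparse skeletons against a per-pixel loop oracle
  set.seed(12)
  for (i in 1:50) {
    m <- matrix(runif(18 * 18) < 0.18, 18, 18)
    nd <- suppressWarnings(detect_nodes(skel_from(m), border_px = 0))
    oracle <- matrix(FALSE, 18, 18)
    for (r in 1:18) for (cc in 1:18) {
      if (!m[r, cc]) next
      nb <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= 18 && c2 >= 1 && c2 <= 18 && m[rr, c2]) nb <- nb + 1L
      }
      oracle[r, cc] <- nb > 2L
    }
    expect_identical(nrow(nd$node_pixel_coords), sum(oracle))
    if (sum(oracle) > 0) {
      got <- nd$node_pixel_coords[order(nd$node_pixel_coords[, 1],
                                        nd$node_pixel_coords[, 2]), , drop = FALSE]
      want <- which(oracle, arr.ind = TRUE)
      want <- unname(want[order(want[, 1], want[, 2]), , drop = FALSE])
      expect_equal(got, want)
    }
  }
})

test_that("node density converts counts to per-area and matches geometric truth", {
  m <- matrix(FALSE, 20, 20)
  nd0 <- detect_nodes(skel_from(m, 0.1))
  expect_equal(node_density(nd0, skel_from(m, 0.1)), 0)

  # 4 nodes in a 2 um x 2 um field -> 1 per um^2
  sk <- skel_from(matrix(FALSE, 20, 20), 0.1)
  fake <- structure(list(node_count = 4), class = "node_set")
  expect_equal(node_density(fake, sk), 1)

  # detected intersections sit near brute-force segment-crossing truth for
  # optically resolvable crossings: interior, >= 2 px apart, away from
  # filament tips, and crossing at >= 60 degrees - below that the two
  # ridges merge into one over ~2 w / tan(angle) pixels and the junction
  # geometry is erased before any estimator sees it
  dmins <- c(); angles <- c()
  for (seed in c(5, 6, 9)) {
    p <- quiet_optics(image_size_px = c(256L, 256L), n_filaments = 25,
                      length_um_mean = 10, psf_sigma_um = 0.2,
                      background = 10, seed = seed)
    f <- sample_filament_field(p)
    sk2 <- extract_skeleton(render_micrograph(f, noise = FALSE))
    nodes <- suppressWarnings(detect_nodes(sk2))
    truth <- f$node_coords
    if (nrow(truth) > 1) {
      dmat <- as.matrix(dist(truth / 0.1))
      diag(dmat) <- Inf
      sep <- apply(dmat, 1, min) >= 2
    } else sep <- rep(TRUE, nrow(truth))
    for (k in seq_len(nrow(truth))) {
      pt <- truth[k, ]
      d <- vapply(f$filaments, function(fl) {
        min(sqrt((fl$xy[, 1] - pt[1])^2 + (fl$xy[, 2] - pt[2])^2))
      }, numeric(1))
      two <- order(d)[1:2]
      ths <- vapply(f$filaments[two], `[[`, numeric(1), "theta")
      ang <- abs(Arg(exp(2i * (ths[1] - ths[2])))) / 2 * 180 / pi
      dend <- vapply(f$filaments[two], function(fl) {
        min(sqrt(sum((fl$xy[1, ] - pt)^2)),
            sqrt(sum((fl$xy[nrow(fl$xy), ] - pt)^2)))
      }, numeric(1))
      px <- c(pt[2] / 0.1 + 1, pt[1] / 0.1 + 1)
      if (sep[k] && all(dend >= 1) && all(px > 4) && all(px < 253)) {
        dmins <- c(dmins, min(sqrt((nodes$merged_node_coords[, 1] - px[1])^2 +
                                     (nodes$merged_node_coords[, 2] - px[2])^2)))
        angles <- c(angles, ang)
      }
    }
  }
  expect_gte(mean(dmins[angles >= 60] <= 3), 0.9)
  expect_gte(mean(dmins[angles >= 40] <= 4), 0.85)
})

test_that("bundling factor is linear, background-invariant and 1 at the reference", {
  m <- matrix(FALSE, 30, 30); m[15, 5:25] <- TRUE
  sk <- skel_from(m, 0.1)
  set.seed(2)
  base <- matrix(rgamma(900, 5), 30, 30)
  base[m] <- base[m] + 40
  img <- micrograph(base, 0.1)

  ref <- reference_intensity(list(list(img, sk)))
  expect_equal(bundling_factor(img, sk, ref), 1)

  img2 <- micrograph(2 * base, 0.1)
  expect_equal(bundling_factor(img2, sk, ref) / bundling_factor(img, sk, ref),
               2, tolerance = 1e-10)

  img3 <- micrograph(base + 17, 0.1)
  expect_equal(bundling_factor(img3, sk, ref), bundling_factor(img, sk, ref),
               tolerance = 1e-10)

  expect_error(bundling_factor(img, skel_from(matrix(FALSE, 30, 30), 0.1), ref),
               "empty skeleton")

  # triple bundles triple the factor against a single-filament reference
  p1 <- quiet_optics(image_size_px = c(192L, 192L), n_filaments = 15,
                     psf_sigma_um = 0.2, background = 10, seed = 8,
                     bundle_multiplicity_probs = 1)
  p3 <- quiet_optics(image_size_px = c(192L, 192L), n_filaments = 15,
                     psf_sigma_um = 0.2, background = 10, seed = 8,
                     bundle_multiplicity_probs = c(0, 0, 1))
  f1 <- sample_filament_field(p1, compute_nodes = FALSE)
  f3 <- sample_filament_field(p3, compute_nodes = FALSE)
  i1 <- render_micrograph(f1, noise = FALSE); s1 <- extract_skeleton(i1)
  i3 <- render_micrograph(f3, noise = FALSE); s3 <- extract_skeleton(i3)
  refc <- reference_intensity(list(list(i1, s1)))
  expect_equal(bundling_factor(i3, s3, refc), 3, tolerance = 0.05)
})

test_that("reference intensity averages image-level skeleton means", {
  mk <- function(level) {
    m <- matrix(FALSE, 10, 10); m[5, 2:9] <- TRUE
    img <- micrograph(matrix(0, 10, 10) + ifelse(m, level, 0), 0.1)
    list(img, skel_from(m, 0.1))
  }
  expect_equal(reference_intensity(list(mk(10)), subtract_background = FALSE), 10)
  expect_equal(reference_intensity(list(mk(10), mk(20)),
                                   subtract_background = FALSE), 15)
  expect_error(reference_intensity(list()), "non-empty")

  # per-image mean against an explicit masked loop
  set.seed(3)
  m <- matrix(runif(100) < 0.3, 10, 10)
  vals <- matrix(rnorm(100, 50, 5), 10, 10)
  img <- micrograph(pmax(vals, 0), 0.1)
  acc <- 0; n <- 0
  for (r in 1:10) for (cc in 1:10) if (m[r, cc]) {
    acc <- acc + img$pixels[r, cc]; n <- n + 1
  }
  expect_equal(reference_intensity(list(list(img, skel_from(m, 0.1))),
                                   subtract_background = FALSE), acc / n)
})

test_that("network_stats assembles a tidy one-row summary", {
  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  img <- micrograph(matrix(1, 11, 11) + plus * 9, 0.1)
  st <- network_stats(img, skel_from(plus, 0.1), reference_mean_intensity = 9)
  expect_s3_class(st, "data.frame")
  expect_equal(nrow(st), 1)
  expect_equal(st$node_count, 1)
  expect_equal(st$skeleton_density, sum(plus) / 121)
  expect_equal(st$bundling_factor, 1, tolerance = 1e-10)
})
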