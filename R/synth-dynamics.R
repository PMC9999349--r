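#' Parameters for a synthetic actomyosin contraction series
#'
#' Describes a kinematic (prescribed-velocity) contraction: filament
#' vertices within `capture_radius_um` of their nearest aster center move
#' toward it at `v0_um_per_s` while a myosin channel accumulates puncta at
#' the aster centers. `mode = "partial"` applies the flow only in the left
#' image half (x below the field midline); `mode = "none"` forces `v0 = 0`.
#' No force balance or motor kinetics is modeled: the generator reproduces
#' the flow and intensity signatures the analysis pipeline reads out, not
#' the mechanics behind them.
#'
#' @param n_frames Number of frames.
#' @param frame_interval_s Seconds between frames.
#' @param aster_centers Matrix (k x 2) or list of um coordinate pairs;
#'   required unless `mode = "none"`.
#' @param v0_um_per_s Inward speed scale (um/s).
#' @param capture_radius_um Radius of aster attraction (um).
#' @param myosin_punctum_rate Expected new myosin puncta per aster per frame.
#' @param bleach_rate_per_frame Fractional intensity loss per frame, in
#'   `[0, 1)`.
#' @param mode One of `"global"`, `"partial"`, `"none"`.
#' @param seed Integer seed for noise and punctum placement.
#' @return A validated list of class `contraction_params`.
#' @export
contraction_params <- function(n_frames = 25L,
                               frame_interval_s = 10,
                               aster_centers = NULL,
                               v0_um_per_s = 0.08,
                               capture_radius_um = 10,
                               myosin_punctum_rate = 1.5,
                               bleach_rate_per_frame = 0.005,
                               mode = c("global", "partial", "none"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_nonneg_scalar(v0_um_per_s, "v0_um_per_s")
  check_positive_scalar(capture_radius_um, "capture_radius_um")
  check_nonneg_scalar(myosin_punctum_rate, "myosin_punctum_rate")
  check_fraction(bleach_rate_per_frame, "bleach_rate_per_frame", open_top = TRUE)
  if (mode == "none") {
    v0_um_per_s <- 0
  } else if (is.null(aster_centers)) {
    stop("`aster_centers` required unless mode = \"none\"", call. = FALSE)
  }
  if (is.list(aster_centers)) aster_centers <- do.call(rbind, aster_centers)
  if (is.null(aster_centers)) aster_centers <- matrix(numeric(0), 0, 2)
  structure(
    list(n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
         aster_centers = aster_centers, v0_um_per_s = v0_um_per_s,
         capture_radius_um = capture_radius_um,
         myosin_punctum_rate = myosin_punctum_rate,
         bleach_rate_per_frame = bleach_rate_per_frame,
         mode = mode, seed = seed),
    class = "contraction_params"
  )
}

# Prescribed aster-inflow velocity (um/s) at points (n x 2, um).
imposed_velocity <- function(points, cparams, fov_x) {
  n <- nrow(points)
  uv <- matrix(0, n, 2)
  if (cparams$v0_um_per_s == 0 || nrow(cparams$aster_centers) == 0) return(uv)
  ac <- cparams$aster_centers
  d2 <- vapply(seq_len(nrow(ac)), function(k) {
    (points[, 1] - ac[k, 1])^2 + (points[, 2] - ac[k, 2])^2
  }, numeric(n))
  d2 <- matrix(d2, nrow = n)
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(n), nearest)])
  active <- dist <= cparams$capture_radius_um & dist > 1e-9
  if (cparams$mode == "partial") active <- active & points[, 1] < fov_x / 2
  if (any(active)) {
    tgt <- ac[nearest[active], , drop = FALSE]
    dir <- (tgt - points[active, , drop = FALSE]) / dist[active]
    uv[active, ] <- cparams$v0_um_per_s * dir
  }
  uv
}

#' Generate a two-channel contraction time series with ground truth
#'
#' Advances the filament geometry frame by frame under the prescribed
#' aster inflow (vertices never overshoot the center), renders the actin
#' channel with photobleaching, and builds a myosin channel whose puncta
#' accumulate at the aster centers. The imposed flow field, evaluated on a
#' regular grid at each frame transition, is returned as ground truth for
#' velocimetry.
#'
#' @param field A `synth_field` from [sample_filament_field()].
#' @param cparams A [contraction_params()].
#' @param optics A [synth_params()] describing rendering and noise;
#'   defaults to the field's own parameters.
#' @param flow_grid_px Spacing (px) of the ground-truth flow grid.
#' @return A list with `actin` and `myosin` ([image_series()]), `flow`
#'   (list of per-transition data frames `x_um, y_um, u_um_s, v_um_s`),
#'   `geoms` (per-frame filament geometry, ground truth for the rendered
#'   frames), `label` (the generating mode) and `cparams`.
#' @export
generate_contraction_series <- function(field, cparams,
                                        optics = field$params,
                                        flow_grid_px = 16L) {
  stopifnot(inherits(cparams, "contraction_params"))
  fov <- fov_um(optics)
  nr <- optics$image_size_px[1]; nc <- optics$image_size_px[2]
  dt <- cparams$frame_interval_s
  geom <- field
  puncta <- matrix(numeric(0), 0, 2)

  gx <- seq(flow_grid_px / 2, nc - flow_grid_px / 2, by = flow_grid_px)
  gy <- seq(flow_grid_px / 2, nr - flow_grid_px / 2, by = flow_grid_px)
  grid_pts <- cbind(rep((gx - 1) * optics$pixel_size_um, times = length(gy)),
                    rep((gy - 1) * optics$pixel_size_um, each = length(gx)))

  actin <- array(0, dim = c(nr, nc, cparams$n_frames))
  myosin <- array(0, dim = c(nr, nc, cparams$n_frames))
  flow <- vector("list", cparams$n_frames - 1L)
  geoms <- vector("list", cparams$n_frames)

  base_seed <- if (!is.null(cparams$seed)) as.integer(cparams$seed) else NULL

  for (f in seq_len(cparams$n_frames)) {
    geoms[[f]] <- geom$filaments
    scale <- (1 - cparams$bleach_rate_per_frame)^(f - 1)
    sd_f <- if (!is.null(base_seed)) base_seed + 7L * f else NULL
    actin[, , f] <- render_micrograph(geom, optics, noise = TRUE,
                                      intensity_scale = scale,
                                      seed = sd_f)$pixels
    myosin[, , f] <- render_myosin(puncta, optics, scale,
                                   seed = if (!is.null(sd_f)) sd_f + 1L else NULL)

    if (f < cparams$n_frames) {
      flow[[f]] <- {
        uv <- imposed_velocity(grid_pts, cparams, fov["x"])
        data.frame(x_um = grid_pts[, 1], y_um = grid_pts[, 2],
                   u_um_s = uv[, 1], v_um_s = uv[, 2])
      }
      geom$filaments <- lapply(geom$filaments, function(fl) {
        uv <- imposed_velocity(fl$xy, cparams, fov["x"])
        step <- uv * dt
        # clamp so vertices stop at the aster center instead of overshooting
        spd <- sqrt(rowSums(step^2))
        mv <- spd > 0
        if (any(mv)) {
          ac <- cparams$aster_centers
          d2 <- vapply(seq_len(nrow(ac)), function(k) {
            (fl$xy[, 1] - ac[k, 1])^2 + (fl$xy[, 2] - ac[k, 2])^2
          }, numeric(nrow(fl$xy)))
          d2 <- matrix(d2, nrow = nrow(fl$xy))
          dist <- sqrt(apply(d2, 1, min))
          shrink <- pmin(1, dist[mv] / spd[mv])
          step[mv, ] <- step[mv, ] * shrink
        }
        fl$xy <- fl$xy + step
        fl
      })
      n_new <- with_seed(if (!is.null(sd_f)) sd_f + 2L else NULL, {
        if (nrow(cparams$aster_centers) > 0 && cparams$mode != "none") {
          rpois(nrow(cparams$aster_centers), cparams$myosin_punctum_rate)
        } else integer(0)
      })
      if (length(n_new) && sum(n_new) > 0) {
        new_pts <- with_seed(if (!is.null(sd_f)) sd_f + 3L else NULL, {
          ctr <- cparams$aster_centers[rep(seq_along(n_new), n_new), ,
                                       drop = FALSE]
          ctr + matrix(rnorm(2 * nrow(ctr), 0, 0.4), ncol = 2)
        })
        puncta <- rbind(puncta, new_pts)
      }
    }
  }

  list(
    actin = image_series(actin, optics$pixel_size_um, dt, t0_index = 1L,
                         channel = "actin"),
    myosin = image_series(myosin, optics$pixel_size_um, dt, t0_index = 1L,
                          channel = "myosin"),
    flow = flow,
    geoms = geoms,
    label = switch(cparams$mode, global = "contracting",
                   partial = "partially_contracting",
                   none = "noncontracting"),
    cparams = cparams
  )
}

# Render accumulated myosin puncta as Gaussian spots on the optics'
# background, with the same camera noise model as the actin channel.
render_myosin <- function(puncta, optics, intensity_scale = 1, seed = NULL) {
  nr <- optics$image_size_px[1]; nc <- optics$image_size_px[2]
  img <- matrix(0, nr, nc)
  if (nrow(puncta) > 0) {
    for (i in seq_len(nrow(puncta))) {
      img <- add_ridge(img, rbind(puncta[i, ], puncta[i, ]),
                       optics$pixel_size_um,
                       2 * optics$line_amplitude * intensity_scale,
                       optics$psf_sigma_um)
    }
  }
  img <- img + optics$background
  with_seed(seed, {
    if (optics$poisson_noise) img <- matrix(rpois(length(img), img), nr, nc)
    if (optics$read_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, optics$read_noise_sd)
    }
    pmax(img, 0)
  })
}

#' Write per-transition imposed flow fields to CSV
#' @param flow The `flow` element of [generate_contraction_series()] output.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  rows <- do.call(rbind, lapply(seq_along(flow), function(i) {
    cbind(frame = i, flow[[i]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
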