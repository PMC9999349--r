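#' Parameters for the synthetic filament-field generator
#'
#' Describes a quasi-2D membrane-bound filament network and the optics used
#' to image it. Filaments are straight segments by default (the persistence
#' length of actin far exceeds filament length at this field of view); a
#' small per-step direction jitter `bend_sd_rad` turns them into gently
#' curved polylines. Orientations are drawn about a piecewise-constant
#' director field with `n_director_domains` Voronoi domains; the angular
#' noise is pi-periodic (a von Mises draw on the doubled angle, halved), so
#' `orientation_kappa = 0` gives orientations uniform on `[0, pi)` and large
#' kappa collapses onto the local director.
#'
#' @param image_size_px Integer pair `c(rows, cols)`.
#' @param pixel_size_um Micrometers per pixel.
#' @param n_filaments Number of filaments.
#' @param length_um_mean,length_um_sd Mean and SD of filament length (um);
#'   lengths are normal draws truncated below at 0.2 um.
#' @param orientation_kappa Concentration of the pi-periodic orientation
#'   noise about the local director (0 = isotropic).
#' @param n_director_domains Number of nematic domains.
#' @param bundle_multiplicity_probs Probability vector over bundle
#'   multiplicities 1, 2, 3, ...; must sum to 1.
#' @param psf_sigma_um Gaussian line-spread SD of the rendered ridge (um).
#' @param line_amplitude Rendered peak counts per unit multiplicity.
#' @param background Constant background counts.
#' @param poisson_noise Apply Poisson shot noise to signal + background?
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param bend_sd_rad Per-vertex direction jitter of the polyline (rad);
#'   0 keeps filaments straight.
#' @param vertex_spacing_um Polyline vertex spacing (um); sets the spatial
#'   resolution at which contraction flows bend filaments.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(image_size_px = c(256L, 256L),
                         pixel_size_um = 0.1,
                         n_filaments = 100L,
                         length_um_mean = 5,
                         length_um_sd = 1.5,
                         orientation_kappa = 0,
                         n_director_domains = 1L,
                         bundle_multiplicity_probs = 1,
                         psf_sigma_um = 0.2,
                         line_amplitude = 120,
                         background = 10,
                         poisson_noise = TRUE,
                         read_noise_sd = 2,
                         bend_sd_rad = 0,
                         vertex_spacing_um = 0.5,
                         seed = NULL) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px <= 0)) {
    stop("`image_size_px` must be two positive integers", call. = FALSE)
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  if (n_filaments < 0) stop("`n_filaments` must be >= 0", call. = FALSE)
  check_positive_scalar(length_um_mean, "length_um_mean")
  check_positive_scalar(length_um_sd, "length_um_sd")
  check_nonneg_scalar(orientation_kappa, "orientation_kappa")
  if (n_director_domains < 1) stop("`n_director_domains` must be >= 1", call. = FALSE)
  if (abs(sum(bundle_multiplicity_probs) - 1) > 1e-9 ||
      any(bundle_multiplicity_probs < 0)) {
    stop("`bundle_multiplicity_probs` must be non-negative and sum to 1",
         call. = FALSE)
  }
  check_positive_scalar(psf_sigma_um, "psf_sigma_um")
  check_positive_scalar(line_amplitude, "line_amplitude")
  check_nonneg_scalar(background, "background")
  check_nonneg_scalar(read_noise_sd, "read_noise_sd")
  check_nonneg_scalar(bend_sd_rad, "bend_sd_rad")
  check_positive_scalar(vertex_spacing_um, "vertex_spacing_um")
  structure(
    list(image_size_px = image_size_px, pixel_size_um = pixel_size_um,
         n_filaments = as.integer(n_filaments),
         length_um_mean = length_um_mean, length_um_sd = length_um_sd,
         orientation_kappa = orientation_kappa,
         n_director_domains = as.integer(n_director_domains),
         bundle_multiplicity_probs = bundle_multiplicity_probs,
         psf_sigma_um = psf_sigma_um, line_amplitude = line_amplitude,
         background = background, poisson_noise = poisson_noise,
         read_noise_sd = read_noise_sd, bend_sd_rad = bend_sd_rad,
         vertex_spacing_um = vertex_spacing_um, seed = seed),
    class = "synth_params"
  )
}

fov_um <- function(params) {
  # physical extent spanned by pixel centers
  c(x = (params$image_size_px[2] - 1) * params$pixel_size_um,
    y = (params$image_size_px[1] - 1) * params$pixel_size_um)
}

# Liang-Barsky clip of segment p0-p1 to [0,xmax] x [0,ymax].
clip_segment <- function(p0, p1, xmax, ymax) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    p <- c(-d[1], d[1], -d[2], d[2])[i]
    q <- c(p0[1], xmax - p0[1], p0[2], ymax - p0[2])[i]
    if (p == 0) {
      if (q < 0) return(NULL)
    } else {
      r <- q / p
      if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(NULL)
  rbind(p0 + t0 * d, p0 + t1 * d)
}

subdivide_segment <- function(ends, spacing) {
  len <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  n <- max(1L, ceiling(len / spacing))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(ends[1, 1] + t * (ends[2, 1] - ends[1, 1]),
        ends[1, 2] + t * (ends[2, 2] - ends[1, 2]))
}

# Intersection point of two segments, or NULL (parallel / disjoint).
segment_intersection <- function(a0, a1, b0, b1) {
  r <- a1 - a0; s <- b1 - b0
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NULL)
  qp <- b0 - a0
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  a0 + t * r
}

# All crossing points between two polylines (um coordinates, n x 2).
polyline_intersections <- function(pa, pb) {
  out <- list()
  for (i in seq_len(nrow(pa) - 1L)) {
    a0 <- pa[i, ]; a1 <- pa[i + 1L, ]
    lo <- pmin(a0, a1); hi <- pmax(a0, a1)
    for (j in seq_len(nrow(pb) - 1L)) {
      b0 <- pb[j, ]; b1 <- pb[j + 1L, ]
      if (max(pmin(b0, b1) - hi) > 0 || max(lo - pmax(b0, b1)) > 0) next
      p <- segment_intersection(a0, a1, b0, b1)
      if (!is.null(p)) out[[length(out) + 1L]] <- p
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Sample a ground-truthed filament field
#'
#' Draws filament centers uniformly over the field of view, orientations
#' about the local domain director with concentration `orientation_kappa`,
#' truncated-normal lengths and categorical bundle multiplicities, clips
#' each filament at the image border and records every pairwise filament
#' crossing as a ground-truth node.
#'
#' @param params A [synth_params()] object.
#' @param compute_nodes Record ground-truth crossings? The all-pairs
#'   search is quadratic in `n_filaments`; disable for very large fields
#'   whose nodes are not needed.
#' @return A `synth_field` with elements `filaments` (list of
#'   `list(xy, theta, multiplicity)` with `xy` an n x 2 matrix of um
#'   coordinates), `node_coords` (m x 2 matrix of um coordinates),
#'   `directors` (domain seed points and director angles) and `params`.
#' @export
sample_filament_field <- function(params, compute_nodes = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  fov <- fov_um(params)
  with_seed(params$seed, {
    nd <- params$n_director_domains
    directors <- list(
      seeds = cbind(runif(nd, 0, fov["x"]), runif(nd, 0, fov["y"])),
      angles = runif(nd, 0, pi)
    )
    filaments <- vector("list", params$n_filaments)
    mults <- if (params$n_filaments > 0) {
      sample.int(length(params$bundle_multiplicity_probs), params$n_filaments,
                 replace = TRUE, prob = params$bundle_multiplicity_probs)
    } else integer(0)
    for (k in seq_len(params$n_filaments)) {
      ctr <- c(runif(1, 0, fov["x"]), runif(1, 0, fov["y"]))
      dom <- which.min((directors$seeds[, 1] - ctr[1])^2 +
                         (directors$seeds[, 2] - ctr[2])^2)
      theta <- wrap_pi(directors$angles[dom] +
                         rvonmises(1, 0, params$orientation_kappa) / 2)
      len <- max(0.2, rnorm(1, params$length_um_mean, params$length_um_sd))
      u <- c(cos(theta), sin(theta))
      ends <- clip_segment(ctr - len / 2 * u, ctr + len / 2 * u,
                           fov["x"], fov["y"])
      if (is.null(ends)) ends <- rbind(ctr, ctr + 0.2 * u) # center is inside
      xy <- subdivide_segment(ends, params$vertex_spacing_um)
      if (params$bend_sd_rad > 0 && nrow(xy) > 2) {
        step <- sqrt(sum((xy[2, ] - xy[1, ])^2))
        ang <- theta + cumsum(c(0, rnorm(nrow(xy) - 2L, 0, params$bend_sd_rad)))
        pts <- xy[1, , drop = FALSE]
        for (i in seq_along(ang)) {
          pts <- rbind(pts, pts[nrow(pts), ] + step * c(cos(ang[i]), sin(ang[i])))
        }
        xy <- pts
        xy[, 1] <- pmin(pmax(xy[, 1], 0), fov["x"])
        xy[, 2] <- pmin(pmax(xy[, 2], 0), fov["y"])
      }
      filaments[[k]] <- list(xy = unname(xy), theta = unname(theta),
                             multiplicity = mults[k])
    }
    node_coords <- if (compute_nodes) {
      field_nodes(filaments)
    } else matrix(numeric(0), 0, 2)
    structure(
      list(filaments = filaments, node_coords = node_coords,
           directors = directors, params = params),
      class = "synth_field"
    )
  })
}

# Brute-force pairwise crossing points between distinct filaments.
field_nodes <- function(filaments) {
  out <- list()
  nf <- length(filaments)
  if (nf >= 2L) {
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        p <- polyline_intersections(filaments[[i]]$xy, filaments[[j]]$xy)
        if (!is.null(p)) out[[length(out) + 1L]] <- p
      }
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
}

#' @export
print.synth_field <- function(x, ...) {
  cat(sprintf("<synth_field> %d filaments, %d true nodes, %d director domain(s)\n",
              length(x$filaments), nrow(x$node_coords),
              length(x$directors$angles)))
  invisible(x)
}

#' Analytic nematic order parameter of a sampled field
#'
#' The ground-truth scalar order parameter of the sampled orientations:
#' the mean of `cos 2(theta - director)` with the director taken as the
#' principal axis of the orientation sample itself.
#'
#' @param field A `synth_field`.
#' @return Scalar in `[0, 1]`; `NA` for an empty field.
#' @export
true_order_parameter <- function(field) {
  th <- vapply(field$filaments, `[[`, numeric(1), "theta")
  if (!length(th)) return(NA_real_)
  sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
}

#' Render a filament field as a fluorescence micrograph
#'
#' Each filament contributes a Gaussian-profile ridge of SD `psf_sigma_um`
#' and peak amplitude `line_amplitude * multiplicity` (bundles are intensity
#' multiples on a single centerline), additive over filaments, on a constant
#' background. Shot noise (Poisson on signal + background) and additive
#' Gaussian read noise are applied last; negative values are clipped to 0.
#'
#' @param field A `synth_field` (or any list with a `filaments` element).
#' @param params A [synth_params()]; defaults to the field's own.
#' @param noise Apply the configured noise model? Set `FALSE` for noiseless
#'   ground-truth rendering.
#' @param intensity_scale Global multiplier on signal amplitude (used for
#'   bleaching in time series).
#' @param seed Seed for the noise draws only.
#' @return A [micrograph()] in the actin channel.
#' @export
render_micrograph <- function(field, params = field$params, noise = TRUE,
                              intensity_scale = 1, seed = NULL) {
  nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
  psz <- params$pixel_size_um
  img <- matrix(0, nr, nc)
  sig <- params$psf_sigma_um
  for (f in field$filaments) {
    img <- add_ridge(img, f$xy, psz,
                     params$line_amplitude * f$multiplicity * intensity_scale,
                     sig)
  }
  img <- img + params$background
  if (noise) {
    img <- with_seed(seed, {
      out <- img
      if (params$poisson_noise) {
        out <- matrix(rpois(length(out), lambda = out), nr, nc)
      }
      if (params$read_noise_sd > 0) {
        out <- out + rnorm(length(out), 0, params$read_noise_sd)
      }
      pmax(out, 0)
    })
  }
  micrograph(img, psz, "actin")
}

# Add one Gaussian ridge along polyline `xy` (um) to the image. The profile
# is a Gaussian of the minimum distance to the polyline, so joints between
# sub-segments are not double counted.
add_ridge <- function(img, xy, psz, amplitude, sigma_um) {
  nr <- nrow(img); nc <- ncol(img)
  reach <- 7 * sigma_um
  lo <- pmax(floor((apply(xy, 2, min) - reach) / psz) + 1, 1)
  hi <- pmin(ceiling((apply(xy, 2, max) + reach) / psz) + 1, c(nc, nr))
  if (any(lo > hi)) return(img)
  cols <- lo[1]:hi[1]; rows <- lo[2]:hi[2]
  px <- (cols - 1) * psz; py <- (rows - 1) * psz
  X <- matrix(px, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(py, length(rows), length(cols))
  d2 <- matrix(Inf, length(rows), length(cols))
  for (i in seq_len(nrow(xy) - 1L)) {
    a <- xy[i, ]; b <- xy[i + 1L, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    if (ab2 == 0) {
      d2 <- pmin(d2, (X - a[1])^2 + (Y - a[2])^2)
    } else {
      t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / ab2
      t <- pmin(pmax(t, 0), 1)
      d2 <- pmin(d2, (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2)
    }
  }
  img[rows, cols] <- img[rows, cols] + amplitude * exp(-d2 / (2 * sigma_um^2))
  img
}

#' Write a field's ground truth to JSON
#'
#' @param field A `synth_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(field, path) {
  obj <- list(
    filaments = lapply(field$filaments, function(f) {
      list(xy_um = f$xy, theta_rad = f$theta, multiplicity = f$multiplicity)
    }),
    node_coords_um = field$node_coords,
    director_angles_rad = field$directors$angles,
    director_seeds_um = field$directors$seeds
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
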