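#' 2D Pearson correlation of two images
#'
#' Pixelwise Pearson correlation coefficient over the full frame.
#'
#' @param a,b Micrographs or bare matrices of identical geometry.
#' @return Scalar in `[-1, 1]`.
#' @export
correlation_2d <- function(a, b) {
  pa <- if (inherits(a, "micrograph")) a$pixels else a
  pb <- if (inherits(b, "micrograph")) b$pixels else b
  if (!identical(dim(pa), dim(pb))) stop("images must share geometry", call. = FALSE)
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
    stop("zero-variance image: correlation undefined", call. = FALSE)
  }
  stats::cor(as.vector(pa), as.vector(pb))
}

# Cross-correlation translation (b relative to a) by FFT, with quadratic
# (3-point parabola) sub-pixel peak interpolation. Returns c(dy, dx) in px:
# shifting b back by this aligns it with a.
xcorr_shift <- function(a, b, max_shift = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
  if (!is.null(max_shift)) {
    allow_r <- c(seq_len(min(max_shift, nr) + 1L),
                 if (max_shift < nr - 1) (nr - max_shift + 1L):nr else integer(0))
    allow_c <- c(seq_len(min(max_shift, nc) + 1L),
                 if (max_shift < nc - 1) (nc - max_shift + 1L):nc else integer(0))
    keep <- matrix(-Inf, nr, nc)
    keep[unique(allow_r), unique(allow_c)] <- 0
    cc <- cc + keep
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  interp <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) 0 else {
      d <- 0.5 * (cm - cp) / den
      max(-0.5, min(0.5, d))
    }
  }
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  dy <- interp(cc[wrap(pk[1] - 1L, nr), pk[2]], cc[pk[1], pk[2]],
               cc[wrap(pk[1] + 1L, nr), pk[2]])
  dx <- interp(cc[pk[1], wrap(pk[2] - 1L, nc)], cc[pk[1], pk[2]],
               cc[pk[1], wrap(pk[2] + 1L, nc)])
  base <- c(pk[1] - 1L, pk[2] - 1L)
  base[1] <- if (base[1] > nr / 2) base[1] - nr else base[1]
  base[2] <- if (base[2] > nc / 2) base[2] - nc else base[2]
  # peak at (dy, dx) means b is a shifted by (-dy, -dx): report b's shift
  -(base + c(dy, dx))
}

# Translate an image by a (possibly fractional) shift with bilinear
# interpolation and replicated edges.
shift_image <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  sy <- seq_len(nr) + dy
  sx <- seq_len(nc) + dx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  m00 <- m[cl(y0, nr), cl(x0, nc), drop = FALSE]
  m10 <- m[cl(y0 + 1, nr), cl(x0, nc), drop = FALSE]
  m01 <- m[cl(y0, nr), cl(x0 + 1, nc), drop = FALSE]
  m11 <- m[cl(y0 + 1, nr), cl(x0 + 1, nc), drop = FALSE]
  wy <- matrix(fy, nr, nc); wx <- matrix(fx, nr, nc, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m10 * wy * (1 - wx) +
    m01 * (1 - wy) * wx + m11 * wy * wx
}

#' Rigid drift registration of a time series
#'
#' Aligns each frame to the running registered reference (the previous
#' aligned frame) by whole-frame cross-correlation with quadratic sub-pixel
#' peak interpolation, translating frames back by the accumulated drift.
#' Thermal drift is modeled as pure translation; no rotation or scaling.
#'
#' @param ts A [image_series()].
#' @param max_shift_px Largest per-frame shift considered.
#' @return The registered series; recovered cumulative shifts (frames x
#'   `c(dy, dx)`, px) in attribute `"shifts"`.
#' @export
register_series <- function(ts, max_shift_px = 32L) {
  stopifnot(inherits(ts, "macnet_series"))
  nf <- n_frames(ts)
  if (nf < 2L) stop("need >= 2 frames to register", call. = FALSE)
  out <- ts$frames
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  for (i in 2:nf) {
    d <- xcorr_shift(out[, , i - 1L], ts$frames[, , i], max_shift_px)
    shifts[i, ] <- d
    out[, , i] <- shift_image(ts$frames[, , i], d[1], d[2])
  }
  res <- ts
  res$frames <- out
  attr(res, "shifts") <- shifts
  res
}

#' Frame-to-next-frame correlation trace
#'
#' Pearson correlation between each frame and the following one, a
#' similarity trace whose transient dip and recovery marks network
#' remodeling.
#'
#' @param ts A registered [image_series()].
#' @return A `correlation_trace`: `values` (length `n - 1`), `times_s`
#'   (time of the earlier frame, relative to t0), `mode`.
#' @export
lag1_trace <- function(ts) {
  nf <- n_frames(ts)
  vals <- vapply(seq_len(nf - 1L), function(i) {
    correlation_2d(ts$frames[, , i], ts$frames[, , i + 1L])
  }, numeric(1))
  structure(
    list(values = vals, times_s = series_times(ts)[-nf],
         mode = "lag1_same_channel"),
    class = "correlation_trace"
  )
}

#' Same-frame cross-channel correlation trace
#'
#' Pearson correlation between the actin and myosin channels frame by
#' frame; rises as myosin accumulates on the actin structures.
#'
#' @param actin,myosin Synchronized [image_series()] objects.
#' @return A `correlation_trace` with mode `same_frame_cross_channel`.
#' @export
crosschannel_trace <- function(actin, myosin) {
  if (n_frames(actin) != n_frames(myosin)) {
    stop("series must be synchronized", call. = FALSE)
  }
  vals <- vapply(seq_len(n_frames(actin)), function(i) {
    correlation_2d(actin$frames[, , i], myosin$frames[, , i])
  }, numeric(1))
  structure(
    list(values = vals, times_s = series_times(actin),
         mode = "same_frame_cross_channel"),
    class = "correlation_trace"
  )
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf("<correlation_trace> %s, %d values in [%.3f, %.3f]\n",
              x$mode, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Normalized per-frame mean intensity trace
#'
#' Per-frame mean intensity divided by the maximal per-frame mean of the
#' series; values in `(0, 1]`.
#'
#' @param ts A [image_series()].
#' @return Numeric vector, one value per frame.
#' @export
normalized_intensity_trace <- function(ts) {
  m <- apply(ts$frames, 3, mean)
  m / max(m)
}

#' Particle image velocimetry on a time series
#'
#' Windowed FFT cross-correlation between frame `t` and frame `t + lag`,
#' with 3-point Gaussian sub-pixel peak interpolation, optional
#' coarse-to-fine passes (each pass pre-shifts the search window by the
#' previous pass's displacement) and normalized-median-test vector
#' validation.
#'
#' @param ts A registered [image_series()].
#' @param lag_s Time difference between correlated frames (s); must be a
#'   multiple of the frame interval.
#' @param window_px Interrogation window sizes per pass, coarse to fine
#'   (each >= 16).
#' @param overlap_frac Window overlap fraction in `[0, 0.75]`.
#' @param nmt_threshold Normalized median test threshold (vectors above it
#'   are invalidated).
#' @return List of `velocity_field` objects, one per frame pair: data
#'   frame `x_um, y_um, u_um_s, v_um_s, valid` with attributes `time_s`
#'   (earlier frame, relative to t0) and `lag_s`.
#' @export
piv <- function(ts, lag_s = 10, window_px = c(64L, 32L), overlap_frac = 0.5,
                nmt_threshold = 2) {
  stopifnot(inherits(ts, "macnet_series"))
  steps <- lag_s / ts$frame_interval_s
  if (abs(steps - round(steps)) > 1e-9 || round(steps) < 1) {
    stop("`lag_s` must be a positive multiple of the frame interval", call. = FALSE)
  }
  steps <- as.integer(round(steps))
  if (any(window_px < 16L)) stop("window sizes must be >= 16 px", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac > 0.75) {
    stop("`overlap_frac` must be in [0, 0.75]", call. = FALSE)
  }
  nf <- n_frames(ts)
  if (nf <= steps) stop("series shorter than one lag", call. = FALSE)
  t_rel <- series_times(ts)
  lapply(seq_len(nf - steps), function(i) {
    piv_pair(ts$frames[, , i], ts$frames[, , i + steps], ts$pixel_size_um,
             lag_s, window_px, overlap_frac, nmt_threshold,
             time_s = t_rel[i])
  })
}

piv_pair <- function(a, b, pixel_size_um, lag_s, window_px, overlap_frac,
                     nmt_threshold, time_s = 0) {
  nr <- nrow(a); nc <- ncol(a)
  du <- NULL; dv <- NULL; cx <- NULL; cy <- NULL
  for (p in seq_along(window_px)) {
    w <- as.integer(window_px[p])
    step <- max(1L, as.integer(round(w * (1 - overlap_frac))))
    y0 <- seq(1L, nr - w + 1L, by = step)
    x0 <- seq(1L, nc - w + 1L, by = step)
    cy_new <- y0 + (w - 1) / 2
    cx_new <- x0 + (w - 1) / 2
    # pre-shift from previous pass, nearest-center lookup
    pre_u <- matrix(0, length(y0), length(x0))
    pre_v <- matrix(0, length(y0), length(x0))
    if (!is.null(du)) {
      iy <- vapply(cy_new, function(y) which.min(abs(cy - y)), integer(1))
      ix <- vapply(cx_new, function(x) which.min(abs(cx - x)), integer(1))
      pre_u <- round(du[iy, ix, drop = FALSE])
      pre_v <- round(dv[iy, ix, drop = FALSE])
    }
    u <- matrix(NA_real_, length(y0), length(x0))
    v <- matrix(NA_real_, length(y0), length(x0))
    for (r in seq_along(y0)) {
      for (cdx in seq_along(x0)) {
        wy <- y0[r]:(y0[r] + w - 1L)
        wx <- x0[cdx]:(x0[cdx] + w - 1L)
        oy <- pre_v[r, cdx]; ox <- pre_u[r, cdx]
        wy2 <- pmin(pmax(wy + oy, 1L), nr)
        wx2 <- pmin(pmax(wx + ox, 1L), nc)
        d <- window_displacement(a[wy, wx], b[wy2, wx2], max_d = w %/% 3L)
        if (!is.null(d)) {
          v[r, cdx] <- d[1] + oy
          u[r, cdx] <- d[2] + ox
        }
      }
    }
    du <- u; dv <- v; cy <- cy_new; cx <- cx_new
  }
  valid <- is.finite(du) & is.finite(dv) &
    normalized_median_ok(du, nmt_threshold) &
    normalized_median_ok(dv, nmt_threshold)
  out <- data.frame(
    x_um = rep((cx - 1) * pixel_size_um, each = length(cy)),
    y_um = rep((cy - 1) * pixel_size_um, times = length(cx)),
    u_um_s = as.vector(du) * pixel_size_um / lag_s,
    v_um_s = as.vector(dv) * pixel_size_um / lag_s,
    valid = as.vector(valid)
  )
  attr(out, "time_s") <- time_s
  attr(out, "lag_s") <- lag_s
  class(out) <- c("velocity_field", class(out))
  out
}

# Displacement of window b relative to window a from the FFT
# cross-correlation peak, restricted to |d| <= max_d, with 3-point
# Gaussian sub-pixel interpolation. NULL if the window is featureless.
window_displacement <- function(a, b, max_d) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NULL)
  n <- nrow(a)
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(a)
  cc <- cc / (stats::sd(a) * stats::sd(b) * length(a))
  # order lags -max_d..max_d via FFT wrap-around
  idx <- function(d) ((d %% n) + n) %% n + 1L
  lags <- -max_d:max_d
  sub <- cc[idx(lags), idx(lags)]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  gauss3 <- function(cm, c0, cp) {
    eps <- 1e-12
    cm <- max(cm, eps); c0 <- max(c0, eps); cp <- max(cp, eps)
    den <- log(cm) - 2 * log(c0) + log(cp)
    if (!is.finite(den) || den >= 0) 0 else {
      max(-0.5, min(0.5, 0.5 * (log(cm) - log(cp)) / den))
    }
  }
  m <- nrow(sub)
  dy <- lags[pk[1]]
  dx <- lags[pk[2]]
  sy <- if (pk[1] > 1 && pk[1] < m) {
    gauss3(sub[pk[1] - 1, pk[2]], sub[pk[1], pk[2]], sub[pk[1] + 1, pk[2]])
  } else 0
  sx <- if (pk[2] > 1 && pk[2] < m) {
    gauss3(sub[pk[1], pk[2] - 1], sub[pk[1], pk[2]], sub[pk[1], pk[2] + 1])
  } else 0
  c(dy + sy, dx + sx)
}

# Westerweel-Scarano normalized median test on one displacement component.
normalized_median_ok <- function(d, threshold, eps = 0.1) {
  nr <- nrow(d); nc <- ncol(d)
  ok <- matrix(TRUE, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!is.finite(d[r, cc])) next
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cc - 1):min(nc, cc + 1)
      nb <- d[rs, cs]
      nb[rs == r, cs == cc] <- NA # drop self
      nb <- nb[is.finite(nb)]
      if (length(nb) < 3) next
      med <- stats::median(nb)
      resid <- stats::median(abs(nb - med))
      ok[r, cc] <- abs(d[r, cc] - med) / (resid + eps) <= threshold
    }
  }
  ok
}

#' Velocity magnitude distribution at a time point
#'
#' Gaussian-kernel density estimate over the valid vector magnitudes of
#' the field nearest to `at_time_s` (normal-reference bandwidth). With
#' `at_time_s = NULL`, magnitudes of all fields are pooled.
#'
#' @param fields Output of [piv()].
#' @param at_time_s Requested frame time (s, relative to t0), or `NULL`.
#' @return A data frame `speed_um_s, density`; integrates to 1.
#' @export
velocity_distribution <- function(fields, at_time_s = NULL) {
  mags <- if (is.null(at_time_s)) {
    unlist(lapply(fields, field_speeds))
  } else {
    tt <- vapply(fields, attr, numeric(1), "time_s")
    field_speeds(fields[[which.min(abs(tt - at_time_s))]])
  }
  mags <- mags[is.finite(mags)]
  if (length(mags) < 2) stop("not enough valid vectors", call. = FALSE)
  bw <- stats::bw.nrd0(mags)
  d <- stats::density(mags, bw = bw, n = 512)
  dx <- diff(d$x)[1]
  data.frame(speed_um_s = d$x, density = d$y / (sum(d$y) * dx))
}

field_speeds <- function(vf) {
  with(vf[vf$valid, ], sqrt(u_um_s^2 + v_um_s^2))
}

#' Three-way contraction classification
#'
#' Applies a quantitative decision rule to the qualitative three-state
#' phenomenology of actomyosin reorganization. Evidence computed:
#' * `dip_depth`: `max(early lag-1 r) - min(lag-1 r)` - how strongly the
#'   network decorrelates during remodeling;
#' * `recovery`: `final lag-1 r - min(lag-1 r)` - whether a new static
#'   (contracted) arrangement is reached;
#' * `high_speed_weight`: fraction of early-frame speeds above the 90th
#'   percentile of pooled late-frame speeds;
#' * `contracting_fraction`: fraction of the valid early-field grid in
#'   measurably converging flow - speed above a floor set by the late
#'   (static) fields and divergence below minus a floor set by the late
#'   fields' divergence noise, so spatially uniform apparent flow (e.g.
#'   registration residue) does not count as contraction.
#'
#' Label `contracting` requires `dip_depth >= d1`, `recovery >= d2` and
#' `contracting_fraction >= f_hi`; `noncontracting` requires
#' `dip_depth < d1` and `high_speed_weight < w0`; anything else is
#' `partially_contracting`. "Early" means the first `n_edge` analyzed
#' lags after t0, "late" the last `n_edge`.
#'
#' @param lag1 A lag-1 `correlation_trace`.
#' @param cross The cross-channel trace (recorded as evidence; the rule
#'   itself uses the lag-1 trace and the fields).
#' @param fields [piv()] output for the same registered series.
#' @param d1,d2,w0,f_hi Decision thresholds.
#' @param n_edge Number of early/late frames.
#' @param speed_floor_quantile Quantile of the pooled late-frame speeds
#'   used as the moving/static floor in the contracting-area evidence
#'   (late frames are the static reference).
#' @return A `contraction_call`: `label` and the `evidence` list.
#' @export
classify_contraction <- function(lag1, cross, fields,
                                 d1 = 0.05, d2 = 0.03, w0 = 0.2,
                                 f_hi = 0.5, n_edge = 3L,
                                 speed_floor_quantile = 0.9) {
  if (length(lag1$values) < 5L) {
    stop("insufficient data: need >= 5 lag-1 values", call. = FALSE)
  }
  r <- lag1$values
  early_idx <- seq_len(min(n_edge, length(r)))
  late_idx <- seq(max(1L, length(r) - n_edge + 1L), length(r))
  dip_depth <- max(r[early_idx]) - min(r)
  recovery <- r[length(r)] - min(r)

  nf <- length(fields)
  fe <- fields[seq_len(min(n_edge, nf))]
  fl <- fields[seq(max(1L, nf - n_edge + 1L), nf)]
  early_speeds <- unlist(lapply(fe, field_speeds))
  late_speeds <- unlist(lapply(fl, field_speeds))
  hsw <- if (length(early_speeds) && length(late_speeds)) {
    mean(early_speeds > stats::quantile(late_speeds, 0.9))
  } else 0
  floor_speed <- if (length(late_speeds)) {
    stats::quantile(late_speeds, speed_floor_quantile, names = FALSE)
  } else 0
  late_div <- unlist(lapply(fl, function(vf) {
    g <- field_div_grid(vf)
    abs(g$divv[g$ok])
  }))
  div_floor <- if (length(late_div)) {
    stats::quantile(late_div, speed_floor_quantile, names = FALSE)
  } else 0
  cf <- mean(vapply(fe, contracting_fraction, numeric(1),
                    floor_speed = floor_speed, div_floor = div_floor))

  label <- if (dip_depth >= d1 && recovery >= d2 && cf >= f_hi) {
    "contracting"
  } else if (dip_depth < d1 && hsw < w0) {
    "noncontracting"
  } else {
    "partially_contracting"
  }
  structure(
    list(label = label,
         evidence = list(dip_depth = dip_depth, recovery = recovery,
                         high_speed_weight = hsw,
                         contracting_fraction = cf,
                         cross_channel_gain = if (length(cross$values) > 1) {
                           cross$values[length(cross$values)] - cross$values[1]
                         } else NA_real_,
                         thresholds = c(d1 = d1, d2 = d2, w0 = w0,
                                        f_hi = f_hi))),
    class = "contraction_call"
  )
}

# Velocity divergence, speed and validity on the regular PIV grid.
field_div_grid <- function(vf) {
  xs <- sort(unique(vf$x_um)); ys <- sort(unique(vf$y_um))
  if (length(xs) < 3 || length(ys) < 3) return(NULL)
  u <- matrix(vf$u_um_s, length(ys), length(xs))
  v <- matrix(vf$v_um_s, length(ys), length(xs))
  ok <- matrix(vf$valid, length(ys), length(xs))
  u[!ok] <- 0; v[!ok] <- 0
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  dudx <- (u[, c(2:length(xs), length(xs))] -
             u[, c(1, 1:(length(xs) - 1))]) / (2 * dx)
  dvdy <- (v[c(2:length(ys), length(ys)), ] -
             v[c(1, 1:(length(ys) - 1)), ]) / (2 * dy)
  list(divv = dudx + dvdy, spd = sqrt(u^2 + v^2), ok = ok)
}

# Fraction of valid grid points in measurably converging flow.
contracting_fraction <- function(vf, floor_speed, div_floor = 0) {
  g <- field_div_grid(vf)
  if (is.null(g)) return(0)
  mean(g$divv[g$ok] < -div_floor & g$spd[g$ok] > floor_speed)
}

#' @export
print.contraction_call <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf(
    "<contraction_call> %s (dip %.3f, recovery %.3f, high-speed weight %.2f, contracting fraction %.2f)\n",
    x$label, ev$dip_depth, ev$recovery, ev$high_speed_weight,
    ev$contracting_fraction))
  invisible(x)
}
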