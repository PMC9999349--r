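#' Orientation field of a micrograph
#'
#' Estimates one dominant fiber orientation per non-overlapping
#' `window_px` x `window_px` tile from the window's structure tensor: the
#' Gaussian-smoothed outer product of the intensity gradients. The reported
#' angle is the direction of least gradient variance (the ridge direction),
#' pi-periodic in `[0, pi)`; coherence is the normalized eigenvalue
#' anisotropy of the tensor. Windows whose mean gradient energy falls below
#' `energy_floor` times the median window energy are marked invalid
#' (background tiles would otherwise contribute noise orientations).
#'
#' @param img A [micrograph()].
#' @param window_px Tile edge length in pixels (>= 4).
#' @param grad_sigma_px Gaussian derivative scale for the gradients;
#'   defaults to `window_px / 4`.
#' @param energy_floor Invalid-window threshold relative to the median
#'   window gradient energy.
#' @param coherence_floor Minimum eigenvalue anisotropy for a window to
#'   carry a meaningful orientation; windows mixing several directions
#'   (filament ends, crossings) fall below it.
#' @return An `orientation_field`: `angles` (radians in `[0, pi)`),
#'   `coherence` in `[0, 1]`, `valid`, `window_px`, `pixel_size_um`.
#' @export
orientation_field <- function(img, window_px = 16L, grad_sigma_px = NULL,
                              energy_floor = 0.05, coherence_floor = 0.3) {
  stopifnot(inherits(img, "micrograph"))
  window_px <- as.integer(window_px)
  if (window_px < 4L) stop("`window_px` must be >= 4", call. = FALSE)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (window_px > min(nr, nc)) {
    stop("window larger than image", call. = FALSE)
  }
  if (is.null(grad_sigma_px)) grad_sigma_px <- window_px / 4
  g0 <- gauss_kernel(grad_sigma_px, 0L)
  g1 <- gauss_kernel(grad_sigma_px, 1L)
  gx <- conv_sep(img$pixels, g1, g0)
  gy <- conv_sep(img$pixels, g0, g1)
  # gradients within reach of the border are contaminated by the padding;
  # drop them so border windows rely on interior support only
  b <- min(ceiling(2 * grad_sigma_px), floor(min(nr, nc) / 4))
  if (b > 0) {
    gx[c(seq_len(b), nr - seq_len(b) + 1L), ] <- 0
    gx[, c(seq_len(b), nc - seq_len(b) + 1L)] <- 0
    gy[c(seq_len(b), nr - seq_len(b) + 1L), ] <- 0
    gy[, c(seq_len(b), nc - seq_len(b) + 1L)] <- 0
  }
  jxx <- tile_mean(gx * gx, window_px)
  jyy <- tile_mean(gy * gy, window_px)
  jxy <- tile_mean(gx * gy, window_px)
  # dominant gradient direction; the ridge runs perpendicular to it
  ang_grad <- 0.5 * atan2(2 * jxy, jxx - jyy)
  angles <- wrap_pi(ang_grad + pi / 2)
  lam_diff <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  energy <- jxx + jyy
  coherence <- ifelse(energy > 0, lam_diff / energy, 0)
  # the absolute term guards against accumulated float residue on
  # structure-free (constant) images
  valid <- energy > 1e-12 * mean(img$pixels^2) &
    energy >= energy_floor * stats::median(energy) &
    coherence >= coherence_floor
  structure(
    list(angles = angles, coherence = coherence, valid = valid,
         window_px = window_px, pixel_size_um = img$pixel_size_um),
    class = "orientation_field"
  )
}

# Per-tile mean over non-overlapping w x w tiles (partial border tiles
# included), shape ceiling(dim / w).
tile_mean <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ceiling(seq_len(nr) / w)
  ci <- ceiling(seq_len(nc) / w)
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri), tabulate(ci))
  sums / cnt
}

#' Build an orientation field from bare angles
#'
#' Wraps a matrix of per-window angles (radians) into an
#' `orientation_field`, e.g. for analytically constructed fields.
#'
#' @param angles Numeric matrix of angles; wrapped to `[0, pi)`.
#' @param valid Logical matrix (default all valid).
#' @param window_px Nominal window size.
#' @param pixel_size_um Nominal pixel size.
#' @return An `orientation_field`.
#' @export
orientation_field_from_angles <- function(angles, valid = NULL,
                                          window_px = 16L,
                                          pixel_size_um = 0.1) {
  angles <- wrap_pi(as.matrix(angles))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(angles), ncol(angles))
  structure(
    list(angles = angles, coherence = matrix(1, nrow(angles), ncol(angles)),
         valid = valid, window_px = as.integer(window_px),
         pixel_size_um = pixel_size_um),
    class = "orientation_field"
  )
}

#' Local nematic order parameter map
#'
#' For every window, the orientations of the valid windows inside a
#' `kernel` x `kernel` block of adjacent windows are reduced to the scalar
#' nematic order parameter `q = 2<cos^2 theta - 1/2>`, with `theta` taken
#' relative to the local director (principal axis of the mean nematic
#' tensor). Two estimators are provided. `"pairwise"` (default) is the
#' unbiased U-statistic `mean over pairs i != j of cos 2(theta_i -
#' theta_j)`, algebraically `(n^2 R^2 - n) / (n (n - 1))` with `R` the
#' resultant length of the doubled angles: it is exactly 1 for a perfectly
#' aligned kernel, has expectation exactly 0 under isotropy, and can dip
#' slightly negative (at most `-1/(n-1)`). `"pooled"` is the plug-in
#' director-projected mean (equal to `R` itself): non-negative, but with a
#' positive `O(n^-1/2)` sampling floor on disordered fields. Windows with
#' fewer than `min_valid` valid kernel members are undefined (`NA`) and
#' excluded from [q_mean()].
#'
#' @param field An `orientation_field`.
#' @param kernel Odd kernel size >= 3 (in windows).
#' @param estimator `"pairwise"` or `"pooled"`.
#' @param min_valid Minimum valid kernel members for a defined q.
#' @return A `q_map`: matrix `q` in `[-1, 1]` (NA where undefined) plus
#'   `kernel`.
#' @export
local_q <- function(field, kernel = 5L, estimator = c("pairwise", "pooled"),
                    min_valid = 3L) {
  stopifnot(inherits(field, "orientation_field"))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) {
    stop("`kernel` must be an odd integer >= 3", call. = FALSE)
  }
  estimator <- match.arg(estimator)
  v <- field$valid
  c2 <- ifelse(v, cos(2 * field$angles), 0)
  s2 <- ifelse(v, sin(2 * field$angles), 0)
  n_k <- box_sum(v + 0, kernel)
  c_k <- box_sum(c2, kernel)
  s_k <- box_sum(s2, kernel)
  q <- matrix(NA_real_, nrow(v), ncol(v))
  r2 <- c_k^2 + s_k^2 # (n R)^2
  if (estimator == "pooled") {
    ok <- n_k >= min_valid
    q[ok] <- sqrt(r2[ok]) / n_k[ok]
  } else {
    ok <- n_k >= max(min_valid, 2L)
    q[ok] <- (r2[ok] - n_k[ok]) / (n_k[ok] * (n_k[ok] - 1))
  }
  structure(list(q = q, kernel = kernel, estimator = estimator),
            class = "q_map")
}

#' @export
print.q_map <- function(x, ...) {
  cat(sprintf("<q_map> %d x %d windows, kernel %d, q_mean = %.4f\n",
              nrow(x$q), ncol(x$q), x$kernel, q_mean(x)))
  invisible(x)
}

#' Mean nematic order parameter
#'
#' Arithmetic mean of the defined local q values. With
#' `include_undefined = TRUE`, undefined (background) windows enter as 0.
#'
#' @param qmap A `q_map` from [local_q()].
#' @param include_undefined Count undefined windows as 0?
#' @return Scalar mean order parameter.
#' @export
q_mean <- function(qmap, include_undefined = FALSE) {
  q <- qmap$q
  if (!any(is.finite(q))) stop("no defined q windows", call. = FALSE)
  if (include_undefined) q[!is.finite(q)] <- 0
  mean(q, na.rm = TRUE)
}

#' Window-size sweep of the mean order parameter
#'
#' Computes `q_mean` over a range of window sizes and selects an operating
#' size by a plateau rule: the smallest window inside `select_band_um`
#' where the absolute change of `q_mean` per step falls below
#' `plateau_tol`; if none qualifies, the band midpoint-nearest size is
#' used.
#'
#' @param img A [micrograph()].
#' @param window_sizes_um Window sizes to evaluate (um).
#' @param kernel Kernel for [local_q()].
#' @param select_band_um Allowed band for the selected size (um).
#' @param plateau_tol Plateau threshold on `|dq_mean|` per step.
#' @param ... Passed to [orientation_field()].
#' @return A data frame `window_um, window_px, q_mean` with attribute
#'   `selected_um`.
#' @export
window_sweep <- function(img, window_sizes_um = seq(0.5, 3, by = 0.25),
                         kernel = 5L, select_band_um = c(1, 2),
                         plateau_tol = 0.02, ...) {
  stopifnot(inherits(img, "micrograph"))
  px <- pmax(4L, as.integer(round(window_sizes_um / img$pixel_size_um)))
  qm <- vapply(px, function(w) {
    q_mean(local_q(orientation_field(img, w, ...), kernel))
  }, numeric(1))
  out <- data.frame(window_um = window_sizes_um, window_px = px, q_mean = qm)
  dq <- c(NA, abs(diff(qm)))
  in_band <- window_sizes_um >= select_band_um[1] &
    window_sizes_um <= select_band_um[2]
  cand <- which(in_band & !is.na(dq) & dq < plateau_tol)
  selected <- if (length(cand)) {
    window_sizes_um[cand[1]]
  } else {
    window_sizes_um[in_band][which.min(abs(window_sizes_um[in_band] -
                                             mean(select_band_um)))]
  }
  attr(out, "selected_um") <- selected
  out
}
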