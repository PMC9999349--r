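#' Generate a FRAP recovery trace for a uniform disc bleach
#'
#' Simulates the mean fluorescence inside a circular bleach spot after an
#' instantaneous uniform-disc bleach in a 2D membrane, with free diffusion
#' of the mobile pool. The diffusion solution is computed exactly in time on
#' a fine periodic grid (heat-kernel multiplication in Fourier space); the
#' domain is sized well beyond both the bleach spot and the diffusion length
#' so periodic images never reach the spot. The trace is normalized so the
#' pre-bleach level is 1; the recovery plateau is
#' `1 - immobile_fraction * bleach_depth`.
#'
#' @param D_um2_per_s Diffusion coefficient of the mobile pool (um^2/s).
#' @param bleach_radius_um Bleach spot radius (um).
#' @param immobile_fraction Fraction of fluorophores that never recover,
#'   in `[0, 1]`.
#' @param frame_time_s Sampling interval (s).
#' @param n_frames Number of post-bleach frames.
#' @param noise_sd SD of additive Gaussian measurement noise.
#' @param bleach_depth Fraction of the spot intensity removed by the pulse.
#' @param n_prebleach Pre-bleach frames recorded at level 1.
#' @param grid_n Grid points per axis of the diffusion solver.
#' @param seed Seed for the noise draws.
#' @return A `frap_trace`: `times_s` (0 at the bleach), `spot_intensity`,
#'   `bleach_radius_um`, `bleach_index` (first post-bleach sample).
#' @export
generate_frap_trace <- function(D_um2_per_s, bleach_radius_um,
                                immobile_fraction = 0,
                                frame_time_s = 0.5, n_frames = 120L,
                                noise_sd = 0, bleach_depth = 0.9,
                                n_prebleach = 5L, grid_n = 256L,
                                seed = NULL) {
  check_positive_scalar(D_um2_per_s, "D_um2_per_s")
  check_positive_scalar(bleach_radius_um, "bleach_radius_um")
  check_fraction(immobile_fraction, "immobile_fraction")
  check_positive_scalar(frame_time_s, "frame_time_s")
  check_fraction(bleach_depth, "bleach_depth")
  t_post <- (seq_len(n_frames) - 1L) * frame_time_s
  t_max <- max(t_post)
  L <- max(12 * bleach_radius_um, 6 * sqrt(4 * D_um2_per_s * t_max) +
             4 * bleach_radius_um)
  n <- as.integer(grid_n)
  dx <- L / n
  ax <- (seq_len(n) - 1L) * dx - L / 2
  r2 <- outer(ax^2, ax^2, `+`)
  spot <- r2 <= bleach_radius_um^2
  u0 <- matrix(1, n, n)
  u0[spot] <- 1 - bleach_depth
  u0_hat <- stats::fft(u0 - 1) # diffuse the deviation from the far field
  kf <- c(0:(n %/% 2), -((n - (n %/% 2 + 1L)):1)) / L
  k2 <- outer((2 * pi * kf)^2, (2 * pi * kf)^2, `+`)
  spot_mean <- vapply(t_post, function(t) {
    if (t == 0) return(mean(u0[spot]))
    ut <- Re(stats::fft(u0_hat * exp(-D_um2_per_s * t * k2),
                        inverse = TRUE)) / n^2 + 1
    mean(ut[spot])
  }, numeric(1))
  # immobile pool keeps its bleached profile; mobile pool recovers
  post <- immobile_fraction * mean(u0[spot]) +
    (1 - immobile_fraction) * spot_mean
  vals <- c(rep(1, n_prebleach), post)
  times <- c(-(n_prebleach:1) * frame_time_s, t_post)
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals + rnorm(length(vals), 0, noise_sd))
  }
  structure(
    list(times_s = times, spot_intensity = vals,
         bleach_radius_um = bleach_radius_um,
         bleach_index = n_prebleach + 1L),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d samples, bleach radius %.3g um, post-bleach min %.3f\n",
              length(x$times_s), x$bleach_radius_um,
              min(x$spot_intensity[x$bleach_index:length(x$spot_intensity)])))
  invisible(x)
}

#' Generate a stepwise optical-thickness (binding) trace
#'
#' Emulates a reflectometric-interference binding experiment: the change in
#' optical thickness is piecewise constant over the given step levels, plus
#' Gaussian readout noise.
#'
#' @param step_levels Two-column matrix or data frame: `duration_s`,
#'   `dOT_nm` per level.
#' @param noise_sd SD of the additive Gaussian noise (nm).
#' @param sample_rate_hz Samples per second.
#' @param seed Seed for the noise draws.
#' @return A `rifs_trace` with `times_s` and `dOT_nm`.
#' @export
generate_rifs_trace <- function(step_levels, noise_sd = 0,
                                sample_rate_hz = 1, seed = NULL) {
  step_levels <- as.data.frame(step_levels)
  names(step_levels)[1:2] <- c("duration_s", "dOT_nm")
  if (any(step_levels$duration_s <= 0)) {
    stop("step durations must be positive", call. = FALSE)
  }
  n_per <- round(step_levels$duration_s * sample_rate_hz)
  vals <- rep(step_levels$dOT_nm, n_per)
  times <- seq_along(vals) / sample_rate_hz
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals + rnorm(length(vals), 0, noise_sd))
  }
  structure(list(times_s = times, dOT_nm = vals), class = "rifs_trace")
}
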