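#' Convert an optical-thickness change to physical layer thickness
#'
#' A reflectometric-interference measurement reports the optical thickness
#' change `dOT = n * d` of an adsorbing layer; dividing by the protein
#' refractive index gives the physical thickness `d = dOT / n_prot`.
#'
#' @param dOT_nm Optical thickness change (nm), >= 0.
#' @param n_prot Protein layer refractive index (> 1); 1.455 is the
#'   standard value for dense protein films.
#' @return Physical thickness in nm.
#' @export
ot_to_thickness <- function(dOT_nm, n_prot = 1.455) {
  if (!is.numeric(n_prot) || length(n_prot) != 1L || !is.finite(n_prot) ||
      n_prot <= 1) {
    stop("`n_prot` must be > 1", call. = FALSE)
  }
  if (any(dOT_nm < 0)) stop("`dOT_nm` must be >= 0", call. = FALSE)
  dOT_nm / n_prot
}

#' Binding-step amplitude of an optical-thickness trace
#'
#' Median plateau level minus median baseline level, robust to the
#' Gaussian readout noise of the interferometer.
#'
#' @param trace A `rifs_trace` (or list with `times_s`, `dOT_nm`).
#' @param baseline_window,plateau_window Two-element time windows (s);
#'   must be disjoint and contain >= 5 samples each.
#' @return Step amplitude in nm.
#' @export
binding_amplitude <- function(trace, baseline_window, plateau_window) {
  in_win <- function(w) trace$times_s >= w[1] & trace$times_s <= w[2]
  if (max(baseline_window[1], plateau_window[1]) <=
      min(baseline_window[2], plateau_window[2])) {
    stop("windows must be disjoint", call. = FALSE)
  }
  ib <- in_win(baseline_window); ip <- in_win(plateau_window)
  if (sum(ib) < 5 || sum(ip) < 5) {
    stop("each window needs >= 5 samples", call. = FALSE)
  }
  stats::median(trace$dOT_nm[ip]) - stats::median(trace$dOT_nm[ib])
}

# Fractional recovery after a uniform-disc bleach in a 2D membrane
# (closed-form Bessel expression; tau = r^2 / (4 D)). 0 at t = 0,
# approaching 1 as t >> tau. Exponentially scaled Bessel functions keep
# the expression stable for t -> 0.
disc_recovery <- function(t, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau / t[pos]
  out[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  out
}

#' Fit a FRAP trace for diffusion coefficient and immobile fraction
#'
#' Least-squares fit (Levenberg-Marquardt) of the post-bleach spot mean to
#' the uniform-disc 2D diffusion recovery model
#' `F(t) = 1 - depth * (1 - (1 - alpha) * f(t / tau))`, where `f` is the
#' closed-form disc recovery, `tau = r^2 / (4 D)` the characteristic
#' diffusion time, `alpha` the immobile fraction and `depth` the bleach
#' depth. The trace must be normalized to a pre-bleach level of 1 and
#' already corrected for acquisition bleaching of the whole field.
#'
#' @param trace A `frap_trace`.
#' @return List: `D_um2_per_s`, `immobile_fraction`, `bleach_depth`,
#'   `tau_s`, `converged`, `identifiable` (FALSE when there is no
#'   measurable recovery, in which case D is `NA` and the immobile
#'   fraction 1), and the `fit` object.
#' @export
fit_frap <- function(trace) {
  stopifnot(!is.null(trace$times_s), !is.null(trace$spot_intensity),
            !is.null(trace$bleach_radius_um), !is.null(trace$bleach_index))
  post <- trace$bleach_index:length(trace$times_s)
  if (length(post) < 20) stop("need >= 20 post-bleach samples", call. = FALSE)
  t <- trace$times_s[post] - trace$times_s[trace$bleach_index]
  y <- trace$spot_intensity[post]
  depth0 <- max(1 - y[1], 0.05)
  rec_range <- stats::median(utils::tail(y, 5)) - min(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (rec_range <= max(3 * noise, 0.01)) {
    # flat post-bleach trace: no recovery, D unidentifiable
    return(list(D_um2_per_s = NA_real_, immobile_fraction = 1,
                bleach_depth = depth0, tau_s = NA_real_,
                converged = TRUE, identifiable = FALSE, fit = NULL))
  }
  r <- trace$bleach_radius_um
  # crude tau start: time of half recovery
  half <- min(y) + rec_range / 2
  tau0 <- max(t[which(y >= half)[1]], t[2])
  fit <- try(minpack.lm::nlsLM(
    y ~ 1 - depth * (1 - (1 - alpha) * disc_recovery(t, tau)),
    start = list(depth = depth0, alpha = 0.05, tau = tau0),
    lower = c(depth = 0.01, alpha = 0, tau = 1e-4),
    upper = c(depth = 1, alpha = 1, tau = max(t) * 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("FRAP fit failed to converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  list(
    D_um2_per_s = r^2 / (4 * cf[["tau"]]),
    immobile_fraction = cf[["alpha"]],
    bleach_depth = cf[["depth"]],
    tau_s = cf[["tau"]],
    converged = TRUE,
    identifiable = TRUE,
    fit = fit
  )
}

#' Read a two-column trace CSV
#'
#' @param path CSV with columns time and value (header optional names
#'   `time_s` and a value column).
#' @param kind `"rifs"` or `"frap"`.
#' @param ... For `kind = "frap"`: `bleach_radius_um` and `bleach_index`.
#' @return A `rifs_trace` or `frap_trace`.
#' @export
read_trace_csv <- function(path, kind = c("rifs", "frap"), ...) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (kind == "rifs") {
    structure(list(times_s = df[[1]], dOT_nm = df[[2]]), class = "rifs_trace")
  } else {
    extra <- list(...)
    structure(list(times_s = df[[1]], spot_intensity = df[[2]],
                   bleach_radius_um = extra$bleach_radius_um,
                   bleach_index = extra$bleach_index %||%
                     (which(df[[1]] >= 0)[1])),
              class = "frap_trace")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
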