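#' Micrograph container
#'
#' A `micrograph` is a 2D intensity image together with its physical pixel
#' size and a channel tag. Pixel `[r, c]` sits at physical position
#' `x = (c - 1) * pixel_size_um`, `y = (r - 1) * pixel_size_um`, with the
#' origin at the top-left pixel center, x rightward, y downward, and angles
#' measured from the +x axis in radians.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Positive scalar, physical pixel edge length in
#'   micrometers.
#' @param channel Channel tag, one of `"actin"`, `"myosin"`, `"membrane"`,
#'   `"other"`.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_um, channel = "actin") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || !all(is.finite(pixels))) {
    stop("`pixels` must be a finite numeric matrix", call. = FALSE)
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  channel <- match.arg(channel, c("actin", "myosin", "membrane", "other"))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, channel = channel),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph> %d x %d px, %.4g um/px, channel = %s, range [%.3g, %.3g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Time series of micrographs
#'
#' A single-channel image stack with a uniform frame interval. `t0_index`
#' marks the frame taken as t = 0 (for actomyosin series, the frame of
#' initial myosin binding); times reported by trace functions are relative
#' to it.
#'
#' @param frames 3D numeric array `[rows, cols, n_frames]`, or a list of
#'   equally sized matrices.
#' @param pixel_size_um Positive scalar, micrometers per pixel.
#' @param frame_interval_s Positive scalar, seconds between frames.
#' @param t0_index Integer index of the reference frame (default 1).
#' @param channel Channel tag as for [micrograph()].
#' @return An object of class `macnet_series`.
#' @export
image_series <- function(frames, pixel_size_um, frame_interval_s,
                         t0_index = 1L, channel = "actin") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
      stop("all frames must share one geometry", call. = FALSE)
    }
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3)
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  t0_index <- as.integer(t0_index)
  channel <- match.arg(channel, c("actin", "myosin", "membrane", "other"))
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, t0_index = t0_index,
         channel = channel),
    class = "macnet_series"
  )
}

#' @export
print.macnet_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<macnet_series> %d frames of %d x %d px, dt = %.3g s, t0 at frame %d, channel = %s\n",
    d[3], d[1], d[2], x$frame_interval_s, x$t0_index, x$channel
  ))
  invisible(x)
}

#' Number of frames in a series
#' @param ts A `macnet_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(ts) dim(ts$frames)[3]

#' Extract one frame of a series as a micrograph
#' @param ts A `macnet_series`.
#' @param i Frame index.
#' @return A [micrograph()].
#' @export
series_frame <- function(ts, i) {
  micrograph(ts$frames[, , i], ts$pixel_size_um, ts$channel)
}

#' Frame times relative to t0
#' @param ts A `macnet_series`.
#' @return Numeric vector of times in seconds, one per frame.
#' @export
series_times <- function(ts) {
  (seq_len(n_frames(ts)) - ts$t0_index) * ts$frame_interval_s
}

#' Read a TIFF file as a micrograph or series
#'
#' Single-page TIFFs become a [micrograph()]; multi-page stacks become a
#' [image_series()] (one page per frame). Multi-sample (RGB) pages are
#' averaged to one intensity plane.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Micrometers per pixel (TIFF tags are not trusted).
#' @param frame_interval_s Seconds per frame, required for stacks.
#' @param channel Channel tag.
#' @param t0_index Reference frame for stacks.
#' @return A `micrograph` or `macnet_series`.
#' @export
read_micrograph <- function(path, pixel_size_um, frame_interval_s = NULL,
                            channel = "actin", t0_index = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  flat <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) rowMeans(p, dims = 2) else p
  })
  if (length(flat) == 1L) {
    micrograph(flat[[1]], pixel_size_um, channel)
  } else {
    if (is.null(frame_interval_s)) {
      stop("`frame_interval_s` is required for a multi-page stack", call. = FALSE)
    }
    image_series(flat, pixel_size_um, frame_interval_s, t0_index, channel)
  }
}

#' Write a micrograph or series to TIFF
#'
#' Intensities are rescaled to `[0, 1]` over the whole object (TIFF stores
#' normalized floats); geometry metadata is not embedded.
#'
#' @param x A `micrograph` or `macnet_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(x, path) {
  rescale <- function(m, lo, hi) {
    if (hi > lo) (m - lo) / (hi - lo) else m * 0
  }
  if (inherits(x, "micrograph")) {
    tiff::writeTIFF(rescale(x$pixels, min(x$pixels), max(x$pixels)), path,
                    bits.per.sample = 16)
  } else if (inherits(x, "macnet_series")) {
    lo <- min(x$frames); hi <- max(x$frames)
    pages <- lapply(seq_len(n_frames(x)), function(i) {
      rescale(x$frames[, , i], lo, hi)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    stop("`x` must be a micrograph or macnet_series", call. = FALSE)
  }
  invisible(path)
}
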