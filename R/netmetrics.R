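#' Skeleton network density
#'
#' Fraction of image pixels occupied by the skeleton (filamentous pixels
#' over all pixels).
#'
#' @param skel A `skeleton_image`.
#' @return Scalar in `[0, 1]`.
#' @export
skeleton_density <- function(skel) {
  stopifnot(inherits(skel, "skeleton_image"))
  mean(skel$mask)
}

count_neighbors8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- out + p[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx)]
  }
  out
}

# 8-connected component labels of a logical matrix (two-pass via repeated
# label propagation; skeleton node clusters are tiny, so this converges in
# a few sweeps).
label_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[m] <- seq_len(sum(m))
  repeat {
    p <- matrix(0L, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- lab
    nb <- matrix(.Machine$integer.max, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      s <- p[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx)]
      s[s == 0L] <- .Machine$integer.max
      nb <- pmin(nb, s)
    }
    new_lab <- lab
    new_lab[m] <- nb[m]
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

#' Detect skeleton nodes (filament intersections)
#'
#' A node pixel is a skeleton pixel with more than two foreground
#' 8-neighbors. Adjacent node pixels are merged into one intersection per
#' 8-connected cluster (cluster centroid), since an X-crossing typically
#' flags several touching pixels; clusters closer than `merge_radius_px`
#' are then fused, because thinning splits a single X-crossing into two
#' Y-junctions about one ridge width apart. Nodes within `border_px` of
#' the image border are discarded (thinning artifacts accumulate at
#' edges).
#'
#' @param skel A `skeleton_image` (thinned; a warning is issued if any
#'   2 x 2 block is fully foreground).
#' @param border_px Border exclusion margin in pixels.
#' @param merge_radius_px Fuse merged intersections closer than this
#'   (in px; 0 disables).
#' @return A `node_set`: `node_pixel_coords` and `merged_node_coords`
#'   (matrices of `row, col` pixel positions, centroids fractional), plus
#'   counts `node_pixel_count` and `node_count`.
#' @export
detect_nodes <- function(skel, border_px = 2L, merge_radius_px = 4) {
  stopifnot(inherits(skel, "skeleton_image"))
  m <- skel$mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr > 1 && nc > 1 && any(m)) {
    blk <- m[-nr, -nc] & m[-1, -nc] & m[-nr, -1] & m[-1, -1]
    # isolated locked blocks occur in dense junction tangles; warn only
    # when solid blocks are pervasive, the signature of unthinned input
    if (sum(blk) > 0.01 * sum(m)) {
      warning("skeleton does not look thinned (2x2 foreground blocks)")
    }
  }
  nodes <- m & count_neighbors8(m) > 2L
  if (border_px > 0) {
    keep <- matrix(FALSE, nr, nc)
    rr <- (border_px + 1L):(nr - border_px)
    cc <- (border_px + 1L):(nc - border_px)
    if (length(rr) > 0 && length(cc) > 0) keep[rr, cc] <- TRUE
    nodes <- nodes & keep
  }
  pix <- which(nodes, arr.ind = TRUE)
  lab <- label_components8(nodes)
  merged <- if (nrow(pix) > 0) {
    l <- lab[nodes]
    cbind(row = tapply(pix[, 1], l, mean), col = tapply(pix[, 2], l, mean))
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (merge_radius_px > 0 && nrow(merged) > 1) {
    merged <- fuse_close_points(merged, merge_radius_px)
  }
  structure(
    list(node_pixel_coords = unname(pix), merged_node_coords = unname(merged),
         node_pixel_count = nrow(pix), node_count = nrow(merged)),
    class = "node_set"
  )
}

# Single-linkage fusion of points closer than radius; fused points are
# replaced by their centroid.
fuse_close_points <- function(pts, radius) {
  h <- stats::hclust(stats::dist(pts), method = "single")
  grp <- stats::cutree(h, h = radius)
  out <- cbind(row = tapply(pts[, 1], grp, mean),
               col = tapply(pts[, 2], grp, mean))
  unname(out)
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> %d node pixels in %d merged intersections\n",
              x$node_pixel_count, x$node_count))
  invisible(x)
}

#' Node density per square micrometer
#'
#' Merged intersection count divided by the field area.
#'
#' @param nodes A `node_set` from [detect_nodes()].
#' @param skel The `skeleton_image` the nodes came from.
#' @return Nodes per um^2.
#' @export
node_density <- function(nodes, skel) {
  area_um2 <- prod(dim(skel$mask)) * skel$pixel_size_um^2
  nodes$node_count / area_um2
}

skeleton_mean_intensity <- function(img, skel, subtract_background = TRUE) {
  stopifnot(identical(dim(img$pixels), dim(skel$mask)))
  if (!any(skel$mask)) {
    stop("empty skeleton: bundling factor undefined", call. = FALSE)
  }
  bg <- if (subtract_background) {
    stats::median(img$pixels[!skel$mask])
  } else 0
  mean(img$pixels[skel$mask]) - bg
}

#' Relative bundling factor
#'
#' Masks the fluorescence image with its skeleton, averages the
#' (optionally background-subtracted) intensity over skeleton pixels, and
#' normalizes by the mean skeleton intensity of a designated reference
#' condition; the reference condition therefore scores 1 by construction.
#' Background is the per-image median of non-skeleton pixels.
#'
#' @param img A [micrograph()] (raw intensities, not equalized).
#' @param skel Its `skeleton_image`.
#' @param reference_mean_intensity Output of [reference_intensity()] for
#'   the reference condition.
#' @param subtract_background Subtract the non-skeleton median first?
#' @return Dimensionless positive scalar.
#' @export
bundling_factor <- function(img, skel, reference_mean_intensity,
                            subtract_background = TRUE) {
  check_positive_scalar(reference_mean_intensity, "reference_mean_intensity")
  skeleton_mean_intensity(img, skel, subtract_background) /
    reference_mean_intensity
}

#' Reference mean skeleton intensity of a condition
#'
#' Per-image mean intensity at skeleton pixels, averaged over the images
#' of the reference condition (image-level averaging first, then the
#' condition-level mean).
#'
#' @param pairs List of `list(img, skel)` pairs.
#' @param subtract_background As in [bundling_factor()].
#' @return Positive scalar.
#' @export
reference_intensity <- function(pairs, subtract_background = TRUE) {
  if (!length(pairs)) stop("`pairs` must be non-empty", call. = FALSE)
  mean(vapply(pairs, function(p) {
    skeleton_mean_intensity(p[[1]], p[[2]], subtract_background)
  }, numeric(1)))
}

#' Summary network statistics for one micrograph
#'
#' @param img A [micrograph()].
#' @param skel Its `skeleton_image`.
#' @param reference_mean_intensity Reference for the bundling factor
#'   (`NA` to skip).
#' @param subtract_background As in [bundling_factor()].
#' @return One-row data frame: `skeleton_density`, `node_pixel_count`,
#'   `node_count`, `node_density_per_um2`, `mean_skeleton_intensity`,
#'   `bundling_factor`.
#' @export
network_stats <- function(img, skel, reference_mean_intensity = NA,
                          subtract_background = TRUE) {
  nodes <- detect_nodes(skel)
  data.frame(
    skeleton_density = skeleton_density(skel),
    node_pixel_count = nodes$node_pixel_count,
    node_count = nodes$node_count,
    node_density_per_um2 = node_density(nodes, skel),
    mean_skeleton_intensity =
      skeleton_mean_intensity(img, skel, subtract_background),
    bundling_factor = if (is.na(reference_mean_intensity)) NA_real_ else
      bundling_factor(img, skel, reference_mean_intensity,
                      subtract_background)
  )
}
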