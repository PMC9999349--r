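#' Contrast-limited adaptive histogram equalization
#'
#' Equalizes local contrast with CLAHE (via EBImage) after rescaling the
#' input to `[0, 1]`. The tile grid is derived from `tile_px`; at least a
#' 2 x 2 grid is used.
#'
#' @param img A [micrograph()].
#' @param clip_limit CLAHE clip limit (> 0); large values approach plain
#'   per-tile equalization.
#' @param tile_px Tile edge length in pixels (>= 8).
#' @return A [micrograph()] with values in `[0, 1]`.
#' @export
equalize_contrast <- function(img, clip_limit = 2, tile_px = 64L) {
  stopifnot(inherits(img, "micrograph"))
  check_positive_scalar(clip_limit, "clip_limit")
  if (tile_px < 8) stop("`tile_px` must be >= 8", call. = FALSE)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (nr < tile_px || nc < tile_px) {
    stop("image smaller than one tile", call. = FALSE)
  }
  rng <- range(img$pixels)
  if (rng[2] == rng[1]) {
    # degenerate histogram: constant in, constant out
    return(micrograph(matrix(1, nr, nc), img$pixel_size_um, img$channel))
  }
  x <- (img$pixels - rng[1]) / (rng[2] - rng[1])
  nx <- max(2L, as.integer(floor(nc / tile_px)))
  ny <- max(2L, as.integer(floor(nr / tile_px)))
  # EBImage images are column-major (x, y); transpose in and out
  eq <- EBImage::clahe(EBImage::Image(t(x)), nx = nx, ny = ny,
                       limit = clip_limit)
  out <- t(EBImage::imageData(eq))
  micrograph(pmin(pmax(out, 0), 1), img$pixel_size_um, img$channel)
}

#' Hessian second-eigenvalue tube response
#'
#' Computes the 2 x 2 Hessian of the image at derivative-of-Gaussian scale
#' `sigma_px` and scores each pixel by the negated algebraically smaller
#' eigenvalue (the minimal surface curvature), clipped at zero, so that
#' bright ridge crests respond strongly and blobs/valleys do not. Border
#' pixels use reflective padding.
#'
#' @param img A [micrograph()] (or bare matrix).
#' @param sigma_px Derivative scale in pixels (>= 0.5); matched filtering
#'   peaks when this is about half the rendered filament width.
#' @return A `tube_response`: `response` matrix (>= 0) and `sigma_px`.
#' @export
hessian_tube_response <- function(img, sigma_px = 2) {
  ev <- hessian_eigenvalues(img, sigma_px)
  structure(list(response = pmax(-ev$lambda2, 0), sigma_px = sigma_px),
            class = "tube_response")
}

# Both Hessian eigenvalues at derivative-of-Gaussian scale sigma_px.
hessian_eigenvalues <- function(img, sigma_px) {
  pix <- if (inherits(img, "micrograph")) img$pixels else img
  if (sigma_px < 0.5) stop("`sigma_px` must be >= 0.5", call. = FALSE)
  g0 <- gauss_kernel(sigma_px, 0L)
  g1 <- gauss_kernel(sigma_px, 1L)
  g2 <- gauss_kernel(sigma_px, 2L)
  ixx <- conv_sep(pix, g2, g0)
  iyy <- conv_sep(pix, g0, g2)
  ixy <- conv_sep(pix, g1, g1)
  tr_half <- (ixx + iyy) / 2
  disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  list(lambda1 = tr_half + disc, lambda2 = tr_half - disc)
}

#' Adaptive threshold of a tube response
#'
#' A pixel is foreground iff its response exceeds the local
#' Gaussian-weighted mean over a `block_px` x `block_px` neighborhood by
#' more than `offset`.
#'
#' @param resp A `tube_response` (or bare matrix).
#' @param block_px Odd block size >= 3.
#' @param offset Additive offset in response units.
#' @return Logical matrix mask.
#' @export
adaptive_threshold <- function(resp, block_px = 51L, offset = 0) {
  r <- if (inherits(resp, "tube_response")) resp$response else resp
  block_px <- as.integer(block_px)
  if (block_px < 3L || block_px %% 2L == 0L) {
    stop("`block_px` must be an odd integer >= 3", call. = FALSE)
  }
  r > local_gaussian_mean(r, block_px) + offset
}

#' Topology-preserving thinning to a 1-pixel skeleton
#'
#' Two-subiteration (Zhang-Suen) thinning on the 8-connected foreground,
#' iterated to its fixed point, followed by a sequential staircase-removal
#' pass that deletes every remaining pixel whose removal neither breaks
#' 8-connectivity of its neighborhood nor shortens a branch end (Zhang-Suen
#' alone leaves 4-connected staircases on diagonals, whose corner pixels
#' would masquerade as junctions). The result is a subset of the input
#' with the same connected components, and re-thinning leaves it
#' unchanged.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Micrometers per pixel carried into the result.
#' @return A `skeleton_image`: logical `mask` plus `pixel_size_um`.
#' @export
skeletonize <- function(mask, pixel_size_um = 1) {
  m <- mask != 0
  storage.mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- thin_candidates(m, sub)
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- remove_redundant_pixels(m)
  structure(list(mask = m, pixel_size_um = pixel_size_um),
            class = "skeleton_image")
}

# Ring positions around a pixel in the order N, NE, E, SE, S, SW, W, NW,
# and which ring positions touch each other (8-adjacency between the
# neighbor cells themselves).
ring_off <- cbind(dy = c(-1, -1, 0, 1, 1, 1, 0, -1),
                  dx = c(0, 1, 1, 1, 0, -1, -1, -1))
ring_adj <- outer(seq_len(8), seq_len(8), function(i, j) {
  abs(ring_off[i, 1] - ring_off[j, 1]) <= 1 &
    abs(ring_off[i, 2] - ring_off[j, 2]) <= 1 & i != j
})

# TRUE iff the foreground neighbors of a pixel stay one 8-connected
# component without it (so the pixel is redundant for connectivity).
ring_one_component <- function(present) {
  ids <- which(present)
  if (length(ids) <= 1) return(TRUE)
  seen <- logical(8)
  stack <- ids[1]
  seen[ids[1]] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(ring_adj[cur, ] & present & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen[ids])
}

# Sequential pass deleting pixels with >= 2 neighbors whose neighborhood
# stays singly 8-connected without them; deterministic scan order.
remove_redundant_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    cand <- which(m & count_neighbors8(m) >= 2L)
    for (idx in cand) {
      if (!m[idx]) next
      r <- (idx - 1L) %% nr + 1L
      cc <- (idx - 1L) %/% nr + 1L
      rr <- r + ring_off[, 1]; ccx <- cc + ring_off[, 2]
      inb <- rr >= 1 & rr <= nr & ccx >= 1 & ccx <= nc
      present <- logical(8)
      present[inb] <- m[cbind(rr[inb], ccx[inb])]
      if (sum(present) >= 2L && ring_one_component(present)) {
        m[idx] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Deletion set of one Zhang-Suen subiteration, computed for every pixel at
# once from zero-padded neighbor shifts. Neighbor order: p2 = N, p3 = NE,
# p4 = E, p5 = SE, p6 = S, p7 = SW, p8 = W, p9 = NW (y down, x right).
thin_candidates <- function(m, sub) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dy, dx) p[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx)]
  p2 <- sh(-1L, 0L); p3 <- sh(-1L, 1L); p4 <- sh(0L, 1L); p5 <- sh(1L, 1L)
  p6 <- sh(1L, 0L); p7 <- sh(1L, -1L); p8 <- sh(0L, -1L); p9 <- sh(-1L, -1L)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  base <- m & b >= 2 & b <= 6 & a == 1
  if (sub == 1L) {
    base & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    base & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
}

# Grow each branch end along its own direction for up to max_px pixels,
# as long as the threshold mask is foreground there and the new pixel does
# not touch foreign skeleton pixels.
extend_skeleton_ends <- function(skel, mask, max_px) {
  nr <- nrow(skel); nc <- ncol(skel)
  ends <- which(skel & count_neighbors8(skel) == 1L)
  for (e in ends) {
    r <- (e - 1L) %% nr + 1L
    cc <- (e - 1L) %/% nr + 1L
    # local direction from up to 3 steps back along the branch
    prev <- c(r, cc)
    cur <- c(r, cc)
    for (k in 1:3) {
      nb <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        r2 <- cur[1] + dy; c2 <- cur[2] + dx
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && skel[r2, c2] &&
            !(r2 == prev[1] && c2 == prev[2])) {
          nb <- c(r2, c2)
        }
      }
      if (is.null(nb)) break
      prev <- cur
      cur <- nb
    }
    dir <- c(r, cc) - cur
    nd <- sqrt(sum(dir^2))
    if (nd == 0) next
    dir <- dir / nd
    pos <- c(r, cc)
    last <- c(r, cc)
    for (step in seq_len(max_px)) {
      pos <- pos + dir
      pr <- round(pos[1]); pc <- round(pos[2])
      if (pr < 1 || pr > nr || pc < 1 || pc > nc) break
      if (pr == last[1] && pc == last[2]) next
      if (!mask[pr, pc] || skel[pr, pc]) break
      # do not graft onto a foreign branch
      clash <- FALSE
      for (dy in -1:1) for (dx in -1:1) {
        r2 <- pr + dy; c2 <- pc + dx
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && skel[r2, c2] &&
            !(r2 == last[1] && c2 == last[2])) {
          clash <- TRUE
        }
      }
      if (clash) break
      skel[pr, pc] <- TRUE
      last <- c(pr, pc)
    }
  }
  skel
}

#' Prune short spurs from a skeleton
#'
#' Iteratively removes endpoint pixels (foreground pixels with at most one
#' foreground 8-neighbor), `n_px` times. Side spurs shorter than `n_px` -
#' thinning artifacts of width wobble in the threshold mask - disappear
#' entirely, together with the fake T-junctions they create; genuine
#' branches only retract by `n_px` at their free ends.
#'
#' @param skel A `skeleton_image` (or logical matrix).
#' @param n_px Number of pruning iterations.
#' @return A `skeleton_image`.
#' @export
prune_skeleton <- function(skel, n_px = 4L) {
  m <- if (inherits(skel, "skeleton_image")) skel$mask else skel
  psz <- if (inherits(skel, "skeleton_image")) skel$pixel_size_um else 1
  for (i in seq_len(n_px)) {
    ends <- m & count_neighbors8(m) <= 1L
    if (!any(ends)) break
    m[ends] <- FALSE
  }
  structure(list(mask = m, pixel_size_um = psz), class = "skeleton_image")
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> %d x %d px, %d foreground px (density %.4f)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), mean(x$mask)))
  invisible(x)
}

#' Tube-filter configuration
#'
#' Collects the stage parameters of [extract_skeleton()]. Because the
#' pipeline thresholds the tube response of a contrast-equalized image
#' (values in [0, 1]), the response scale is set by the smoothing and
#' derivative scales rather than by the camera gain, so a fixed offset is
#' meaningful across images. Set `offset = 0` to threshold on the local
#' mean alone.
#'
#' @param clip_limit,tile_px CLAHE parameters ([equalize_contrast()]).
#' @param smooth_sigma_px Gaussian pre-filter SD (px).
#' @param hessian_sigma_px Hessian derivative scale (px); about half the
#'   expected filament width.
#' @param block_px,offset Adaptive-threshold parameters.
#' @param prune_px Spur-pruning iterations applied after thinning
#'   ([prune_skeleton()]; 0 disables - spurs do not create junctions once
#'   staircases are removed, and pruning retracts genuine filament ends).
#' @param min_object_px Minimum connected-component size kept in the
#'   skeleton (default 20 px, about 2 um of filament at 0.1 um/px):
#'   isolated fragments below this cannot be told apart from the specks
#'   that camera noise leaves after equalization and thinning, so they
#'   are discarded; real filaments almost always exceed it, alone or
#'   fused into larger network components.
#' @param extend_ends_px Optionally reconstruct up to this many pixels at
#'   each branch end by following the end's direction while the threshold
#'   mask is still foreground (0 disables); recovers ends retracted by
#'   aggressive pruning at some cost in centerline precision.
#' @param close_px Structuring-element size of the morphological closing
#'   applied to the threshold mask before thinning (0 disables). Contrast
#'   equalization flattens the bright plateau where two filaments cross,
#'   which dents the tube response there and can punch a 1-2 px hole into
#'   the mask right at the junction; a small closing restores the
#'   connectivity the junction detection relies on.
#' @param equalize_first Apply CLAHE before the Gaussian pre-filter
#'   (default) or after.
#' @return A list of class `tube_cfg`.
#' @export
tube_cfg <- function(clip_limit = 2, tile_px = 64L, smooth_sigma_px = 1,
                     hessian_sigma_px = 2, block_px = 51L, offset = 0.006,
                     close_px = 3L, prune_px = 0L, min_object_px = 14L,
                     extend_ends_px = 0L, equalize_first = TRUE) {
  structure(
    list(clip_limit = clip_limit, tile_px = tile_px,
         smooth_sigma_px = smooth_sigma_px,
         hessian_sigma_px = hessian_sigma_px, block_px = block_px,
         offset = offset, close_px = as.integer(close_px),
         prune_px = as.integer(prune_px),
         min_object_px = as.integer(min_object_px),
         extend_ends_px = as.integer(extend_ends_px),
         equalize_first = equalize_first),
    class = "tube_cfg"
  )
}

#' Full tube-filter pipeline: micrograph to skeleton
#'
#' Composes contrast equalization, Gaussian smoothing, the Hessian
#' second-eigenvalue tube response, adaptive thresholding and thinning.
#' All intermediate products are attached for audit.
#'
#' @param img A [micrograph()].
#' @param cfg A [tube_cfg()].
#' @return A `skeleton_image` whose `stages` element holds the equalized
#'   image, smoothed image, tube response, threshold mask and the offset
#'   actually used.
#' @export
extract_skeleton <- function(img, cfg = tube_cfg()) {
  stopifnot(inherits(img, "micrograph"))
  if (cfg$equalize_first) {
    eq <- equalize_contrast(img, cfg$clip_limit, cfg$tile_px)
    sm <- micrograph(gaussian_smooth(eq$pixels, cfg$smooth_sigma_px),
                     img$pixel_size_um, img$channel)
  } else {
    sm0 <- micrograph(gaussian_smooth(img$pixels, cfg$smooth_sigma_px),
                      img$pixel_size_um, img$channel)
    eq <- sm0
    sm <- equalize_contrast(sm0, cfg$clip_limit, cfg$tile_px)
  }
  resp <- hessian_tube_response(sm, cfg$hessian_sigma_px)
  offset <- cfg$offset
  mask <- adaptive_threshold(resp, cfg$block_px, offset)
  if (cfg$close_px > 0) {
    brush <- EBImage::makeBrush(cfg$close_px, "box")
    mask <- t(EBImage::imageData(EBImage::closing(EBImage::Image(t(mask * 1)),
                                                  brush))) > 0
  }
  skel <- skeletonize(mask, img$pixel_size_um)
  if (cfg$prune_px > 0) skel <- prune_skeleton(skel, cfg$prune_px)
  if (cfg$min_object_px > 1 && any(skel$mask)) {
    lab <- label_components8(skel$mask)
    sizes <- tabulate(lab[skel$mask])
    small <- which(sizes < cfg$min_object_px)
    if (length(small)) skel$mask[lab %in% small] <- FALSE
  }
  if (cfg$extend_ends_px > 0) {
    skel$mask <- extend_skeleton_ends(skel$mask, mask, cfg$extend_ends_px)
  }
  skel$stages <- list(equalized = eq, smoothed = sm, response = resp,
                      mask = mask, offset = offset)
  skel
}
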