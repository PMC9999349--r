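# Separable correlation with reflective (symmetric, edge-repeating) padding.
# Kernels are 1D vectors of odd length applied along x (columns) and y
# (rows). Implemented as a sum of shifted slices of the padded matrix so it
# stays vectorized for the image sizes this package targets.

reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  pre <- pmin(r:1, n)
  post <- pmax(n - seq_len(r) + 1L, 1L)
  c(pre, seq_len(n), post)
}

conv_sep <- function(img, kx, ky) {
  nr <- nrow(img); nc <- ncol(img)
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- img[reflect_idx(nr, ry), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(ky)) {
    out <- out + ky[i] * p[i:(i + nr - 1L), , drop = FALSE]
  }
  p <- out[, reflect_idx(nc, rx), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(kx)) {
    out <- out + kx[i] * p[, i:(i + nc - 1L), drop = FALSE]
  }
  out
}

# Sampled Gaussian kernel and its first/second derivatives. The order-0
# kernel is normalized to unit sum; derivative kernels share that
# normalization so responses approximate continuous Gaussian derivatives.
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  if (sigma <= 0) {
    if (order == 0L) return(1)
    stop("derivative kernels need sigma > 0", call. = FALSE)
  }
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  # derivative kernels are re-centered to zero sum so they annihilate
  # constants exactly despite truncation
  switch(as.character(order),
    "0" = g,
    "1" = {
      k <- -x / sigma^2 * g
      k - mean(k)
    },
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - mean(k)
    },
    stop("order must be 0, 1 or 2", call. = FALSE)
  )
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gauss_kernel(sigma, 0L)
  conv_sep(img, g, g)
}

# Local Gaussian-weighted mean over a block_px x block_px support.
local_gaussian_mean <- function(img, block_px) {
  r <- (block_px - 1L) %/% 2L
  sigma <- max(block_px / 6, 0.8)
  g <- gauss_kernel(sigma, 0L, radius = r)
  conv_sep(img, g, g)
}

# Sliding sums over a k x k box on tile grids (zero padding); used by the
# nematic kernel aggregation.
box_sum <- function(m, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  out <- matrix(0, nr, nc)
  for (dy in 0:(k - 1L)) {
    out <- out + p[(1L + dy):(nr + dy), (r + 1L):(r + nc), drop = FALSE]
  }
  p2 <- matrix(0, nr + 2L * r, nc + 2L * r)
  p2[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- out
  out <- matrix(0, nr, nc)
  for (dx in 0:(k - 1L)) {
    out <- out + p2[(r + 1L):(r + nr), (1L + dx):(nc + dx), drop = FALSE]
  }
  out
}
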