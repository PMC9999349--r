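check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a non-negative finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, open_top = FALSE) {
  top_ok <- if (open_top) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || !top_ok) {
    stop(sprintf("`%s` must lie in [0, 1%s", name, if (open_top) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Sample from a von Mises law on (-pi, pi] by Best-Fisher rejection.
# kappa = 0 degenerates to the uniform circle.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) {
    return(((runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (u2 < cc * (2 - cc)) | (u2 <= cc * exp(1 - cc))
    k <- sum(ok)
    if (k > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

# Wrap angles to the nematic fundamental domain [0, pi).
wrap_pi <- function(theta) theta %% pi
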