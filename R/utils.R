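# Internal helpers shared across modules.

# round-half-up at `digits` decimals; base round() is round-half-even, which
# does not reproduce the reporting convention of the printed tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 nudge absorbs binary-representation error in exact halves
  floor(x * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All exported stochastic entry points funnel through this, so the
# package never leaves global RNG state behind.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# finite-difference Hessian of a scalar function (central differences);
# used for curvature-based confidence intervals in fit diagnostics.
fd_hessian <- function(fn, x, rel_h = 1e-4) {
  d <- length(x)
  h <- pmax(abs(x), 1) * rel_h
  H <- matrix(NA_real_, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a
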