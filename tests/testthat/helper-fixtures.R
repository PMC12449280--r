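# Shared fixtures and independent reference implementations (oracles).
# Oracles are deliberately written as naive per-element code, independent
# of the package's vectorized/compiled paths.

# Random integer-valued volume (scanner-like units; integer values keep
# float arithmetic exact under inversion round trips).
randomIntVolume <- function(shape = c(16L, 16L, 16L), lo = 0L, hi = 3000L,
                            spacing = c(1, 1, 1)) {
  Volume(array(as.double(sample(lo:hi, prod(shape), replace = TRUE)),
               shape), spacing = spacing)
}

# Naive straight-line reference for inversion with background zeroing:
# per-voxel loop applying the piecewise definition.
naiveInvertBlack <- function(x, p = 1) {
  t <- stats::quantile(x, p / 100, names = FALSE, type = 7)
  M <- max(x)
  m <- min(x)
  out <- x
  for (i in seq_along(x)) {
    out[i] <- if (x[i] <= t) 0 else M - x[i] + m
  }
  out
}

# Brute-force Dice by an explicit voxel loop.
bruteDice <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1L
    if (b[i]) nb <- nb + 1L
    if (a[i] && b[i]) inter <- inter + 1L
  }
  if (na + nb == 0L) return(NA_real_)
  2 * inter / (na + nb)
}

# Exhaustive sign-flip enumeration of the two-sided signed-rank p-value:
# all 2^n assignments of signs to the midranks of |d|.
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vall <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(Vall - mu) >= abs(V - mu) - 1e-9)
}

# Small deterministic phantom for fast tests.
smallPhantom <- function(seed = 1L, tumorVolume = 12, side = "left") {
  generatePhantom(PhantomSpec(gridShape = 64L, tumorVolume = tumorVolume,
                              tumorSide = side, seed = seed))
}

# Mask helper
asMask <- function(v) array(v != 0, dim(v))
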