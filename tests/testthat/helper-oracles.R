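# Independent brute-force oracles and toy-spectrum builders. These stay
# deliberately naive (explicit loops, two-pass formulas) and share no code
# with the package internals they check.

# Explicit two-point anchored baseline + loop over window grid points.
bruteHeights <- function(s, cfg, positions) {
  w <- wavenumbers(s)
  a <- absorbance(s)
  lin <- function(at) {
    i <- max(which(w <= at))
    if (w[i] == at) return(a[i])
    a[i] + (a[i + 1] - a[i]) * (at - w[i]) / (w[i + 1] - w[i])
  }
  aL <- lin(cfg@baselineLeft)
  aR <- lin(cfg@baselineRight)
  vapply(positions, function(pos) {
    best <- -Inf
    for (j in seq_along(w)) {
      if (w[j] < pos - cfg@apexHalfwidth || w[j] > pos + cfg@apexHalfwidth)
        next
      base <- aL + (aR - aL) * (w[j] - cfg@baselineLeft) /
        (cfg@baselineRight - cfg@baselineLeft)
      if (a[j] - base > best) best <- a[j] - base
    }
    best
  }, numeric(1))
}

# Two-pass closed-form OLS with standard errors and R^2.
bruteOLS <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  b <- sxy / sxx
  a <- ybar - b * xbar
  res <- y - (a + b * x)
  ssres <- sum(res^2)
  sstot <- sum((y - ybar)^2)
  s2 <- ssres / (n - 2)
  list(slope = b, intercept = a,
       seSlope = sqrt(s2 / sxx),
       seIntercept = sqrt(s2 * (1 / n + xbar^2 / sxx)),
       residualSd = sqrt(s2),
       rSquared = 1 - ssres / sstot)
}

# Triangular bump of given apex height, zero outside center +/- halfbase.
triangularBump <- function(w, center, height, halfbase = 6) {
  pmax(0, 1 - abs(w - center) / halfbase) * height
}

# A toy spectrum on a regular grid covering the default baseline window.
toySpectrum <- function(absorbance, from = 855, to = 912, by = 1) {
  w <- seq(from, to, by = by)
  Spectrum(w, absorbance(w))
}

# Noise-free generator settings (band overlap is then the only deviation).
noiselessConfig <- function(seed = 1L, ...) {
  generatorConfig(filmScaleSd = 0, additiveNoiseSd = 0,
                  driftSlopeRange = c(0, 0), driftOffsetRange = c(0, 0),
                  seed = seed, ...)
}
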