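cfg <- RatioConfig()

test_that("a flat background is subtracted exactly by the anchored baseline", {
  s <- toySpectrum(function(w) 0.1 + triangularBump(w, 873, 0.05))
  expect_warning(h <- correctedHeights(s, cfg), "non-detected")
  expect_equal(h$height[h$position == 873], 0.05, tolerance = 1e-12)
  expect_equal(h$height[h$position == 890], 0, tolerance = 1e-12)
  expect_false(h$detected[h$position == 890])
})

test_that("a slanted baseline is subtracted exactly (independent oracle)", {
  # absorbance rises linearly 0.0 -> 0.43 across the anchor window, plus a
  # 0.02 bump at 890; the two-point line oracle is computed by hand
  ramp <- function(w) (w - 862) * 0.43 / (905 - 862)
  s <- toySpectrum(function(w) ramp(w) + triangularBump(w, 890, 0.02))
  h <- suppressWarnings(correctedHeights(s, cfg))
  expect_equal(h$height[h$position == 890], 0.02, tolerance = 1e-10)
  expect_equal(h$height[h$position == 873], 0, tolerance = 1e-10)
})

test_that("the apex within the search window is found and reported", {
  s <- toySpectrum(function(w) 0.05 + triangularBump(w, 875, 0.03))
  h <- suppressWarnings(correctedHeights(s, cfg))
  expect_equal(h$apex[h$position == 873], 875)
  expect_equal(h$height[h$position == 873], 0.03, tolerance = 1e-12)
})

test_that("fixed mode reads at the nominal wavenumber instead of the apex", {
  s <- toySpectrum(function(w) 0.05 + triangularBump(w, 875, 0.03))
  h <- suppressWarnings(correctedHeights(s, cfg, mode = "fixed"))
  expect_equal(h$apex[h$position == 873], 873)
  # triangular bump of halfbase 6 read 2 cm-1 off apex: 0.03 * (1 - 2/6)
  expect_equal(h$height[h$position == 873], 0.03 * (1 - 2 / 6),
               tolerance = 1e-12)
})

test_that("windows and coverage preconditions are enforced", {
  short <- Spectrum(seq(870, 900, 1), rep(0.1, 31))
  expect_error(correctedHeights(short, cfg), "does not cover")
  coarse <- Spectrum(seq(850, 915, 13), rep(0.1, 6))
  expect_error(correctedHeights(coarse, cfg), "grid spacing")
})

test_that("non-detected peaks warn but are reported, and a missing
           denominator errors", {
  flat <- toySpectrum(function(w) rep(0.1, length(w)))
  expect_warning(correctedHeights(flat, cfg, positions = 873),
                 "non-detected")
  h <- suppressWarnings(correctedHeights(flat, cfg))
  expect_true(all(h$height <= 0))
  expect_error(ratioStatistic(h, cfg), "denominator peak absent")

  h2 <- data.frame(position = c(873, 890), height = c(0.2925, 0.1),
                   apex = c(873, 890), detected = TRUE)
  expect_equal(ratioStatistic(h2, cfg), 2.925)
  h2$height[2] <- 0
  expect_error(ratioStatistic(h2, cfg), "denominator peak absent")
})

test_that("the ratio statistic is invariant to scale and to any affine
           offset of the absorbance", {
  set.seed(42)
  for (i in 1:25) {
    s <- toySpectrum(function(w)
      0.2 + triangularBump(w, 873, runif(1, 0.05, 0.6)) +
        triangularBump(w, 890, runif(1, 0.05, 0.6)) +
        0.01 * sin(w / runif(1, 2, 9)))
    r0 <- peakHeightRatio(s, cfg)
    g <- runif(1, 0.1, 10)
    expect_equal(peakHeightRatio(g * s, cfg), r0, tolerance = 1e-12)
    c0 <- runif(1, -0.5, 0.5)
    c1 <- runif(1, -0.01, 0.01)
    shifted <- Spectrum(wavenumbers(s),
                        absorbance(s) + c0 + c1 * wavenumbers(s))
    h0 <- correctedHeights(s, cfg)$height
    h1 <- correctedHeights(shifted, cfg)$height
    expect_equal(h1, h0, tolerance = 1e-10)
  }
})

test_that("corrected heights agree with the brute-force oracle on
           randomized spectra", {
  set.seed(99)
  for (i in 1:30) {
    by <- sample(c(0.5, 1, 2), 1)
    s <- toySpectrum(function(w)
      runif(1, 0, 0.3) +
        triangularBump(w, runif(1, 870, 876), runif(1, 0, 0.5),
                       runif(1, 3, 9)) +
        triangularBump(w, runif(1, 887, 893), runif(1, 0, 0.5),
                       runif(1, 3, 9)) +
        rnorm(length(w), 0, 0.02),
      from = 855 - runif(1), to = 912 + runif(1), by = by)
    got <- suppressWarnings(
      correctedHeights(s, cfg, positions = c(873, 890))$height)
    expect_equal(got, bruteHeights(s, cfg, c(873, 890)), tolerance = 1e-10)
  }
})
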