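test_that("anchor amplitudes follow the linear-mixing algebra", {
  am <- deriveAnchorAmplitudes(2.74, -2.52)
  expect_equal(unname(am), c(0.22, 1, 2.74, 0), tolerance = 1e-12)
  expect_equal(deriveAnchorAmplitudes(1, 0),
               c(P873 = 1, P890 = 1, T873 = 1, T890 = 0))
  expect_error(deriveAnchorAmplitudes(1, -2), "positive")
  expect_error(deriveAnchorAmplitudes(-1, 0), "positive")
})

test_that("the pseudo-Voigt line shape has unit height and the right
           half-widths", {
  expect_equal(pseudoVoigt(890, 890, 6, 0.7), 1)
  # pure Lorentzian: exactly half height at +/- fwhm/2
  expect_equal(pseudoVoigt(890 + 3, 890, 6, 1), 0.5)
  expect_equal(pseudoVoigt(890 - 3, 890, 6, 1), 0.5)
  # pure Gaussian too, by definition of fwhm
  expect_equal(pseudoVoigt(890 + 3, 890, 6, 0), 0.5)
  # far tails decay below 1e-3 within 500 cm-1 for the default mix
  expect_lt(pseudoVoigt(890 + 500, 890, 6, 0.7), 1e-3)
})

test_that("well-separated bands superpose with negligible cross-talk", {
  cfg <- noiselessConfig(
    bandTables = data.frame(api = "PIP", center = c(1000, 1500),
                            amplitude = c(0.4, 0.7), fwhm = 6, eta = 0.7))
  s <- synthComponentSpectrum("PIP", cfg)
  a <- absorbance(s)
  w <- wavenumbers(s)
  expect_equal(a[w == 1000], 0.4, tolerance = 1e-3 / 0.4)
  expect_equal(a[w == 1500], 0.7, tolerance = 1e-3 / 0.7)
})

test_that("component synthesis needs a configured band table", {
  expect_error(synthComponentSpectrum("XYZ"), "no bands")
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- generatorConfig(seed = 123)
  a1 <- synthMixtureReplicates(89, 11, 2, cfg)
  a2 <- synthMixtureReplicates(89, 11, 2, cfg)
  expect_identical(lapply(a1, absorbance), lapply(a2, absorbance))
  # replicates differ from one another
  expect_false(identical(absorbance(a1[[1]]), absorbance(a1[[2]])))
  # a different seed produces different draws
  a3 <- synthMixtureReplicates(89, 11, 2, generatorConfig(seed = 124))
  expect_false(identical(absorbance(a1[[1]]), absorbance(a3[[1]])))
})

test_that("the generator respects the RNG state of the caller", {
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(synthMixtureReplicates(50, 50, 1, generatorConfig(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("closure and replicate-count preconditions are enforced", {
  expect_error(synthMixtureReplicates(101, -1), "closure")
  expect_error(synthMixtureReplicates(60, 50), "closure")
  expect_error(synthBlankPipFilms(1), "at least 2")
})

test_that("noiseless mixtures reproduce the encoded calibration line within
           the band-overlap tolerance", {
  cfg <- noiselessConfig()
  # the 50:50 mixture: exact line value 2.96 (Table value 2.925 measured)
  y50 <- peakHeightRatio(synthMixtureReplicates(50, 50, 1, cfg)[[1]])
  expect_equal(y50, 2.96, tolerance = 0.05 / 2.96)
  # across all six standard compositions
  for (cp in c(50, 55, 75, 85, 90, 95)) {
    y <- peakHeightRatio(synthMixtureReplicates(cp, 100 - cp, 1, cfg)[[1]])
    expect_lt(abs(y - (-2.52 + 2.74 * 100 / cp)), 0.05)
  }
  # and the statistic is intermediate between the pure components
  yPip <- peakHeightRatio(synthComponentSpectrum("PIP", cfg))
  yTaz <- peakHeightRatio(synthMixtureReplicates(0, 100, 1, cfg)[[1]])
  expect_true(yPip < y50 && y50 < yTaz)
})

test_that("noiseless blank films sit at the pure-PIP ratio", {
  cfg <- noiselessConfig()
  blanks <- synthBlankPipFilms(2, cfg)
  r <- vapply(blanks, peakHeightRatio, numeric(1))
  expect_equal(r[1], r[2], tolerance = 1e-12)
  expect_equal(r[1], 0.22, tolerance = 0.02 / 0.22)
})

test_that("default-noise blanks yield dispersed but well-defined blank
           statistics", {
  b <- blankStats(vapply(synthBlankPipFilms(20, generatorConfig(seed = 8)),
                         peakHeightRatio, numeric(1)))
  expect_gt(b@sdRatio, 0)
  expect_equal(b@meanRatio, 0.22, tolerance = 0.1)
  expect_equal(b@nBlanks, 20L)
})

test_that("the ratio cancels the film scale and the anchored baseline
           removes drift exactly", {
  ratioAt <- function(filmSd) {
    cfg <- generatorConfig(filmScaleSd = filmSd, additiveNoiseSd = 0,
                           seed = 77)
    vapply(synthMixtureReplicates(75, 25, 3, cfg), peakHeightRatio,
           numeric(1))
  }
  expect_equal(ratioAt(0.5), ratioAt(0), tolerance = 1e-9)
  # drift alone (no film scale, no additive noise) leaves the ratio at its
  # noiseless value
  driftCfg <- generatorConfig(filmScaleSd = 0, additiveNoiseSd = 0,
                              driftSlopeRange = c(-2e-4, 2e-4),
                              driftOffsetRange = c(-0.1, 0.1), seed = 78)
  expect_equal(
    vapply(synthMixtureReplicates(75, 25, 3, driftCfg), peakHeightRatio,
           numeric(1)),
    rep(peakHeightRatio(synthMixtureReplicates(75, 25, 1,
                                               noiselessConfig())[[1]]), 3),
    tolerance = 1e-10)
})

test_that("replicate ratio dispersion at default noise matches the
           published reproducibility", {
  # expected 3-replicate RSD near 2.8 % at the 10:90 composition; average
  # over several triplets to damp the chi-distribution spread of n=3 RSDs
  rsds <- vapply(1:12, function(k) {
    r <- vapply(synthMixtureReplicates(90, 10, 3,
                                       generatorConfig(seed = 400 + k)),
                peakHeightRatio, numeric(1))
    100 * stats::sd(r) / mean(r)
  }, numeric(1))
  expect_gt(mean(rsds), 2)
  expect_lt(mean(rsds), 4)
})
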