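test_that("the composition transform linearizes the closed mixture", {
  expect_equal(compositionTransform(50), 2)
  expect_equal(compositionTransform(100), 1)
  expect_error(compositionTransform(0), "positive")
  expect_error(compositionTransform(-5), "positive")
  expect_error(compositionTransform(101), "closure")
})

test_that("fitting the six published standard means recovers the published
           line", {
  std <- pipTazStandards()
  m <- fitCalibration(data.frame(cPip = std$cPip, ratio = std$ratio),
                      fitMode = "on_means")
  # frozen from the independent closed-form oracle on the printed means
  expect_equal(slope(m), 2.732488, tolerance = 1e-6)
  expect_equal(intercept(m), -2.510757, tolerance = 1e-6)
  expect_equal(rSquared(m), 0.99962, tolerance = 1e-4)
  o <- bruteOLS(compositionTransform(std$cPip), std$ratio)
  expect_equal(slope(m), o$slope, tolerance = 1e-12)
  expect_equal(intercept(m), o$intercept, tolerance = 1e-12)
  expect_equal(unname(standardErrors(m)),
               c(o$seSlope, o$seIntercept), tolerance = 1e-10)
})

test_that("exact and degenerate designs are handled as specified", {
  exact <- data.frame(cPip = c(100, 50, 100 / 3),
                      ratio = c(1, 3, 5))  # x = 1, 2, 3
  m <- fitCalibration(exact, fitMode = "on_means")
  expect_equal(slope(m), 2, tolerance = 1e-12)
  expect_equal(intercept(m), -1, tolerance = 1e-12)
  expect_equal(rSquared(m), 1)
  expect_equal(residualSd(m), 0, tolerance = 1e-12)

  expect_error(
    fitCalibration(data.frame(cPip = c(80, 80), ratio = c(1, 2))),
    "no x spread")

  expect_warning(
    m2 <- fitCalibration(data.frame(cPip = c(50, 95),
                                    ratio = c(2.925, 0.367))),
    "undefined")
  expect_true(is.na(residualSd(m2)))
  expect_true(all(is.na(standardErrors(m2))))
})

test_that("replicate-mode and mean-mode fits differ only as intended", {
  set.seed(3)
  reps <- do.call(rbind, lapply(c(50, 75, 95), function(cp)
    data.frame(cPip = cp, ratio = -2.5 + 2.7 * 100 / cp + rnorm(3, 0, 0.02))))
  mR <- fitCalibration(reps, fitMode = "on_replicates")
  mM <- fitCalibration(reps, fitMode = "on_means")
  expect_equal(mR@nPoints, 9L)
  expect_equal(mM@nPoints, 3L)
  # balanced design: identical point estimates, different dispersion
  expect_equal(slope(mR), slope(mM), tolerance = 1e-10)
  expect_equal(intercept(mR), intercept(mM), tolerance = 1e-10)
})

test_that("prediction evaluates the line on the transformed axis", {
  m <- publishedCalibrationModel()
  expect_equal(predictRatio(m, 100), 0.22, tolerance = 1e-12)
  expect_equal(predictRatio(m, 50), 2.96, tolerance = 1e-12)
  unit <- new("CalibrationModel", slope = 1, intercept = 0,
              seSlope = NA_real_, seIntercept = NA_real_, rSquared = 1,
              residualSd = NA_real_, nPoints = 3L, fitMode = "on_means")
  expect_equal(predictRatio(unit, 100), 1)
})

test_that("inversion recovers compositions, closes, and flags as required", {
  m <- publishedCalibrationModel()
  inv <- invertToComposition(m, 0.367)
  expect_equal(inv$cPip, 94.91, tolerance = 1e-3)
  expect_equal(inv$cTaz, 5.09, tolerance = 1e-3)
  expect_equal(inv$cPip + inv$cTaz, 100)

  expect_error(invertToComposition(m, -2.52), "below calibration intercept")
  expect_error(invertToComposition(m, -3), "below calibration intercept")

  below <- invertToComposition(m, 0.20)  # under the pure-PIP ratio 0.22
  expect_gt(below$cPip, 100)
  expect_match(paste(below$notes, collapse = " "), "extrapolation")

  # predict -> invert round trip across the whole composition range
  for (cp in c(0.5, 5, 11, 50, 89, 99, 100)) {
    rt <- invertToComposition(m, predictRatio(m, cp))
    expect_equal(rt$cPip, cp, tolerance = 1e-9)
  }

  # strictly decreasing in y: more TAZ means a larger ratio
  ys <- seq(0.23, 3, length.out = 40)
  cps <- vapply(ys, function(y) invertToComposition(m, y)$cPip, numeric(1))
  expect_true(all(diff(cps) < 0))
})

test_that("replicate summaries use the sample (n-1) convention", {
  sm <- replicateSummary(c(0.50, 0.52, 0.53))
  expect_equal(sm$mean, 0.5166667, tolerance = 1e-6)
  expect_equal(sm$sd, 0.01527525, tolerance = 1e-6)
  expect_equal(sm$rsd, 2.9565005, tolerance = 1e-5)
  expect_equal(sm$se, sm$sd / sqrt(3))

  const <- replicateSummary(c(0.5, 0.5, 0.5))
  expect_equal(const$rsd, 0)

  single <- replicateSummary(0.5)
  expect_equal(single$mean, 0.5)
  expect_true(is.na(single$sd) && is.na(single$rsd))

  expect_warning(z <- replicateSummary(c(-1, 1)), "mean is zero")
  expect_true(is.na(z$rsd))
})

test_that("delta-method uncertainty matches the hand-derived derivative", {
  m <- publishedCalibrationModel()
  sm <- list(mean = 0.559, se = 0.002, sd = 0.002 * sqrt(3), rsd = 1, n = 3)
  expect_equal(propagateUncertainty(m, sm), 274 / 3.079^2 * 0.002,
               tolerance = 1e-9)
  # hand value from the derivative chain: |dC/dy| = 28.90 at y = 0.559
  expect_equal(propagateUncertainty(m, sm), 0.0578, tolerance = 1e-3)

  sm0 <- list(mean = 0.559, se = 0, n = 3)
  expect_equal(propagateUncertainty(m, sm0), 0)
  sm2 <- list(mean = 0.559, se = 0.004, n = 3)
  expect_equal(propagateUncertainty(m, sm2),
               2 * propagateUncertainty(m, sm), tolerance = 1e-12)

  # extended mode adds the calibration-parameter terms in quadrature
  ext <- propagateUncertainty(m, sm, mode = "extended")
  dCdy <- 274 / 3.079^2
  expect_equal(ext, sqrt(dCdy^2 * 0.002^2 + dCdy^2 * 0.026^2 +
                           (100 / 3.079)^2 * 0.024^2), tolerance = 1e-9)
  expect_gt(ext, propagateUncertainty(m, sm))
})

test_that("quantifySample bundles closure, uncertainty and flags", {
  m <- publishedCalibrationModel()
  q <- quantifySample(m, c(0.555, 0.559, 0.563), "formulation")
  cc <- composition(q)
  expect_equal(unname(cc["cPip"] + cc["cTaz"]), 100)
  expect_equal(unname(cc["cPip"]), 100 * 2.74 / (0.559 + 2.52),
               tolerance = 1e-9)
  expect_gt(q@sdComposition, 0)

  single <- quantifySample(m, 0.559)
  expect_true(is.na(single@sdComposition))
  expect_equal(single@nReplicates, 1L)

  low <- quantifySample(m, c(0.30, 0.31, 0.29))  # ~3 % w/w TAZ
  expect_match(paste(low@notes, collapse = " "), "outside calibrated range")
})

test_that("blank-based detection limits reproduce the published pair", {
  m <- publishedCalibrationModel()
  b <- referenceBlankStats(m)
  expect_equal(b@meanRatio, 0.22, tolerance = 1e-12)
  dl <- estimateDetectionLimits(m, b, kDetect = 3, loqFactor = 3)
  expect_equal(dl@lodTaz, 1.618, tolerance = 0.005 / 1.618)
  expect_equal(dl@loqTaz, 3 * dl@lodTaz, tolerance = 1e-12)
  expect_equal(round(dl@loqTaz, 3), 4.854)

  # noiseless blank exactly at the pure-PIP point: zero detectable TAZ
  b0 <- new("BlankStats", meanRatio = 0.22, sdRatio = 0, nBlanks = 5L)
  expect_equal(estimateDetectionLimits(m, b0)@lodTaz, 0)

  # k = 0 reduces to the blank-mean-implied TAZ content (here zero)
  dl0 <- estimateDetectionLimits(m, b, kDetect = 0)
  expect_equal(dl0@lodTaz, 0)

  # LOD grows linearly with the blank sd in the small-sd regime
  lods <- vapply(c(1, 2, 4), function(f)
    estimateDetectionLimits(m, new("BlankStats", meanRatio = 0.22,
                                   sdRatio = f * 0.002, nBlanks = 5L))@lodTaz,
    numeric(1))
  expect_equal(lods[2] / lods[1], 2, tolerance = 0.01)
  expect_equal(lods[3] / lods[1], 4, tolerance = 0.02)

  # ratio mode: ICH-style kQ decision ratio instead of the factor rule
  dlr <- estimateDetectionLimits(m, b, kDetect = 3, method = "ratio",
                                 kQ = 10)
  yQ <- 0.22 + 10 * 0.01502
  expect_equal(dlr@loqTaz, 100 - 100 * 2.74 / (yQ + 2.52), tolerance = 1e-9)

  expect_error(estimateDetectionLimits(
    m, new("BlankStats", meanRatio = -2.6, sdRatio = 0.01, nBlanks = 3L)),
    "below the intercept")
})

test_that("the model serializes to JSON and reloads bit-exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  std <- pipTazStandards()
  m <- fitCalibration(data.frame(cPip = std$cPip, ratio = std$ratio),
                      fitMode = "on_means")
  writeCalibrationModel(m, f)
  m2 <- readCalibrationModel(f)
  expect_identical(slope(m2), slope(m))
  expect_identical(intercept(m2), intercept(m))
  expect_identical(standardErrors(m2), standardErrors(m))
  expect_identical(rSquared(m2), rSquared(m))
  expect_identical(residualSd(m2), residualSd(m))
  expect_identical(m2@nPoints, m@nPoints)
  expect_identical(fitMode(m2), fitMode(m))
  expect_equal(ratioConfig(m2)@apexHalfwidth, 4)
})

test_that("OLS matches the closed-form oracle on random small designs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- runif(n, 1, 2.2)
    y <- runif(1, 1, 4) * x + rnorm(n, 0, 0.1)
    m <- fitCalibration(data.frame(cPip = 100 / x, ratio = y),
                        fitMode = "on_replicates")
    o <- bruteOLS(x, y)
    expect_equal(slope(m), o$slope, tolerance = 1e-10)
    expect_equal(intercept(m), o$intercept, tolerance = 1e-10)
    expect_equal(rSquared(m), o$rSquared, tolerance = 1e-10)
    expect_equal(residualSd(m), o$residualSd, tolerance = 1e-10)
  }
})
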