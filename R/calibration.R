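#' Closed-mixture composition transform
#'
#' For a binary mixture under the closure C_PIP + C_TAZ = 100 % w/w the
#' peak-height ratio is linear in x = 100 / C_PIP, which is the abscissa of
#' the single calibration line.
#'
#' @param cPip piperacillin content, % w/w, in (0, 100]
#' @return x = 100 / cPip
#' @examples
#' compositionTransform(50)   # 2
#' compositionTransform(100)  # 1, the pure-PIP limit
#' @export
compositionTransform <- function(cPip) {
  if (any(!is.finite(cPip)) || any(cPip <= 0))
    stop("cPip must be positive: the transform 100/cPip is undefined at 0")
  if (any(cPip > 100))
    stop("cPip exceeds 100 % w/w (closure violated)")
  100 / cPip
}

#' Fit the calibration line
#'
#' Ordinary least squares of the replicate peak-height ratios (or their
#' per-standard means) on x = 100 / C_PIP. `fitMode = "on_replicates"`
#' (default) uses every film; `"on_means"` first averages replicates within
#' each standard, which is the right mode when only mean ratios are
#' available (as in a printed standards table).
#'
#' @param standards data.frame with columns `cPip` (% w/w) and `ratio` (one
#'   row per replicate film); an optional `cTaz` column is checked for
#'   closure
#' @param fitMode `"on_replicates"` (default) or `"on_means"`
#' @param cfg the [RatioConfig-class] snapshot stored in the model
#' @return a [CalibrationModel-class]
#' @examples
#' std <- data.frame(cPip = c(50, 75, 95), ratio = c(2.9, 1.1, 0.37))
#' fitCalibration(std, fitMode = "on_means")
#' @export
fitCalibration <- function(standards,
                           fitMode = c("on_replicates", "on_means"),
                           cfg = RatioConfig()) {
  fitMode <- match.arg(fitMode)
  stopifnot(is.data.frame(standards),
            all(c("cPip", "ratio") %in% names(standards)))
  if ("cTaz" %in% names(standards) &&
      any(abs(standards$cPip + standards$cTaz - 100) > 1e-9, na.rm = TRUE))
    stop("standards violate closure: cPip + cTaz must equal 100")
  if (fitMode == "on_means") {
    agg <- stats::aggregate(ratio ~ cPip, data = standards, FUN = mean)
    x <- compositionTransform(agg$cPip)
    y <- agg$ratio
  } else {
    x <- compositionTransform(standards$cPip)
    y <- standards$ratio
  }
  ux <- unique(x)
  if (length(ux) < 2L)
    stop("all standards share one composition: no x spread to fit a line")
  if (length(ux) < 3L && length(x) < 3L)
    warning("only 2 points: exact fit, standard errors undefined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  n <- length(x)
  if (n > 2L) {
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    se <- sm$coefficients[, "Std. Error"]
    s <- sm$sigma
    r2 <- sm$r.squared
  } else {
    se <- c(NA_real_, NA_real_)
    s <- NA_real_
    r2 <- 1
  }
  new("CalibrationModel",
      slope = unname(cf[2]), intercept = unname(cf[1]),
      seSlope = unname(se[2]), seIntercept = unname(se[1]),
      rSquared = r2, residualSd = s, nPoints = as.integer(n),
      fitMode = fitMode, ratioConfig = cfg)
}

#' @rdname accessors
#' @export
setMethod("slope", "CalibrationModel", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("intercept", "CalibrationModel", function(object) object@intercept)

#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationModel", function(object) object@rSquared)

#' @rdname accessors
#' @export
setMethod("residualSd", "CalibrationModel", function(object) object@residualSd)

#' @rdname accessors
#' @export
setMethod("standardErrors", "CalibrationModel", function(object)
  c(slope = object@seSlope, intercept = object@seIntercept))

#' @rdname accessors
#' @export
setMethod("fitMode", "CalibrationModel", function(object) object@fitMode)

#' @rdname accessors
#' @export
setMethod("ratioConfig", "CalibrationModel", function(object)
  object@ratioConfig)

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: y = %.4g x %+.4g  (x = 100/C_PIP)\n",
    object@slope, object@intercept))
  cat(sprintf("  se(slope) = %.3g, se(intercept) = %.3g, R2 = %.5f\n",
              object@seSlope, object@seIntercept, object@rSquared))
  cat(sprintf("  residual sd = %.3g, n = %d, fit %s\n",
              object@residualSd, object@nPoints, object@fitMode))
})

#' Predict the peak-height ratio of a known composition
#'
#' Evaluates the calibration line at x = 100 / cPip.
#'
#' @param m a [CalibrationModel-class]
#' @param cPip piperacillin content, % w/w, in (0, 100]
#' @return predicted ratio(s)
#' @export
predictRatio <- function(m, cPip) {
  stopifnot(is(m, "CalibrationModel"))
  m@slope * compositionTransform(cPip) + m@intercept
}

#' Invert a measured ratio to a composition
#'
#' Solves the calibration line for C_PIP and applies the closure
#' C_TAZ = 100 - C_PIP. A ratio at or below the intercept has no positive
#' solution; a solution above 100 % w/w (ratio below the pure-PIP point) is
#' reported but flagged as extrapolation, as is a composition outside the
#' calibrated 5-50 % w/w TAZ range.
#'
#' @param m a [CalibrationModel-class]
#' @param y measured (mean) peak-height ratio
#' @return list with `cPip`, `cTaz`, `notes` (character vector of flags)
#' @export
invertToComposition <- function(m, y) {
  stopifnot(is(m, "CalibrationModel"), length(y) == 1L, is.finite(y))
  a <- m@intercept
  b <- m@slope
  if (y <= a)
    stop(sprintf("ratio %.4g below calibration intercept %.4g: no positive solution",
                 y, a))
  cPip <- 100 * b / (y - a)
  notes <- character()
  if (cPip > 100)
    notes <- c(notes, sprintf(
      "extrapolation: ratio %.4g below the pure-PIP point, cPip = %.2f > 100",
      y, cPip))
  cTaz <- 100 - cPip
  if (cTaz > 0 && (cTaz < 5 || cTaz > 50))
    notes <- c(notes, sprintf(
      "outside calibrated range 5-50 %% w/w TAZ (cTaz = %.2f)", cTaz))
  list(cPip = cPip, cTaz = cTaz, notes = notes)
}

#' Replicate summary statistics
#'
#' Mean, sample (n-1) standard deviation, relative standard deviation in
#' percent and standard error of a set of replicate ratio measurements.
#' With a single replicate the dispersion statistics are NA.
#'
#' @param ratios numeric vector, one value per replicate film
#' @return list with `mean`, `sd`, `rsd`, `se`, `n`
#' @examples
#' replicateSummary(c(0.50, 0.52, 0.53))
#' @export
replicateSummary <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (!length(ratios) || anyNA(ratios))
    stop("need at least one finite replicate ratio")
  n <- length(ratios)
  m <- mean(ratios)
  if (n >= 2L) {
    s <- stats::sd(ratios)
    rsd <- if (m == 0) {
      warning("mean is zero: RSD undefined")
      NA_real_
    } else 100 * s / abs(m)
    se <- s / sqrt(n)
  } else {
    s <- NA_real_; rsd <- NA_real_; se <- NA_real_
  }
  list(mean = m, sd = s, rsd = rsd, se = se, n = n)
}

#' First-order uncertainty of the inverted composition
#'
#' Delta-method propagation through the inversion
#' C_PIP = 100 b / (y - a). The default `"replicate"` mode propagates only
#' the standard error of the mean measured ratio:
#' sd(C_PIP) = (100 b / (y - a)^2) * se(y). The `"extended"` mode
#' additionally folds in the calibration parameter uncertainties:
#' var(C_PIP) = (dC/dy)^2 se(y)^2 + (dC/da)^2 se(a)^2 + (dC/db)^2 se(b)^2
#' with dC/dy = -100 b/(y-a)^2, dC/da = 100 b/(y-a)^2, dC/db = 100/(y-a)
#' (the slope-intercept covariance is neglected). The closure makes
#' sd(C_TAZ) = sd(C_PIP).
#'
#' @param m a [CalibrationModel-class]
#' @param summary output of [replicateSummary()] for the sample's ratios
#' @param mode `"replicate"` (default) or `"extended"`
#' @return sd of C_PIP (= sd of C_TAZ), % w/w
#' @export
propagateUncertainty <- function(m, summary,
                                 mode = c("replicate", "extended")) {
  mode <- match.arg(mode)
  stopifnot(is(m, "CalibrationModel"))
  y <- summary$mean
  a <- m@intercept
  b <- m@slope
  if (y <= a) stop("ratio below calibration intercept")
  dCdy <- 100 * b / (y - a)^2
  se <- summary$se
  if (is.na(se)) return(NA_real_)
  v <- dCdy^2 * se^2
  if (mode == "extended") {
    if (is.na(m@seSlope) || is.na(m@seIntercept))
      stop("extended mode needs defined calibration standard errors")
    v <- v + dCdy^2 * m@seIntercept^2 + (100 / (y - a))^2 * m@seSlope^2
  }
  sqrt(v)
}

#' Quantify one unknown sample
#'
#' Replicate summary, inversion through the calibration line, first-order
#' uncertainty and range flags, bundled into a [QuantResult-class].
#'
#' @param m a [CalibrationModel-class]
#' @param ratios replicate peak-height ratios of the sample
#' @param sampleId identifier carried into the result
#' @param uncertaintyMode passed to [propagateUncertainty()]
#' @return a [QuantResult-class]
#' @export
quantifySample <- function(m, ratios, sampleId = NA_character_,
                           uncertaintyMode = c("replicate", "extended")) {
  uncertaintyMode <- match.arg(uncertaintyMode)
  sm <- replicateSummary(ratios)
  inv <- invertToComposition(m, sm$mean)
  sdC <- if (sm$n >= 2L)
    propagateUncertainty(m, sm, mode = uncertaintyMode) else NA_real_
  new("QuantResult",
      sampleId = as.character(sampleId),
      cPip = inv$cPip, cTaz = inv$cTaz,
      sdComposition = sdC,
      meanRatio = sm$mean, ratioRsd = sm$rsd,
      nReplicates = as.integer(sm$n),
      notes = inv$notes)
}

#' @rdname accessors
#' @export
setMethod("composition", "QuantResult", function(object)
  c(cPip = object@cPip, cTaz = object@cTaz))

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult [%s]\n", object@sampleId))
  cat(sprintf("  C_PIP = (%.2f +/- %s) %% w/w, C_TAZ = (%.2f +/- %s) %% w/w\n",
              object@cPip, format(object@sdComposition, digits = 2),
              object@cTaz, format(object@sdComposition, digits = 2)))
  cat(sprintf("  mean ratio %.4g, RSD %.2f %%, n = %d\n",
              object@meanRatio, object@ratioRsd, object@nReplicates))
  for (nt in object@notes) cat("  note:", nt, "\n")
})
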