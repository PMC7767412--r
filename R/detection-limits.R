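#' Blank (pure-PIP film) ratio statistics
#'
#' @param ratios peak-height ratios of >= 2 blank films
#' @return a [BlankStats-class]
#' @export
blankStats <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < 2L)
    stop("need at least 2 blank measurements for a defined sd")
  new("BlankStats",
      meanRatio = mean(ratios),
      sdRatio = stats::sd(ratios),
      nBlanks = length(ratios))
}

setMethod("show", "BlankStats", function(object) {
  cat(sprintf("BlankStats: mean ratio %.4g, sd %.4g, n = %d\n",
              object@meanRatio, object@sdRatio, object@nBlanks))
})

#' Blank-based detection limits for the minor component
#'
#' The decision ratio is the blank mean plus `kDetect` blank standard
#' deviations, y_D = mean + k * sd. Mapping y_D through the calibration
#' line gives the largest C_PIP still distinguishable from a pure-PIP film,
#' and LOD_TAZ = 100 - C_PIP(y_D). In `"factor"` mode (default)
#' LOQ = loqFactor * LOD; in `"ratio"` mode the LOQ is computed like the
#' LOD but from y_Q = mean + kQ * sd (ICH-style k = 3.3/10 is available
#' this way).
#'
#' @param m a [CalibrationModel-class]
#' @param blanks a [BlankStats-class]
#' @param kDetect blank-sd multiplier for the LOD decision ratio (default 3)
#' @param loqFactor LOQ/LOD multiplier in factor mode (default 3)
#' @param method `"factor"` (default) or `"ratio"`
#' @param kQ blank-sd multiplier for the LOQ decision ratio in ratio mode
#'   (default 10)
#' @return a [DetectionLimits-class]
#' @examples
#' m <- new("CalibrationModel", slope = 2.74, intercept = -2.52,
#'          seSlope = NA_real_, seIntercept = NA_real_, rSquared = 0.999,
#'          residualSd = NA_real_, nPoints = 6L, fitMode = "on_means")
#' b <- new("BlankStats", meanRatio = 0.22, sdRatio = 0.01502, nBlanks = 20L)
#' estimateDetectionLimits(m, b)
#' @export
estimateDetectionLimits <- function(m, blanks, kDetect = 3, loqFactor = 3,
                                    method = c("factor", "ratio"), kQ = 10) {
  method <- match.arg(method)
  stopifnot(is(m, "CalibrationModel"), is(blanks, "BlankStats"),
            kDetect >= 0, loqFactor > 0)
  lodFromDecision <- function(yD) {
    if (yD <= m@intercept)
      stop(sprintf("decision ratio %.4g at or below the intercept %.4g",
                   yD, m@intercept))
    cPip <- 100 * m@slope / (yD - m@intercept)
    # a blank mean below the pure-PIP point would give cPip > 100; the
    # implied TAZ content cannot be negative
    max(0, 100 - cPip)
  }
  yD <- blanks@meanRatio + kDetect * blanks@sdRatio
  lod <- lodFromDecision(yD)
  loq <- if (method == "factor") loqFactor * lod
         else lodFromDecision(blanks@meanRatio + kQ * blanks@sdRatio)
  new("DetectionLimits",
      lodTaz = lod, loqTaz = loq,
      kDetect = kDetect, loqFactor = loqFactor, method = method)
}

setMethod("show", "DetectionLimits", function(object) {
  cat(sprintf(
    "DetectionLimits (%s mode): LOD = %.3f %% w/w TAZ, LOQ = %.3f %% w/w\n",
    object@method, object@lodTaz, object@loqTaz))
})
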