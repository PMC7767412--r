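#' Serialize a calibration model to JSON
#'
#' All model fields plus the ratio-configuration snapshot and creation
#' metadata, written at full numeric precision so that
#' [readCalibrationModel()] reloads the model bit-exactly.
#'
#' @param m a [CalibrationModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCalibrationModel <- function(m, path) {
  stopifnot(is(m, "CalibrationModel"))
  rc <- m@ratioConfig
  x <- list(
    type = "CalibrationModel",
    slope = m@slope, intercept = m@intercept,
    se_slope = m@seSlope, se_intercept = m@seIntercept,
    r_squared = m@rSquared, residual_sd = m@residualSd,
    n_points = m@nPoints, fit_mode = m@fitMode,
    ratio_config = list(
      numerator_position = rc@numeratorPosition,
      denominator_position = rc@denominatorPosition,
      baseline_left = rc@baselineLeft,
      baseline_right = rc@baselineRight,
      apex_halfwidth = rc@apexHalfwidth),
    created = list(
      package = as.character(utils::packageVersion("atrquant")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  # digits = I(17) keeps 17 significant digits: doubles reload bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Reload a calibration model from JSON
#'
#' @param path path written by [writeCalibrationModel()]
#' @return a [CalibrationModel-class]
#' @export
readCalibrationModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$type) || x$type != "CalibrationModel")
    stop("not a CalibrationModel file: ", path)
  rc <- x$ratio_config
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("CalibrationModel",
      slope = num(x$slope), intercept = num(x$intercept),
      seSlope = num(x$se_slope), seIntercept = num(x$se_intercept),
      rSquared = num(x$r_squared), residualSd = num(x$residual_sd),
      nPoints = as.integer(x$n_points), fitMode = x$fit_mode,
      ratioConfig = RatioConfig(
        numeratorPosition = num(rc$numerator_position),
        denominatorPosition = num(rc$denominator_position),
        baselineLeft = num(rc$baseline_left),
        baselineRight = num(rc$baseline_right),
        apexHalfwidth = num(rc$apex_halfwidth)))
}
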