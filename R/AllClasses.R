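#' @import methods
NULL

#' Spectrum: an infrared absorbance spectrum on an ordered wavenumber grid
#'
#' The universal carrier through the pipeline: a strictly increasing
#' wavenumber grid (cm^-1), matching absorbance values (a.u.) and free-form
#' metadata (sample id, replicate index, role, resolution, ...). Readers
#' normalise descending input (common in infrared exports) to ascending.
#'
#' @slot wavenumbers numeric, strictly increasing, length >= 2 (cm^-1)
#' @slot absorbance numeric, same length, all finite (a.u.)
#' @slot meta named list of free-form metadata
#'
#' @seealso [Spectrum()] for the user-facing constructor,
#'   [readSpectrum()] for file input.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavenumbers = "numeric",
    absorbance  = "numeric",
    meta        = "list"
  ),
  prototype(meta = list())
)

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers
  a <- object@absorbance
  msgs <- character()
  if (length(w) < 2L)
    msgs <- c(msgs, "need at least 2 grid points")
  if (length(w) != length(a))
    msgs <- c(msgs, "wavenumbers and absorbance differ in length")
  if (anyNA(w) || any(!is.finite(w)))
    msgs <- c(msgs, "wavenumbers must be finite")
  if (anyNA(a) || any(!is.finite(a)))
    msgs <- c(msgs, "absorbance values must be finite")
  if (length(w) >= 2L && !all(diff(w) > 0))
    msgs <- c(msgs, "wavenumbers must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' RatioConfig: definition of the peak-height ratio statistic
#'
#' Holds the two peak positions, the anchored-baseline window and the apex
#' search half-width that together define the I(numerator)/I(denominator)
#' statistic. Defaults reproduce the published method: I(873)/I(890) over
#' a single straight baseline anchored at 862 and 905 cm^-1, apexes sought
#' within +/- 4 cm^-1 (the instrument resolution).
#'
#' @slot numeratorPosition numeric(1), cm^-1 (default 873, TAZ-enhanced band)
#' @slot denominatorPosition numeric(1), cm^-1 (default 890, PIP band)
#' @slot baselineLeft numeric(1), cm^-1 left anchor (default 862)
#' @slot baselineRight numeric(1), cm^-1 right anchor (default 905)
#' @slot apexHalfwidth numeric(1), cm^-1 half-width of the apex search
#'   window (default 4); set to 0 conceptually meaning "read at the nominal
#'   position" is not allowed -- use a value below half the grid spacing.
#'
#' @exportClass RatioConfig
setClass("RatioConfig",
  representation(
    numeratorPosition   = "numeric",
    denominatorPosition = "numeric",
    baselineLeft        = "numeric",
    baselineRight       = "numeric",
    apexHalfwidth       = "numeric"
  ),
  prototype(
    numeratorPosition   = 873,
    denominatorPosition = 890,
    baselineLeft        = 862,
    baselineRight       = 905,
    apexHalfwidth       = 4
  )
)

setValidity("RatioConfig", function(object) {
  msgs <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@numeratorPosition, object@denominatorPosition,
                       object@baselineLeft, object@baselineRight,
                       object@apexHalfwidth), one, logical(1))))
    return("all fields must be finite scalars")
  if (!(object@baselineLeft < object@numeratorPosition &&
        object@numeratorPosition < object@denominatorPosition &&
        object@denominatorPosition < object@baselineRight))
    msgs <- c(msgs,
      "require baselineLeft < numeratorPosition < denominatorPosition < baselineRight")
  if (object@apexHalfwidth <= 0)
    msgs <- c(msgs, "apexHalfwidth must be positive")
  if (object@denominatorPosition - object@numeratorPosition <=
      2 * object@apexHalfwidth)
    msgs <- c(msgs, "apex search windows of the two peaks overlap")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationModel: the fitted calibration line
#'
#' Ordinary least-squares line relating the peak-height ratio y to the
#' closed-mixture transform x = 100 / C_PIP, with standard errors, R^2,
#' residual standard deviation and a snapshot of the ratio configuration
#' the training ratios were computed with. An exact two-point fit carries
#' NA standard errors and residual SD (undefined markers).
#'
#' @slot slope numeric(1), fitted slope b
#' @slot intercept numeric(1), fitted intercept a
#' @slot seSlope numeric(1), standard error of b (NA if n = 2)
#' @slot seIntercept numeric(1), standard error of a (NA if n = 2)
#' @slot rSquared numeric(1), coefficient of determination
#' @slot residualSd numeric(1), residual standard deviation s (NA if n = 2)
#' @slot nPoints integer(1), number of fitted points
#' @slot fitMode character(1), "on_means" or "on_replicates"
#' @slot ratioConfig the [RatioConfig-class] snapshot
#'
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(
    slope       = "numeric",
    intercept   = "numeric",
    seSlope     = "numeric",
    seIntercept = "numeric",
    rSquared    = "numeric",
    residualSd  = "numeric",
    nPoints     = "integer",
    fitMode     = "character",
    ratioConfig = "RatioConfig"
  ),
  prototype(ratioConfig = new("RatioConfig"))
)

setValidity("CalibrationModel", function(object) {
  msgs <- character()
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    msgs <- c(msgs, "slope and intercept must be finite")
  if (object@nPoints < 2L)
    msgs <- c(msgs, "a fitted line needs at least 2 points")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msgs <- c(msgs, "rSquared must lie in [0, 1]")
  if (!object@fitMode %in% c("on_means", "on_replicates"))
    msgs <- c(msgs, "fitMode must be 'on_means' or 'on_replicates'")
  if (length(msgs)) msgs else TRUE
})

#' QuantResult: recovered composition of one unknown sample
#'
#' Inverse prediction of one sample through the calibration line, under the
#' two-component closure C_PIP + C_TAZ = 100 % w/w. The closure makes the
#' two composition standard deviations identical by construction.
#'
#' @slot sampleId character(1)
#' @slot cPip numeric(1), recovered piperacillin content (% w/w)
#' @slot cTaz numeric(1), recovered tazobactam content (% w/w)
#' @slot sdComposition numeric(1), first-order sd of either content (% w/w;
#'   NA for a single replicate)
#' @slot meanRatio numeric(1), mean replicate ratio fed to the inversion
#' @slot ratioRsd numeric(1), replicate relative standard deviation (%)
#' @slot nReplicates integer(1)
#' @slot notes character, range/extrapolation warnings attached to this sample
#'
#' @exportClass QuantResult
setClass("QuantResult",
  representation(
    sampleId      = "character",
    cPip          = "numeric",
    cTaz          = "numeric",
    sdComposition = "numeric",
    meanRatio     = "numeric",
    ratioRsd      = "numeric",
    nReplicates   = "integer",
    notes         = "character"
  ),
  prototype(sampleId = NA_character_, notes = character())
)

setValidity("QuantResult", function(object) {
  msgs <- character()
  if (abs(object@cPip + object@cTaz - 100) > 1e-9)
    msgs <- c(msgs, "closure violated: cPip + cTaz must equal 100")
  if (object@nReplicates < 1L)
    msgs <- c(msgs, "need at least one replicate")
  if (length(msgs)) msgs else TRUE
})

#' BlankStats: replicate ratio statistics of blank (pure-PIP) films
#'
#' @slot meanRatio numeric(1), mean blank ratio
#' @slot sdRatio numeric(1), sample sd of the blank ratios (>= 0)
#' @slot nBlanks integer(1), number of blank films (>= 2 for a defined sd)
#'
#' @exportClass BlankStats
setClass("BlankStats",
  representation(
    meanRatio = "numeric",
    sdRatio   = "numeric",
    nBlanks   = "integer"
  )
)

setValidity("BlankStats", function(object) {
  msgs <- character()
  if (object@nBlanks < 2L)
    msgs <- c(msgs, "need at least 2 blanks for a defined sd")
  if (!is.na(object@sdRatio) && object@sdRatio < 0)
    msgs <- c(msgs, "sdRatio must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' DetectionLimits: blank-based LOD and LOQ for the minor component
#'
#' @slot lodTaz numeric(1), limit of detection (% w/w TAZ)
#' @slot loqTaz numeric(1), limit of quantification (% w/w TAZ)
#' @slot kDetect numeric(1), blank-sd multiplier for the decision ratio
#' @slot loqFactor numeric(1), LOQ = loqFactor * LOD in factor mode
#' @slot method character(1), "factor" or "ratio"
#'
#' @exportClass DetectionLimits
setClass("DetectionLimits",
  representation(
    lodTaz    = "numeric",
    loqTaz    = "numeric",
    kDetect   = "numeric",
    loqFactor = "numeric",
    method    = "character"
  )
)

setValidity("DetectionLimits", function(object) {
  msgs <- character()
  if (object@lodTaz < 0)
    msgs <- c(msgs, "lodTaz must be non-negative")
  if (!object@method %in% c("factor", "ratio"))
    msgs <- c(msgs, "method must be 'factor' or 'ratio'")
  if (object@method == "factor" &&
      abs(object@loqTaz - object@loqFactor * object@lodTaz) > 1e-9)
    msgs <- c(msgs, "factor mode requires loqTaz == loqFactor * lodTaz")
  if (length(msgs)) msgs else TRUE
})

#' GeneratorConfig: the synthetic ground truth
#'
#' Everything the seeded spectrum simulator needs: per-API pseudo-Voigt band
#' tables, the wavenumber grid, the film-deposition scale noise (lognormal
#' sigma, multiplicative, cancelled by the ratio), the additive detector
#' noise, the linear drift ranges, and the seed.
#'
#' @slot bandTables data.frame with columns api, center, amplitude, fwhm, eta
#' @slot grid numeric wavenumber grid (cm^-1), must cover the baseline window
#' @slot filmScaleSd numeric(1), sigma of the lognormal film scale g
#' @slot additiveNoiseSd numeric(1), sd of i.i.d. Gaussian absorbance noise
#' @slot driftSlopeRange numeric(2), uniform range of the drift slope
#'   (a.u. per cm^-1)
#' @slot driftOffsetRange numeric(2), uniform range of the drift offset (a.u.)
#' @slot seed integer(1), master seed
#'
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    bandTables       = "data.frame",
    grid             = "numeric",
    filmScaleSd      = "numeric",
    additiveNoiseSd  = "numeric",
    driftSlopeRange  = "numeric",
    driftOffsetRange = "numeric",
    seed             = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  bt <- object@bandTables
  need <- c("api", "center", "amplitude", "fwhm", "eta")
  if (!all(need %in% names(bt)))
    msgs <- c(msgs, paste("bandTables needs columns:",
                          paste(need, collapse = ", ")))
  else {
    if (any(bt$amplitude < 0)) msgs <- c(msgs, "band amplitudes must be >= 0")
    if (any(bt$fwhm <= 0)) msgs <- c(msgs, "band fwhm must be > 0")
    if (any(bt$eta < 0 | bt$eta > 1)) msgs <- c(msgs, "eta must lie in [0, 1]")
  }
  if (object@filmScaleSd < 0 || object@additiveNoiseSd < 0)
    msgs <- c(msgs, "noise scales must be >= 0")
  if (length(object@grid) < 2L || !all(diff(object@grid) > 0))
    msgs <- c(msgs, "grid must be strictly increasing with >= 2 points")
  else if (min(object@grid) > 862 || max(object@grid) < 905)
    msgs <- c(msgs, "grid must cover the baseline window [862, 905]")
  if (length(object@driftSlopeRange) != 2L ||
      length(object@driftOffsetRange) != 2L)
    msgs <- c(msgs, "drift ranges must have length 2")
  if (length(msgs)) msgs else TRUE
})
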