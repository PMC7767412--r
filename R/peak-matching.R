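#' MarkerReport: qualitative identification of the two APIs
#'
#' @slot matchedPositions named list: per API, the reference positions that
#'   a detected local maximum matched within tolerance
#' @slot matchFraction named numeric: fraction of each API's reference
#'   positions matched
#' @slot tazMarkerRatio numeric(1): the I(873)/I(890) statistic (NA when the
#'   890 cm^-1 peak is absent)
#' @slot tazFlag logical(1): TRUE iff tazMarkerRatio exceeds the decision
#'   threshold
#' @exportClass MarkerReport
setClass("MarkerReport",
  representation(
    matchedPositions = "list",
    matchFraction    = "numeric",
    tazMarkerRatio   = "numeric",
    tazFlag          = "logical"
  ))

setMethod("show", "MarkerReport", function(object) {
  cat("MarkerReport\n")
  for (api in names(object@matchFraction))
    cat(sprintf("  %s: %d/%s positions matched (fraction %.2f)\n", api,
                length(object@matchedPositions[[api]]),
                "table", object@matchFraction[[api]]))
  cat(sprintf("  I(873)/I(890) = %s; TAZ flag: %s\n",
              format(object@tazMarkerRatio, digits = 4), object@tazFlag))
})

#' Reference peak table for piperacillin and tazobactam
#'
#' Characteristic mid-infrared band positions of the two APIs: the
#' prominent PIP and TAZ peaks plus the TAZ marker positions where the
#' formulation spectrum differs visibly from pure PIP (intensity
#' enhancement at 873, 945, 1023, 1081 cm^-1 and the 1135 cm^-1 shoulder).
#' Marker positions carry a lower qualitative weight because they sit on
#' top of PIP bands.
#'
#' @return data.frame with columns `api`, `position` (cm^-1), `weight`
#' @export
referencePeakTable <- function() {
  rbind(
    data.frame(api = "PIP",
               position = c(728, 762, 850, 890, 1072, 1094, 1461, 1602,
                            1713, 1764),
               weight = 1),
    data.frame(api = "TAZ",
               position = c(1135, 1191, 1312, 1232, 1452, 1385, 1616),
               weight = 1),
    data.frame(api = "TAZ",
               position = c(873, 945, 1023, 1081),
               weight = 0.5)
  )
}

# Local maxima with a simple valley-to-valley prominence (internal).
findLocalMaxima <- function(w, a, minProminence) {
  n <- length(a)
  if (n < 3L) return(integer(0))
  cand <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    j <- i; while (j > 1L && a[j - 1L] <= a[j]) j <- j - 1L
    k <- i; while (k < n && a[k + 1L] <= a[k]) k <- k + 1L
    prom <- a[i] - max(a[j], a[k])
    prom >= minProminence
  }, logical(1))
  cand[keep]
}

#' Match detected peaks against the reference table
#'
#' Detects local maxima of the raw absorbance whose prominence exceeds
#' `promFactor` times a noise scale (the median absolute successive
#' difference of the absorbance), matches them to the reference positions
#' within `matchTolerance`, and evaluates the TAZ presence flag from the
#' I(873)/I(890) ratio statistic against a decision threshold.
#'
#' @param s a [Spectrum-class] covering all table positions
#' @param table reference table as from [referencePeakTable()]
#' @param cfg a [RatioConfig-class] for the marker ratio
#' @param threshold decision threshold on the ratio; the default 0.27 is the
#'   theoretical pure-PIP ratio 0.22 plus a 3-sigma blank margin (see
#'   [estimateDetectionLimits()], whose decision ratio is the principled
#'   source for this value)
#' @param matchTolerance position match tolerance, cm^-1 (default 4)
#' @param promFactor prominence multiplier on the noise scale (default 3)
#' @return a [MarkerReport-class]
#' @export
matchReferencePeaks <- function(s, table = referencePeakTable(),
                                cfg = RatioConfig(), threshold = 0.27,
                                matchTolerance = 4, promFactor = 3) {
  stopifnot(is(s, "Spectrum"))
  w <- wavenumbers(s)
  a <- absorbance(s)
  if (min(w) > min(table$position) || max(w) < max(table$position))
    stop("spectrum range too short to cover all reference positions")
  noise <- stats::median(abs(diff(a)))
  peaks <- w[findLocalMaxima(w, a, minProminence = promFactor * noise)]
  apis <- unique(table$api)
  matched <- lapply(apis, function(api) {
    pos <- table$position[table$api == api]
    pos[vapply(pos, function(p) any(abs(peaks - p) <= matchTolerance),
               logical(1))]
  })
  names(matched) <- apis
  frac <- vapply(apis, function(api)
    length(matched[[api]]) / sum(table$api == api), numeric(1))
  names(frac) <- apis
  ratio <- tryCatch(
    suppressWarnings(peakHeightRatio(s, cfg)),
    error = function(e) NA_real_)
  new("MarkerReport",
      matchedPositions = matched,
      matchFraction = frac,
      tazMarkerRatio = ratio,
      tazFlag = isTRUE(!is.na(ratio) && ratio > threshold))
}

#' Serialize a MarkerReport to JSON
#'
#' @param report a [MarkerReport-class]
#' @param path optional output path; when NULL the JSON string is returned
#' @return the JSON string, invisibly when written to `path`
#' @export
markerReportToJson <- function(report, path = NULL) {
  stopifnot(is(report, "MarkerReport"))
  x <- list(
    matched_positions = report@matchedPositions,
    match_fraction = as.list(report@matchFraction),
    taz_marker_ratio = report@tazMarkerRatio,
    taz_flag = report@tazFlag
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
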