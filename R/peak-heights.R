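#' Baseline-corrected peak heights over a single anchored baseline
#'
#' The baseline is the straight line through the spectrum's absorbance at
#' the two anchor wavenumbers (linearly interpolated where an anchor falls
#' between grid points). For each target position the height is the maximum
#' of `A(v) - B(v)` over the grid points within `+/- apexHalfwidth` of the
#' nominal position (`mode = "apex"`, default), or the corrected absorbance
#' interpolated exactly at the nominal position (`mode = "fixed"`). The apex
#' wavenumber actually used is reported alongside each height for audit.
#'
#' A window whose corrected values are all `<= 0` is flagged as a
#' non-detected peak with a warning; the (non-positive) height is still
#' reported rather than silently clipped.
#'
#' @param s a [Spectrum-class] covering the baseline window
#' @param cfg a [RatioConfig-class]
#' @param positions target positions in cm^-1; default the configured
#'   numerator and denominator peaks
#' @param mode `"apex"` (default) or `"fixed"`
#' @return data.frame with columns `position`, `apex`, `height`, `detected`
#' @examples
#' w <- seq(860, 910, by = 2)
#' bump <- pmax(0, 1 - abs(w - 873) / 6) * 0.05
#' s <- Spectrum(w, 0.1 + bump)
#' correctedHeights(s, RatioConfig())
#' @export
correctedHeights <- function(s, cfg = RatioConfig(), positions = NULL,
                             mode = c("apex", "fixed")) {
  stopifnot(is(s, "Spectrum"), is(cfg, "RatioConfig"))
  mode <- match.arg(mode)
  if (is.null(positions))
    positions <- c(cfg@numeratorPosition, cfg@denominatorPosition)
  w <- wavenumbers(s)
  a <- absorbance(s)
  bl <- cfg@baselineLeft
  br <- cfg@baselineRight
  if (min(w) > bl || max(w) < br)
    stop(sprintf("spectrum [%g, %g] does not cover baseline window [%g, %g]",
                 min(w), max(w), bl, br))
  hw <- cfg@apexHalfwidth
  inWin <- w >= bl & w <= br
  if (sum(inWin) >= 2L && max(diff(w[inWin])) > hw)
    stop("grid spacing exceeds the apex half-width; resample first")
  aL <- interpAbsorbance(s, bl)
  aR <- interpAbsorbance(s, br)
  baselineAt <- function(v) aL + (aR - aL) * (v - bl) / (br - bl)
  out <- lapply(positions, function(pos) {
    lo <- pos - hw
    hi <- pos + hw
    idx <- which(w >= lo & w <= hi)
    if (!length(idx))
      stop(sprintf("no grid points in window [%g, %g] around %g cm-1",
                   lo, hi, pos))
    if (mode == "fixed") {
      h <- interpAbsorbance(s, pos) - baselineAt(pos)
      apex <- pos
    } else {
      corr <- a[idx] - baselineAt(w[idx])
      k <- which.max(corr)
      h <- corr[k]
      apex <- w[idx][k]
    }
    detected <- h > 0
    if (!detected)
      warning(sprintf(
        "non-detected peak at %g cm-1: corrected height %.3g <= 0", pos, h))
    data.frame(position = pos, apex = apex, height = h, detected = detected)
  })
  do.call(rbind, out)
}

#' The peak-height ratio statistic
#'
#' Returns `height(numerator) / height(denominator)` from a table of
#' baseline-corrected heights. The statistic cancels the multiplicative
#' film-deposition scale, which is what makes a single calibration line
#' possible without an internal standard.
#'
#' @param heights output of [correctedHeights()], or a numeric vector named
#'   by position
#' @param cfg the [RatioConfig-class] naming the two positions
#' @param floor smallest admissible denominator height (default `1e-12`)
#' @return the ratio, a single number
#' @export
ratioStatistic <- function(heights, cfg = RatioConfig(), floor = 1e-12) {
  stopifnot(is(cfg, "RatioConfig"))
  pick <- function(pos) {
    if (is.data.frame(heights)) {
      i <- which(abs(heights$position - pos) < 1e-9)
      if (!length(i)) stop("no height recorded for position ", pos)
      heights$height[i[1]]
    } else {
      v <- heights[[as.character(pos)]]
      if (is.null(v) || is.na(v)) stop("no height recorded for position ", pos)
      v
    }
  }
  num <- pick(cfg@numeratorPosition)
  den <- pick(cfg@denominatorPosition)
  if (!is.finite(den) || den <= floor)
    stop(sprintf("denominator peak absent: height at %g cm-1 is %.3g",
                 cfg@denominatorPosition, den))
  num / den
}

#' Peak-height ratio of a spectrum in one call
#'
#' Convenience wrapper: [correctedHeights()] then [ratioStatistic()].
#'
#' @inheritParams correctedHeights
#' @inheritParams ratioStatistic
#' @return the ratio, a single number
#' @export
peakHeightRatio <- function(s, cfg = RatioConfig(), mode = c("apex", "fixed"),
                            floor = 1e-12) {
  mode <- match.arg(mode)
  ratioStatistic(correctedHeights(s, cfg, mode = mode), cfg, floor = floor)
}
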