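#' Construct a Spectrum
#'
#' Builds a validated [Spectrum-class] from parallel wavenumber and
#' absorbance vectors. Descending wavenumber order (common in infrared
#' exports) is normalised to ascending; duplicate wavenumbers are rejected.
#'
#' @param wavenumbers numeric vector, cm^-1 (ascending or descending)
#' @param absorbance numeric vector of the same length, a.u.
#' @param meta named list of metadata (sample id, replicate, role, ...)
#' @return a [Spectrum-class]
#' @examples
#' s <- Spectrum(c(600, 604, 608), c(0.1, 0.2, 0.1))
#' wavenumbers(s)
#' @export
Spectrum <- function(wavenumbers, absorbance, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance differ in length")
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers at position(s): ",
         paste(which(duplicated(wavenumbers)), collapse = ", "))
  if (length(wavenumbers) >= 2L && all(diff(wavenumbers) < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  }
  new("Spectrum", wavenumbers = wavenumbers, absorbance = absorbance,
      meta = meta)
}

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("absorbance", "Spectrum", function(object) object@absorbance)

#' @rdname accessors
#' @export
setMethod("specMeta", "Spectrum", function(object) object@meta)

#' @describeIn Spectrum number of grid points
#' @param x a Spectrum
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavenumbers))

#' @describeIn Spectrum two-column data.frame view
#' @param row.names,optional,... ignored, present for generic compatibility
#' @export
setMethod("as.data.frame", "Spectrum",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(wavenumber = x@wavenumbers, absorbance = x@absorbance)
  })

#' @describeIn Spectrum scale the absorbance by a positive factor
#' @param e1,e2 a Spectrum and a numeric scalar (either order)
#' @export
setMethod("*", signature("Spectrum", "numeric"), function(e1, e2) {
  new("Spectrum", wavenumbers = e1@wavenumbers,
      absorbance = e1@absorbance * e2, meta = e1@meta)
})

#' @describeIn Spectrum scale the absorbance by a positive factor
#' @export
setMethod("*", signature("numeric", "Spectrum"), function(e1, e2) e2 * e1)

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("Spectrum: %d points, %.1f-%.1f cm-1 (step ~%.2f)\n",
              length(w), min(w), max(w), mean(diff(w))))
  id <- object@meta$sample_id
  if (!is.null(id)) cat("  sample_id:", id, "\n")
  role <- object@meta$role
  if (!is.null(role)) cat("  role:", role, "\n")
})

#' Construct a RatioConfig
#'
#' @param numeratorPosition,denominatorPosition peak positions in cm^-1;
#'   defaults 873 (TAZ-enhanced) and 890 (PIP).
#' @param baselineLeft,baselineRight anchor wavenumbers of the single
#'   straight baseline; defaults 862 and 905 cm^-1.
#' @param apexHalfwidth half-width (cm^-1) of the apex search window around
#'   each nominal position; default 4 (the instrument resolution).
#' @return a validated [RatioConfig-class]
#' @export
RatioConfig <- function(numeratorPosition = 873, denominatorPosition = 890,
                        baselineLeft = 862, baselineRight = 905,
                        apexHalfwidth = 4) {
  new("RatioConfig",
      numeratorPosition = numeratorPosition,
      denominatorPosition = denominatorPosition,
      baselineLeft = baselineLeft,
      baselineRight = baselineRight,
      apexHalfwidth = apexHalfwidth)
}

setMethod("show", "RatioConfig", function(object) {
  cat(sprintf(
    "RatioConfig: I(%g)/I(%g), baseline %g-%g cm-1, apex +/- %g cm-1\n",
    object@numeratorPosition, object@denominatorPosition,
    object@baselineLeft, object@baselineRight, object@apexHalfwidth))
})

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation of the absorbance onto a new, strictly increasing
#' grid that must lie within the spectrum's range (no extrapolation).
#' Metadata are preserved.
#'
#' @param s a [Spectrum-class]
#' @param grid numeric target grid, strictly increasing, within
#'   `range(wavenumbers(s))`
#' @return a [Spectrum-class] on `grid`
#' @export
resampleSpectrum <- function(s, grid) {
  stopifnot(is(s, "Spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) < 1L || !all(diff(grid) > 0))
    stop("target grid must be strictly increasing")
  w <- wavenumbers(s)
  if (min(grid) < min(w) || max(grid) > max(w))
    stop(sprintf(
      "extrapolation requested: target [%g, %g] outside spectrum [%g, %g]",
      min(grid), max(grid), min(w), max(w)))
  a <- stats::approx(w, absorbance(s), xout = grid, method = "linear")$y
  if (length(grid) == 1L) {
    # a single-point query cannot form a valid Spectrum; return the value
    return(a)
  }
  new("Spectrum", wavenumbers = grid, absorbance = a, meta = specMeta(s))
}

# Linear interpolation of the absorbance at one wavenumber (internal).
interpAbsorbance <- function(s, at) {
  stats::approx(s@wavenumbers, s@absorbance, xout = at, method = "linear",
                rule = 1)$y
}
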