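#' Read an infrared spectrum from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`csv-xy`}{two numeric columns (wavenumber cm^-1, absorbance),
#'     comma or tab separated, optional single header line; comment lines
#'     start with `#`. Comments of the form `# key: value` are captured
#'     into the spectrum metadata.}
#'   \item{`jcamp`}{a minimal JCAMP-DX subset: a single
#'     `##XYDATA=(X++(Y..Y))` block with plain (AFFN) numbers. Compressed
#'     encodings (SQZ/DIF/DUP) are rejected.}
#' }
#' Descending wavenumber order is normalised to ascending.
#'
#' @param path path to the file
#' @param dialect `"csv-xy"` (default) or `"jcamp"`
#' @return a [Spectrum-class]
#' @export
readSpectrum <- function(path, dialect = c("csv-xy", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         "csv-xy" = readSpectrumCsvXy(path),
         "jcamp"  = readSpectrumJcamp(path))
}

readSpectrumCsvXy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  meta <- list()
  xs <- numeric(0)
  ys <- numeric(0)
  rows <- integer(0)
  headerSkipped <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      kv <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1]]
      if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
      next
    }
    fields <- trimws(strsplit(line, "[,\t]")[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L)
      stop(sprintf("line %d of %s: expected two columns", i, path))
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      if (!headerSkipped && !length(xs)) {
        headerSkipped <- TRUE  # a single non-numeric header line is allowed
        next
      }
      stop(sprintf("line %d of %s: non-numeric row '%s'", i, path, line))
    }
    xs <- c(xs, vals[1]); ys <- c(ys, vals[2]); rows <- c(rows, i)
  }
  if (length(xs) < 2L)
    stop("fewer than 2 numeric rows in ", path)
  dup <- which(duplicated(xs))
  if (length(dup))
    stop(sprintf("duplicate wavenumber %g at line %d of %s",
                 xs[dup[1]], rows[dup[1]], path))
  meta$source_path <- path
  Spectrum(xs, ys, meta = meta)
}

readSpectrumJcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    pat <- paste0("^##", key, "=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  }
  xyIdx <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(xyIdx))
    stop("no ##XYDATA record in ", path)
  form <- gsub("\\s", "", sub("^##XYDATA=", "", lines[xyIdx[1]],
                              ignore.case = TRUE))
  if (toupper(form) != "(X++(Y..Y))")
    stop("unsupported XYDATA form '", form,
         "': only (X++(Y..Y)) with AFFN numbers is supported")
  xf <- suppressWarnings(as.numeric(hdr("XFACTOR"))); if (is.na(xf)) xf <- 1
  yf <- suppressWarnings(as.numeric(hdr("YFACTOR"))); if (is.na(yf)) yf <- 1
  firstx <- suppressWarnings(as.numeric(hdr("FIRSTX")))
  lastx <- suppressWarnings(as.numeric(hdr("LASTX")))
  npoints <- suppressWarnings(as.numeric(hdr("NPOINTS")))
  deltax <- suppressWarnings(as.numeric(hdr("DELTAX")))
  if (is.na(deltax)) {
    if (is.na(firstx) || is.na(lastx) || is.na(npoints) || npoints < 2)
      stop("need DELTAX or FIRSTX/LASTX/NPOINTS in ", path)
    deltax <- (lastx - firstx) / (npoints - 1)
  }
  end <- grep("^##END", lines[-seq_len(xyIdx[1])], ignore.case = TRUE)
  stopLine <- if (length(end)) xyIdx[1] + end[1] - 1L else length(lines)
  body <- lines[seq(xyIdx[1] + 1L, stopLine)]
  body <- body[!grepl("^##", body)]
  body <- trimws(body[nzchar(trimws(body))])
  if (!length(body)) stop("empty XYDATA block in ", path)
  numTok <- "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"
  xs <- numeric(0); ys <- numeric(0)
  for (line in body) {
    toks <- regmatches(line, gregexpr(numTok, line))[[1]]
    clean <- gsub("\\s+", " ", gsub(numTok, "", line))
    if (grepl("[^ ,;+-]", clean))
      stop("compressed or non-AFFN XYDATA in ", path,
           " (SQZ/DIF/DUP encodings are not supported): '", line, "'")
    if (length(toks) < 2L)
      stop("XYDATA line with fewer than 2 values in ", path, ": '", line, "'")
    v <- as.numeric(toks)
    x0 <- v[1] * xf
    yy <- v[-1] * yf
    xs <- c(xs, x0 + (seq_along(yy) - 1L) * deltax)
    ys <- c(ys, yy)
  }
  meta <- list(source_path = path, dialect = "jcamp")
  ttl <- hdr("TITLE"); if (!is.na(ttl)) meta$title <- ttl
  Spectrum(xs, ys, meta = meta)
}

#' Write a spectrum as csv-xy
#'
#' Full-precision (`%.17g`) two-column CSV with metadata as `# key: value`
#' comment lines; `readSpectrum()` round-trips grid and values bit-exactly.
#'
#' @param s a [Spectrum-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "Spectrum"))
  meta <- specMeta(s)
  meta <- meta[vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, as.character,
                                                 character(1)))
  body <- sprintf("%.17g,%.17g", wavenumbers(s), absorbance(s))
  writeLines(c(hdr, "wavenumber,absorbance", body), path)
  invisible(path)
}
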