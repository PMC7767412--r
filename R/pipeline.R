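#' Default run configuration
#'
#' The settings that reproduce the published method: the I(873)/I(890)
#' statistic over the 862-905 cm^-1 anchored baseline, replicate-level
#' calibration fit, k = 3 blank decision rule with LOQ = 3 x LOD, and
#' replicate-only uncertainty.
#'
#' @return named list of settings
#' @export
defaultRunConfig <- function() {
  list(
    numerator_position = 873,
    denominator_position = 890,
    baseline_left = 862,
    baseline_right = 905,
    apex_halfwidth = 4,
    height_mode = "apex",
    fit_mode = "on_replicates",
    k_detect = 3,
    loq_factor = 3,
    loq_method = "factor",
    uncertainty_mode = "replicate",
    log_level = "info"
  )
}

#' Read a run configuration file (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [defaultRunConfig()]. The configuration is validated before any
#' computation.
#'
#' @param path path to a YAML or JSON configuration file, or NULL for
#'   pure defaults
#' @return named list of settings
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  ratioConfigFromRun(cfg)  # validates the geometric fields
  stopifnot(cfg$fit_mode %in% c("on_means", "on_replicates"),
            cfg$height_mode %in% c("apex", "fixed"),
            cfg$loq_method %in% c("factor", "ratio"),
            cfg$uncertainty_mode %in% c("replicate", "extended"),
            cfg$k_detect >= 0, cfg$loq_factor > 0)
  cfg
}

ratioConfigFromRun <- function(cfg) {
  RatioConfig(numeratorPosition = cfg$numerator_position,
              denominatorPosition = cfg$denominator_position,
              baselineLeft = cfg$baseline_left,
              baselineRight = cfg$baseline_right,
              apexHalfwidth = cfg$apex_halfwidth)
}

#' Read and validate a sample manifest
#'
#' A delimited table (comma or tab, with header) with columns
#' `spectrum_path`, `sample_id`, `role` (standard/blank/unknown), `c_pip`,
#' `c_taz` (% w/w, empty for blanks and unknowns) and `replicate_index`.
#' Standards must carry a closed composition; unknowns must carry none.
#' Relative spectrum paths resolve against the manifest's directory.
#'
#' @param path manifest file
#' @return data.frame with resolved paths
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  mf <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("spectrum_path", "sample_id", "role", "c_pip", "c_taz",
            "replicate_index")
  missing <- setdiff(need, names(mf))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(mf$role %in% c("standard", "blank", "unknown")))
    stop("manifest roles must be standard, blank or unknown")
  mf$c_pip <- suppressWarnings(as.numeric(mf$c_pip))
  mf$c_taz <- suppressWarnings(as.numeric(mf$c_taz))
  std <- mf$role == "standard"
  if (any(std & (is.na(mf$c_pip) | is.na(mf$c_taz))))
    stop("standards must carry both compositions")
  if (any(std) && any(abs(mf$c_pip[std] + mf$c_taz[std] - 100) > 1e-9))
    stop("standard compositions violate closure c_pip + c_taz = 100")
  unk <- mf$role == "unknown"
  if (any(unk & (!is.na(mf$c_pip) | !is.na(mf$c_taz))))
    stop("unknowns must not carry compositions")
  base <- dirname(normalizePath(path))
  abs <- file.path(base, mf$spectrum_path)
  mf$spectrum_path <- ifelse(file.exists(mf$spectrum_path),
                             mf$spectrum_path, abs)
  gone <- !file.exists(mf$spectrum_path)
  if (any(gone))
    stop("missing spectrum file(s): ",
         paste(utils::head(mf$spectrum_path[gone], 5), collapse = ", "))
  mf
}

pipelineLog <- function(cfg, ...) {
  if (identical(cfg$log_level, "silent")) return(invisible())
  message("[atrquant] ", ...)
}

manifestRatios <- function(mf, rcfg, mode) {
  vapply(seq_len(nrow(mf)), function(i) {
    s <- readSpectrum(mf$spectrum_path[i])
    suppressWarnings(peakHeightRatio(s, rcfg, mode = mode))
  }, numeric(1))
}

#' Calibrate from a manifest
#'
#' Reads every standard spectrum, computes per-replicate peak-height
#' ratios, summarises each standard (mean ratio, RSD), fits the
#' calibration line and writes `model.json` plus `standards_table.csv`
#' (one row per standard, mirroring the layout of a published standards
#' table) into `outDir`.
#'
#' @param manifest path to a manifest file, or a data.frame from
#'   [readManifest()]
#' @param config run configuration list (see [readRunConfig()])
#' @param outDir output directory, created if needed
#' @return invisibly, list with `model`, `table`, `modelPath`
#' @export
runCalibrate <- function(manifest, config = defaultRunConfig(),
                         outDir = ".") {
  mf <- if (is.data.frame(manifest)) manifest else readManifest(manifest)
  std <- mf[mf$role == "standard", , drop = FALSE]
  if (length(unique(std$c_pip)) < 3L)
    stop("need at least 3 distinct standard compositions to calibrate")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rcfg <- ratioConfigFromRun(config)
  std$ratio <- manifestRatios(std, rcfg, config$height_mode)
  tab <- do.call(rbind, lapply(split(std, std$c_pip), function(g) {
    sm <- replicateSummary(g$ratio)
    data.frame(c_taz = g$c_taz[1], c_pip = g$c_pip[1],
               mean_ratio = sm$mean, rsd_pct = sm$rsd, n = sm$n)
  }))
  tab <- tab[order(-tab$c_taz), , drop = FALSE]
  rownames(tab) <- NULL
  model <- fitCalibration(
    data.frame(cPip = std$c_pip, cTaz = std$c_taz, ratio = std$ratio),
    fitMode = config$fit_mode, cfg = rcfg)
  modelPath <- file.path(outDir, "model.json")
  writeCalibrationModel(model, modelPath)
  utils::write.csv(tab, file.path(outDir, "standards_table.csv"),
                   row.names = FALSE)
  pipelineLog(config, sprintf(
    "calibrate: %d standards, %d films; slope %.4f intercept %.4f R2 %.5f",
    nrow(tab), nrow(std), slope(model), intercept(model), rSquared(model)))
  pipelineLog(config, "model md5: ",
              unname(tools::md5sum(modelPath)),
              "; package ", as.character(utils::packageVersion("atrquant")))
  invisible(list(model = model, table = tab, modelPath = modelPath))
}

#' Quantify unknowns (and blanks) from a manifest
#'
#' Each unknown sample's replicate ratios are summarised and inverted
#' through the calibration line into a [QuantResult-class]; a failing
#' sample (e.g. ratio below the intercept) is recorded and the batch
#' continues. Blank-role rows, when present, yield [BlankStats-class] and
#' [DetectionLimits-class] appended to the report. Writes
#' `quant_results.json` and a human-readable `quant_results.txt`.
#'
#' @param manifest path or data.frame (see [readManifest()])
#' @param model a [CalibrationModel-class] or path to `model.json`
#' @param config run configuration list
#' @param outDir output directory
#' @return invisibly, list with `results` (list of QuantResult), `errors`
#'   (named character), `blanks`, `limits`
#' @export
runQuantify <- function(manifest, model, config = defaultRunConfig(),
                        outDir = ".") {
  mf <- if (is.data.frame(manifest)) manifest else readManifest(manifest)
  if (is.character(model)) model <- readCalibrationModel(model)
  stopifnot(is(model, "CalibrationModel"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rcfg <- ratioConfig(model)
  unk <- mf[mf$role == "unknown", , drop = FALSE]
  if (!nrow(unk)) stop("manifest contains no unknown samples")
  unk$ratio <- vapply(seq_len(nrow(unk)), function(i) {
    tryCatch({
      s <- readSpectrum(unk$spectrum_path[i])
      suppressWarnings(peakHeightRatio(s, rcfg, mode = config$height_mode))
    }, error = function(e) NA_real_)
  }, numeric(1))
  results <- list()
  errors <- character()
  for (sid in unique(unk$sample_id)) {
    ratios <- unk$ratio[unk$sample_id == sid]
    res <- tryCatch({
      if (anyNA(ratios)) {
        # re-read one failing replicate to surface its message
        i <- which(unk$sample_id == sid & is.na(unk$ratio))[1]
        s <- readSpectrum(unk$spectrum_path[i])
        suppressWarnings(peakHeightRatio(s, rcfg, mode = config$height_mode))
        stop("replicate ratio could not be computed")
      }
      quantifySample(model, ratios, sampleId = sid,
                     uncertaintyMode = config$uncertainty_mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[sid] <- conditionMessage(res)
      pipelineLog(config, "sample ", sid, " failed: ", errors[sid])
    } else results[[sid]] <- res
  }
  blanks <- NULL
  limits <- NULL
  blk <- mf[mf$role == "blank", , drop = FALSE]
  if (nrow(blk) >= 2L) {
    blanks <- blankStats(manifestRatios(blk, rcfg, config$height_mode))
    limits <- estimateDetectionLimits(model, blanks,
                                      kDetect = config$k_detect,
                                      loqFactor = config$loq_factor,
                                      method = config$loq_method)
  }
  report <- list(
    results = lapply(results, function(r) list(
      sample_id = r@sampleId, c_pip = r@cPip, c_taz = r@cTaz,
      sd = r@sdComposition, mean_ratio = r@meanRatio,
      ratio_rsd_pct = r@ratioRsd, n_replicates = r@nReplicates,
      notes = r@notes)),
    errors = as.list(errors),
    blanks = if (!is.null(blanks)) list(
      mean_ratio = blanks@meanRatio, sd_ratio = blanks@sdRatio,
      n_blanks = blanks@nBlanks),
    detection_limits = if (!is.null(limits)) list(
      lod_taz = limits@lodTaz, loq_taz = limits@loqTaz,
      k_detect = limits@kDetect, loq_factor = limits@loqFactor,
      method = limits@method))
  jsonlite::write_json(report, file.path(outDir, "quant_results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  txt <- c(sprintf("%-16s %10s %10s %8s %8s %4s", "sample", "C_PIP",
                   "C_TAZ", "+/-", "RSD%", "n"),
           vapply(results, function(r) sprintf(
             "%-16s %10.2f %10.2f %8.2f %8.2f %4d", r@sampleId, r@cPip,
             r@cTaz, r@sdComposition, r@ratioRsd, r@nReplicates),
             character(1)))
  if (!is.null(limits))
    txt <- c(txt, sprintf("LOD = %.3f %% w/w TAZ, LOQ = %.3f %% w/w TAZ",
                          limits@lodTaz, limits@loqTaz))
  writeLines(txt, file.path(outDir, "quant_results.txt"))
  pipelineLog(config, sprintf("quantify: %d samples ok, %d failed",
                              length(results), length(errors)))
  invisible(list(results = results, errors = errors, blanks = blanks,
                 limits = limits))
}

#' Simulate a complete study dataset
#'
#' Writes csv-xy spectra for the six calibration standards (three replicate
#' films each), a set of blank pure-PIP films and one unknown sample at the
#' formulation's nominal 89:11 PIP:TAZ composition, plus `manifest.csv` and
#' `ground_truth.json` (generator settings and true compositions).
#' Idempotent for a fixed seed.
#'
#' @param cfg a [GeneratorConfig-class]
#' @param outDir output directory
#' @param standards data.frame with columns `cPip`, `cTaz` (default the six
#'   published standard compositions)
#' @param nReps replicate films per standard and per unknown (default 3)
#' @param nBlanks number of blank films (default 20)
#' @param unknown numeric `c(cPip, cTaz)` of the unknown (default 89:11)
#' @return invisibly, the manifest path
#' @export
runSimulate <- function(cfg = generatorConfig(), outDir = "simdata",
                        standards = data.frame(
                          cPip = c(50, 55, 75, 85, 90, 95),
                          cTaz = c(50, 45, 25, 15, 10, 5)),
                        nReps = 3, nBlanks = 20, unknown = c(89, 11)) {
  stopifnot(is(cfg, "GeneratorConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(s, fname, sid, role, cPip, cTaz, rep) {
    writeSpectrum(s, file.path(outDir, fname))
    rows[[length(rows) + 1L]] <<- data.frame(
      spectrum_path = fname, sample_id = sid, role = role,
      c_pip = ifelse(role == "standard", cPip, NA_real_),
      c_taz = ifelse(role == "standard", cTaz, NA_real_),
      replicate_index = rep)
  }
  for (i in seq_len(nrow(standards))) {
    cp <- standards$cPip[i]; ct <- standards$cTaz[i]
    reps <- synthMixtureReplicates(cp, ct, nReps, cfg, salt = 1L)
    for (r in seq_along(reps))
      emit(reps[[r]], sprintf("std_%02.0f_%02.0f_r%d.csv", ct, cp, r),
           sprintf("std_%02.0f_%02.0f", ct, cp), "standard", cp, ct, r)
  }
  blanks <- synthBlankPipFilms(nBlanks, cfg)
  for (i in seq_along(blanks))
    emit(blanks[[i]], sprintf("blank_%02d.csv", i), sprintf("blank_%02d", i),
         "blank", NA, NA, i)
  unkReps <- synthMixtureReplicates(unknown[1], unknown[2], nReps, cfg,
                                    salt = 2L)
  for (r in seq_along(unkReps))
    emit(unkReps[[r]], sprintf("unknown_r%d.csv", r), "unknown_01",
         "unknown", NA, NA, r)
  mf <- do.call(rbind, rows)
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(mf, manifestPath, row.names = FALSE, na = "")
  truth <- list(
    seed = cfg@seed,
    film_scale_sd = cfg@filmScaleSd,
    additive_noise_sd = cfg@additiveNoiseSd,
    drift_slope_range = cfg@driftSlopeRange,
    drift_offset_range = cfg@driftOffsetRange,
    standards = standards,
    unknown = list(c_pip = unknown[1], c_taz = unknown[2]),
    n_blanks = nBlanks, n_reps = nReps,
    band_tables = cfg@bandTables)
  jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifestPath)
}
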