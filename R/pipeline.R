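# End-to-end experiment orchestration: generate or load cases, resample,
# preprocess, segment, evaluate, test, and write a report directory.

.configDefaults <- function() {
  list(
    data = list(phantom = list(n = 20, master_seed = 1,
                               tumor_volume_range = c(1, 200),
                               side_fractions = c(left = 0.45, right = 0.55),
                               grid_shape = c(96, 96, 96),
                               noise_sd = 0.009, bias_amplitude = 0.01)),
    sequences = c("T1w", "T2wfs"),
    variants = c("unprocessed", "inverted", "inverted_black"),
    backend = list(type = "windows", windows = NULL, scale = NULL,
                   command = NULL, class_mapping = NULL),
    mapping = NULL,
    preprocess = list(clip = c(0, 3000), percentile = 1),
    resample_mm = 1,
    bootstrap = list(B = 2000, seed = 1),
    output_dir = "invertseg_report"
  )
}

#' Validate an experiment configuration
#'
#' Reads a YAML experiment configuration (or takes an equivalent list),
#' fills defaults (clip 0-3000, background percentile 1, bootstrap
#' B = 2000, 1 mm resampling, phantom cohort source), and validates it
#' strictly: unknown keys, misspelled variant or sequence names, empty
#' selections, and missing referenced paths are all errors.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The validated config list (invisibly classed
#'   `"invertseg_config"`).
#' @seealso [runExperiment()]
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a YAML file or a list")
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config keys: %s (allowed: %s)",
          paste(unknown, collapse = ", "),
          paste(names(defaults), collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  if (!length(cfg$sequences)) stopf("'sequences' must not be empty")
  badSeq <- setdiff(cfg$sequences, c("T1w", "T2wfs", "CT"))
  if (length(badSeq))
    stopf("unknown sequences: %s (allowed: T1w, T2wfs, CT)",
          paste(badSeq, collapse = ", "))
  if (!length(cfg$variants)) stopf("'variants' must not be empty")
  badVar <- setdiff(cfg$variants, variantNames())
  if (length(badVar))
    stopf("unknown variants: %s (allowed: %s)",
          paste(badVar, collapse = ", "),
          paste(variantNames(), collapse = ", "))
  if (!cfg$backend$type %in% c("windows", "external"))
    stopf("backend type must be \"windows\" or \"external\"")
  if (cfg$backend$type == "external" && is.null(cfg$backend$command))
    stopf("external backend requires 'command'")
  for (p in c(cfg$backend$windows, cfg$backend$class_mapping, cfg$mapping))
    if (!is.null(p) && !file.exists(p)) stopf("referenced path missing: %s", p)
  if (!is.null(config$data$directory)) {
    cfg$data <- list(directory = config$data$directory)
    if (!dir.exists(cfg$data$directory))
      stopf("data directory not found: %s", cfg$data$directory)
  }
  if (cfg$resample_mm <= 0) stopf("'resample_mm' must be positive")
  if (cfg$preprocess$clip[1] >= cfg$preprocess$clip[2])
    stopf("clip range must be increasing")
  class(cfg) <- c("invertseg_config", "list")
  invisible(cfg)
}

.loadCases <- function(cfg) {
  if (!is.null(cfg$data$directory)) {
    dirs <- list.dirs(cfg$data$directory, recursive = FALSE)
    cases <- lapply(dirs, function(d) {
      list(id = basename(d),
           volumes = list(
             CT = file.path(d, "ct.nii.gz"),
             T1w = file.path(d, "t1.nii.gz"),
             T2wfs = file.path(d, "t2fs.nii.gz")),
           truth = file.path(d, "truth.nii.gz"))
    })
    names(cases) <- vapply(cases, `[[`, "", "id")
    return(list(kind = "directory", cases = cases))
  }
  ph <- cfg$data$phantom
  cohort <- generateCohort(
    n = ph$n, masterSeed = ph$master_seed,
    tumorVolumeRange = unlist(ph$tumor_volume_range),
    sideFractions = unlist(ph$side_fractions),
    gridShape = as.integer(rep_len(unlist(ph$grid_shape), 3L)),
    noiseSD = ph$noise_sd, biasAmplitude = ph$bias_amplitude)
  list(kind = "phantom", cohort = cohort)
}

.caseVolume <- function(src, caseName, sequence) {
  if (src$kind == "phantom") {
    cs <- src$cohort[[caseName]]
    switch(sequence, CT = cs@ct, T1w = cs@t1, T2wfs = cs@t2fs)
  } else {
    readVolume(src$cases[[caseName]]$volumes[[sequence]],
               modality = sequence)
  }
}

.caseTruth <- function(src, caseName) {
  if (src$kind == "phantom") src$cohort[[caseName]]@truth
  else readLabelMap(src$cases[[caseName]]$truth)
}

.makeSegmenter <- function(cfg) {
  if (cfg$backend$type == "windows") {
    windows <- if (is.null(cfg$backend$windows)) defaultWindows()
               else readWindows(cfg$backend$windows)
    scale <- cfg$backend$scale
    function(v) windowSegment(v, windows, scale = scale)
  } else {
    function(v) externalSegment(cfg$backend$command, v,
                                classMapping = cfg$backend$class_mapping)
  }
}

#' Run an end-to-end experiment
#'
#' For every case x sequence x preprocessing variant in the configuration:
#' resample to the working isotropic resolution, preprocess, segment,
#' and evaluate against the reference labels. Writes to the output
#' directory: the full evaluation table (`eval_table.csv`), mean-DSC
#' summaries with bootstrap confidence intervals (`summary.csv`), paired
#' variant comparisons for the across-class mean and for the tumor class
#' (`stats_mean.csv`, `stats_tumor.csv`), tumor localization counts
#' (`localization.csv`), volume-stratified tumor DSC (`volume_strata.csv`),
#' a JSON manifest (config, config hash, package version, seeds), and a
#' per-case log. A backend failure on one case is recorded and the run
#' continues; the run errors only if more than half the case-level steps
#' fail.
#'
#' @param config A config path or list, validated via [validateConfig()].
#' @return Invisibly, a list with the output directory and the in-memory
#'   tables (`eval`, `summary`, `stats_mean`, `stats_tumor`,
#'   `localization`, `strata`).
#' @export
runExperiment <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$output_dir, "log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  logf <- function(...) {
    writeLines(sprintf(...), logCon)
  }

  src <- .loadCases(cfg)
  caseNames <- if (src$kind == "phantom") names(src$cohort)
               else names(src$cases)
  segment <- .makeSegmenter(cfg)

  records <- list()
  locRows <- list()
  failures <- 0L
  attempts <- 0L
  for (cn in caseNames) {
    truth <- resampleIsotropic(.caseTruth(src, cn), cfg$resample_mm)
    mapping <- if (is.null(cfg$mapping)) identityMapping(truth) else {
      mp <- jsonlite::read_json(cfg$mapping, simplifyVector = TRUE)
      stats::setNames(as.character(mp), names(mp))
    }
    tumorId <- vocabulary(truth)["tumor"]
    for (sq in cfg$sequences) {
      vol <- resampleIsotropic(.caseVolume(src, cn, sq), cfg$resample_mm)
      for (vr in cfg$variants) {
        attempts <- attempts + 1L
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
          pv <- preprocessVolume(vol, PreprocessVariant(
            vr, clipLo = cfg$preprocess$clip[1],
            clipHi = cfg$preprocess$clip[2],
            backgroundPercentile = cfg$preprocess$percentile))
          pred <- segment(pv)
          rec <- evaluateCase(pred, truth, mapping = mapping, case_id = cn,
                              sequence = sq, variant = vr)
          if (!is.na(tumorId)) {
            predIds <- vocabulary(pred)[names(mapping)[mapping == "tumor"]]
            loc <- classifyLocalization(
              array(pred@data %in% stats::na.omit(predIds), dim(pred@data)),
              truth@data == tumorId)
            locRows[[length(locRows) + 1L]] <- data.frame(
              case_id = cn, sequence = sq, variant = vr,
              localization = loc, stringsAsFactors = FALSE)
          }
          rec
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- failures + 1L
          logf("case=%s seq=%s variant=%s FAILED: %s", cn, sq, vr,
               conditionMessage(res))
        } else {
          records[[length(records) + 1L]] <- res
          logf("case=%s seq=%s variant=%s ok (%.2fs)", cn, sq, vr,
               proc.time()[["elapsed"]] - t0)
        }
      }
    }
  }
  if (failures > attempts / 2)
    stopf("more than half of all case steps failed (%d of %d); see %s",
          failures, attempts, logPath)
  evalTable <- do.call(rbind, records)
  locTable <- if (length(locRows)) do.call(rbind, locRows) else NULL

  summary <- summarizeDice(evalTable, B = cfg$bootstrap$B,
                           seed = cfg$bootstrap$seed)
  statsMean <- statsTumor <- NULL
  if (length(cfg$variants) >= 2) {
    prs <- utils::combn(cfg$variants, 2, simplify = FALSE)
    statsMean <- compareVariants(evalTable, pairs = prs, level = "mean")
    if ("tumor" %in% evalTable$class_name)
      statsTumor <- compareVariants(evalTable, pairs = prs, level = "tumor")
  }
  locCounts <- if (!is.null(locTable)) {
    agg <- stats::aggregate(case_id ~ sequence + variant + localization,
                            data = locTable, FUN = length)
    names(agg)[names(agg) == "case_id"] <- "n"
    agg[order(agg$sequence, agg$variant, agg$localization), , drop = FALSE]
  } else NULL
  tumorRecs <- evalTable[evalTable$class_name == "tumor", , drop = FALSE]
  strata <- NULL
  if (nrow(tumorRecs)) {
    grp <- interaction(tumorRecs$sequence, tumorRecs$variant, drop = TRUE)
    strata <- do.call(rbind, lapply(levels(grp), function(g) {
      sub <- tumorRecs[grp == g, , drop = FALSE]
      if (nrow(sub) < 2) return(NULL)
      st <- stratifyByVolume(sub)
      data.frame(sequence = sub$sequence[1], variant = sub$variant[1],
                 median_volume_cm3 = st$median_volume_cm3,
                 mean_dsc_below = st$mean_dsc_below,
                 mean_dsc_above = st$mean_dsc_above,
                 n_below = st$n_below, n_above = st$n_above,
                 stringsAsFactors = FALSE)
    }))
  }

  wcsv <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(cfg$output_dir, name), row.names = FALSE)
  }
  wcsv(evalTable, "eval_table.csv")
  wcsv(summary, "summary.csv")
  wcsv(statsMean, "stats_mean.csv")
  wcsv(statsTumor, "stats_tumor.csv")
  wcsv(locCounts, "localization.csv")
  wcsv(strata, "volume_strata.csv")

  cfgPlain <- unclass(cfg)
  manifest <- list(
    package = "invertseg",
    version = as.character(utils::packageVersion("invertseg")),
    config = cfgPlain,
    config_hash = objectHash(cfgPlain),
    n_cases = length(caseNames),
    failures = failures)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done: %d records, %d failures", nrow(evalTable), failures)

  invisible(list(output_dir = cfg$output_dir, eval = evalTable,
                 summary = summary, stats_mean = statsMean,
                 stats_tumor = statsTumor, localization = locCounts,
                 strata = strata, manifest = manifest))
}
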