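## End-to-end pipeline: simulate -> extract-pe -> analyze -> report, wired
## through plain files in an artifact directory so each stage can be re-run
## and audited on its own. Configuration is a YAML file.

logMsg <- function(level, current, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[current]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Read and validate a pipeline configuration
#'
#' The YAML configuration has a top-level `seed` plus `simulate` and
#' `analyze` blocks (see the packaged example under
#' `system.file("extdata", "demo-config.yaml", package = "peLaterality")`).
#' All validation happens here, before any computation.
#'
#' @param path YAML file path.
#' @param seed optional integer overriding the configured seed.
#' @return The validated configuration list.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  sim <- cfg$simulate %||% list()
  an <- cfg$analyze %||% list()
  an$trim <- as.numeric(an$trim %||% 0.2)
  if (is.na(an$trim) || an$trim < 0 || an$trim >= 0.5)
    stop("config: 'analyze.trim' must be in [0, 0.5)")
  an$alpha <- as.numeric(an$alpha %||% 0.05)
  if (is.na(an$alpha) || an$alpha <= 0 || an$alpha >= 1)
    stop("config: 'analyze.alpha' must be in (0, 1)")
  an$threshold_basis <- an$threshold_basis %||% "full_map"
  if (!an$threshold_basis %in% c("full_map", "nonnegative_map"))
    stop("config: unknown 'analyze.threshold_basis'")
  an$designs <- an$designs %||%
    c("hemispheric", "within_group", "between_group")
  bad <- setdiff(an$designs,
                 c("hemispheric", "within_group", "between_group"))
  if (length(bad)) stop("config: unknown design(s): ",
                        paste(bad, collapse = ", "))
  an$group_filters <- an$group_filters %||% "all"
  bad <- setdiff(an$group_filters, c("all", "LH", "RH"))
  if (length(bad)) stop("config: unknown group filter(s): ",
                        paste(bad, collapse = ", "))
  cfg$analyze <- an
  # building the spec validates all simulate fields
  cfg$simulate <- sim
  invisible(cohortSpecFromConfig(cfg))
  cfg
}

# Translate the config's simulate block into a SyntheticCohortSpec.
cohortSpecFromConfig <- function(cfg) {
  sim <- cfg$simulate %||% list()
  syntheticCohortSpec(
    nPerGroup = sim$n_per_group %||% 70L,
    nParcelsPerHemi = sim$n_parcels_per_hemi %||% 180L,
    verticesPerParcel = sim$vertices_per_parcel %||% 50L,
    baselineMu = sim$baseline_mu %||% 0.5,
    parcelActivation = sim$parcel_activation,
    lateralityDelta = sim$laterality_delta,
    groupEffect = sim$group_effect,
    subjectSd = sim$subject_sd %||% 0.5,
    vertexSd = sim$vertex_sd %||% 1,
    contaminationProb = sim$contamination_prob %||% 0,
    contaminationScale = sim$contamination_scale %||% 3,
    contrast = sim$contrast %||% "STORY",
    seed = cfg$seed)
}

stageSimulate <- function(cfg, outdir, logLevel = "info") {
  spec <- cohortSpecFromConfig(cfg)
  cohort <- simulateCohort(spec)
  mapDir <- file.path(outdir, "maps")
  dir.create(mapDir, recursive = TRUE, showWarnings = FALSE)
  writeParcellation(makeParcellation(spec),
                    file.path(outdir, "parcellation.tsv"))
  writeSubjectRecords(cohort$subjects, file.path(outdir, "subjects.tsv"))
  files <- vapply(cohort$maps, function(m) {
    f <- file.path(mapDir, sprintf("%s_%s.tsv", subjectId(m),
                                   contrastName(m)))
    writeVertexMap(m, f)
    f
  }, character(1))
  tr <- cohort$truth
  jsonlite::write_json(
    list(left_dominant_areas = tr@leftDominantAreas,
         right_dominant_areas = tr@rightDominantAreas,
         group_affected_parcels = tr@groupAffectedParcels),
    file.path(outdir, "ground_truth.json"))
  logMsg("info", logLevel, "simulate: wrote ", length(files),
         " maps to ", mapDir)
  invisible(c(file.path(outdir, c("parcellation.tsv", "subjects.tsv",
                                  "ground_truth.json")), files))
}

stageExtractPe <- function(cfg, outdir, logLevel = "info") {
  parcPath <- file.path(outdir, "parcellation.tsv")
  subjPath <- file.path(outdir, "subjects.tsv")
  mapDir <- file.path(outdir, "maps")
  for (f in c(parcPath, subjPath, mapDir))
    if (!file.exists(f))
      stop("extract-pe: missing upstream artifact '", f,
           "' (run the simulate stage first)")
  parc <- readParcellation(parcPath)
  subjects <- readSubjectRecords(subjPath)
  nV <- length(parcelAssignment(parc, "left"))
  mapFiles <- sort(list.files(mapDir, pattern = "\\.tsv$",
                              full.names = TRUE))
  if (!length(mapFiles)) stop("extract-pe: no map files in '", mapDir, "'")
  maps <- lapply(mapFiles, function(f) {
    stem <- sub("\\.tsv$", "", basename(f))
    parts <- regmatches(stem, regexec("^(.*)_(STORY_MATH|STORY)$", stem))[[1]]
    if (length(parts) != 3L)
      stop("extract-pe: cannot parse subject/contrast from '", f, "'")
    readVertexMap(f, nV, parts[2], parts[3])
  })
  pe <- peCountTable(maps, parc, subjects,
                     thresholdBasis = cfg$analyze$threshold_basis)
  writePECountTable(pe, file.path(outdir, "pe_counts.tsv"))
  logMsg("info", logLevel, "extract-pe: ", ncol(pe), " samples x ",
         nrow(pe), " sided parcels")
  invisible(file.path(outdir, "pe_counts.tsv"))
}

stageAnalyze <- function(cfg, outdir, logLevel = "info") {
  pePath <- file.path(outdir, "pe_counts.tsv")
  subjPath <- file.path(outdir, "subjects.tsv")
  for (f in c(pePath, subjPath))
    if (!file.exists(f))
      stop("analyze: missing upstream artifact '", f,
           "' (run the extract-pe stage first)")
  subjects <- readSubjectRecords(subjPath)
  pe <- readPECountTable(pePath, subjects)
  an <- cfg$analyze
  contrasts <- unique(colData(pe)$contrast)
  outputs <- character(0)
  log <- list()
  for (ct in contrasts) {
    if ("hemispheric" %in% an$designs) {
      for (gf in an$group_filters) {
        r <- hemisphericComparison(pe, ct, gf, trim = an$trim)
        tag <- sprintf("hemispheric_%s_%s", ct, gf)
        f <- file.path(outdir, paste0("results_", tag, ".tsv"))
        df <- resultsFrame(r)
        df$region <- "hemisphere_totals"
        writeResultsTable(df, f, ordering = "as_is")
        outputs <- c(outputs, f)
        log[[tag]] <- list(n_tests = 1L, direction = "left_minus_right")
      }
    }
    if ("within_group" %in% an$designs) {
      for (gf in an$group_filters) {
        res <- withinGroupParcelTests(pe, ct, gf, trim = an$trim)
        tag <- sprintf("within_group_%s_%s", ct, gf)
        f <- file.path(outdir, paste0("results_", tag, ".tsv"))
        writeResultsTable(res, f, ordering = "as_is")
        sig <- summarizeSignificant(res, an$alpha)
        fs <- file.path(outdir, paste0("significant_", tag, ".tsv"))
        writeResultsTable(sig, fs, ordering = "by_xi")
        fx <- file.path(outdir, paste0("xi_map_", tag, ".tsv"))
        writeTsv(res[, c("region", "xi")], fx, realCols = "xi")
        outputs <- c(outputs, f, fs, fx)
        log[[tag]] <- list(n_tests = attr(res, "n_tests"),
                           direction = attr(res, "direction"),
                           n_significant = nrow(sig))
      }
    }
    if ("between_group" %in% an$designs) {
      res <- betweenGroupParcelTests(pe, ct, trim = an$trim)
      tag <- sprintf("between_group_%s", ct)
      f <- file.path(outdir, paste0("results_", tag, ".tsv"))
      writeResultsTable(res, f, ordering = "as_is")
      sig <- summarizeSignificant(res, an$alpha)
      fs <- file.path(outdir, paste0("significant_", tag, ".tsv"))
      writeResultsTable(sig, fs, ordering = "by_xi")
      fx <- file.path(outdir, paste0("xi_map_", tag, ".tsv"))
      writeTsv(res[, c("region", "xi")], fx, realCols = "xi")
      outputs <- c(outputs, f, fs, fx)
      log[[tag]] <- list(n_tests = attr(res, "n_tests"),
                         direction = attr(res, "direction"),
                         n_significant = nrow(sig))
    }
  }
  jsonlite::write_json(log, file.path(outdir, "analysis_log.json"),
                       auto_unbox = TRUE)
  logMsg("info", logLevel, "analyze: wrote ", length(outputs),
         " result tables")
  invisible(c(outputs, file.path(outdir, "analysis_log.json")))
}

stageReport <- function(cfg, outdir, logLevel = "info") {
  logPath <- file.path(outdir, "analysis_log.json")
  if (!file.exists(logPath))
    stop("report: missing upstream artifact '", logPath,
         "' (run the analyze stage first)")
  log <- jsonlite::read_json(logPath)
  lines <- c("PE lateralization pipeline summary", "")
  for (tag in names(log)) {
    e <- log[[tag]]
    lines <- c(lines, sprintf(
      "%-40s %4d tests (%s)%s", tag, e$n_tests, e$direction,
      if (!is.null(e$n_significant))
        sprintf(", %d significant after BH", e$n_significant) else ""))
  }
  writeLines(lines, file.path(outdir, "summary.txt"))
  logMsg("info", logLevel, "report: summary.txt written")
  invisible(file.path(outdir, "summary.txt"))
}

#' Run the synthetic lateralization pipeline
#'
#' Executes the requested stages in order (`simulate`, `extract-pe`,
#' `analyze`, `report`), communicating only through plain files in
#' `outdir`, then writes a manifest (`manifest.json`) recording the seed, a
#' hash of the canonicalized configuration, and every file produced. Re-runs
#' with the same configuration and seed reproduce the result tables
#' bit-identically.
#'
#' @param configPath path to the YAML configuration.
#' @param outdir artifact directory (created if needed).
#' @param seed optional integer overriding the configured seed.
#' @param stages character vector of stages to run, in pipeline order.
#' @param logLevel `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(configPath, outdir, seed = NULL,
                        stages = c("simulate", "extract-pe", "analyze",
                                   "report"),
                        logLevel = c("info", "debug", "warn", "quiet")) {
  logLevel <- match.arg(logLevel)
  known <- c("simulate", "extract-pe", "analyze", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- readPipelineConfig(configPath, seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  for (st in known[known %in% stages]) {
    logMsg("info", logLevel, "stage: ", st)
    outputs <- c(outputs, switch(st,
      "simulate" = stageSimulate(cfg, outdir, logLevel),
      "extract-pe" = stageExtractPe(cfg, outdir, logLevel),
      "analyze" = stageAnalyze(cfg, outdir, logLevel),
      "report" = stageReport(cfg, outdir, logLevel)))
  }
  manifest <- list(
    package = "peLaterality",
    version = as.character(packageVersion("peLaterality")),
    seed = cfg$seed,
    config_hash = configHash(cfg),
    stages = stages,
    outputs = sort(unname(outputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
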