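## Config-driven end-to-end orchestration:
## simulate -> measure -> register -> stats -> report.

#' Default run configuration
#'
#' The default demo design mirrors the validated study conditions:
#' 23 subjects, two visits, two operators, ramp gap 1.9-2.9 mm over a
#' 20 mm facet, 0.37 mm voxels, PSF 0.5 mm, noise SD 20, and 199
#' permutations for the angulation SPM.
#'
#' @param outputDir output directory.
#' @param seed integer master seed.
#' @param nSubjects cohort size.
#' @param nPermutations SPM permutations.
#' @return a nested configuration list (RunConfig)
#' @export
#' @rdname runPipeline
defaultRunConfig <- function(outputDir = tempfile("jsmap_run_"), seed = 1,
                             nSubjects = 23, nPermutations = 199) {
  list(
    seed = as.integer(seed),
    outputDir = outputDir,
    stages = c("simulate", "measure", "register", "stats", "report"),
    saveVolumes = FALSE,
    cohort = list(nSubjects = as.integer(nSubjects), visits = 2L,
                  operators = 2L,
                  geometry = "parallel-slabs", extent = 20,
                  meshResolution = 1,
                  gap = list(type = "ramp", from = 1.9, to = 2.9),
                  betweenSubjectSd = 0.3, visitNoiseSd = 20,
                  visitPoseJitter = c(2, 0.5), perimeterJitter = 1,
                  effectMap = 0),
    measure = list(tMax = 4, back = 3, step = 0.1,
                   psfBounds = c(0.2, 1.5), smoothIterations = 5,
                   smoothWeight = 0.5),
    stats = list(nPermutations = as.integer(nPermutations), alpha = 0.05))
}

#' Read a run configuration from a YAML file
#' @param path YAML file path
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Write a run configuration to a YAML file
#' @param config configuration list. @param path output path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cohortSpecFromConfig <- function(cc, seed) {
  cohortSpec(
    nSubjects = cc$nSubjects, visits = cc$visits, operators = cc$operators,
    gapBase = phantomSpec(geometry = cc$geometry, extent = cc$extent,
                          gapField = cc$gap,
                          meshResolution = cc$meshResolution),
    betweenSubjectSd = cc$betweenSubjectSd, visitNoiseSd = cc$visitNoiseSd,
    visitPoseJitter = as.numeric(cc$visitPoseJitter),
    effectMap = if (is.null(cc$effectMap)) 0 else as.numeric(cc$effectMap),
    perimeterJitter = cc$perimeterJitter, seed = seed)
}

#' Run the joint space mapping pipeline
#'
#' Executes the requested stages in order (simulate, measure, register,
#' stats, report). Every artefact is written under the configured output
#' directory and recorded in a manifest (path, stage, md5 checksum)
#' together with the parameters and seed; deterministic stages reproduce
#' their checksums on rerun with the same config.
#'
#' @param config a configuration list (see \code{defaultRunConfig}) or the
#'   path to a YAML file.
#' @return invisibly, a list with the in-memory results (cohort, maps,
#'   atlas, stats), the manifest data.frame, and the output paths.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  addFile <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
  }
  logStage <- function(stage, t0, ...) {
    message(sprintf("[%s] %.1fs %s", stage,
                    as.numeric(Sys.time()) - t0, paste(..., collapse = " ")))
  }
  stages <- config$stages
  state <- list(config = config)

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    spec <- cohortSpecFromConfig(config$cohort, config$seed)
    cohort <- simulateCohort(spec)
    state$cohort <- cohort
    write.csv(cohort@covariates, file.path(out, "covariates.csv"),
              row.names = FALSE)
    addFile(file.path(out, "covariates.csv"), "simulate")
    writePLY(cohort@template, file.path(out, "template.ply"))
    addFile(file.path(out, "template.ply"), "simulate")
    write.csv(round(cohort@groundTruth, 6),
              file.path(out, "ground_truth.csv"), row.names = FALSE)
    addFile(file.path(out, "ground_truth.csv"), "simulate")
    writeVTK(cohort@template, file.path(out, "ground_truth_mean.vtk"),
             fields = list(true_gap = rowMeans(cohort@groundTruth)))
    addFile(file.path(out, "ground_truth_mean.vtk"), "simulate")
    if (isTRUE(config$saveVolumes)) {
      for (k in seq_along(cohort@volumes)) {
        p <- file.path(out, sprintf("volume_%03d.nii.gz", k))
        writeVoxelVolume(cohort@volumes[[k]], p)
        addFile(p, "simulate")
      }
    }
    logStage("simulate", t0, sprintf("%d records", length(cohort@records)))
  }

  if ("measure" %in% stages) {
    if (is.null(state$cohort))
      stop("missing upstream artefact: stage 'measure' requires the cohort from stage 'simulate'")
    t0 <- as.numeric(Sys.time())
    cohort <- state$cohort
    mp <- config$measure
    params <- list(tMax = mp$tMax, back = mp$back, step = mp$step,
                   psfBounds = as.numeric(mp$psfBounds),
                   smoothIterations = mp$smoothIterations,
                   smoothWeight = mp$smoothWeight)
    maps <- vector("list", length(cohort@records))
    for (k in seq_along(cohort@records)) {
      rec <- cohort@records[[k]]
      patch <- patchSubmesh(rec$reference, rec$mask, label = "facet")
      maps[[k]] <- suppressWarnings(
        mapJSW(cohort@volumes[[rec$volumeIndex]], patch, rec$opposing,
               params))
    }
    state$maps <- maps
    logStage("measure", t0, sprintf("%d maps", length(maps)))
  }

  if ("register" %in% stages) {
    if (is.null(state$maps))
      stop("missing upstream artefact: stage 'register' requires JSW maps from stage 'measure'")
    t0 <- as.numeric(Sys.time())
    cohort <- state$cohort
    tmplPatch <- JointPatch(cohort@template,
                            seq_len(nrow(cohort@template@vertices)),
                            label = "template")
    nRec <- length(state$maps)
    fields <- matrix(NA_real_, nrow(cohort@template@vertices), nRec)
    meta <- do.call(rbind, lapply(cohort@records, function(r)
      data.frame(subject = r$subject, visit = r$visit,
                 operator = r$operator)))
    for (k in seq_len(nRec)) {
      rec <- cohort@records[[k]]
      patch <- state$maps[[k]]@patch
      tr <- icpRigid(patch@mesh, cohort@template)
      f <- suppressMessages(
        transferField(patch, state$maps[[k]]@field, tmplPatch, tr))
      fields[, k] <- ifelse(f@mask, f@values, NA_real_)
    }
    state$atlas <- new("TemplateAtlas", template = tmplPatch,
                       fields = fields, meta = meta)
    fcsv <- file.path(out, "stacked_fields.csv")
    colnames(fields) <- sprintf("s%02d_v%d_o%d", meta$subject, meta$visit,
                                meta$operator)
    write.csv(round(fields, 6), fcsv, row.names = FALSE)
    addFile(fcsv, "register")
    logStage("register", t0)
  }

  if ("stats" %in% stages) {
    if (is.null(state$atlas))
      stop("missing upstream artefact: stage 'stats' requires stacked fields from stage 'register'")
    t0 <- as.numeric(Sys.time())
    cohort <- state$cohort
    atlas <- state$atlas
    meta <- atlas@meta
    tmplPatch <- atlas@template
    sel <- function(v, o) atlas@fields[, meta$visit == v & meta$operator == o,
                                       drop = FALSE]
    v1o1 <- sel(1, 1); v1o2 <- sel(1, 2); v2o1 <- sel(2, 1)
    repro <- blandAltmanMap(v1o1, v1o2, patch = tmplPatch)
    repeatability <- blandAltmanMap(v1o1, v2o1, patch = tmplPatch)
    spm <- spmFMap(v1o1, cohort@covariates$angle_deg,
                   nPermutations = config$stats$nPermutations,
                   seed = config$seed, alpha = config$stats$alpha)
    meanJsw <- rowMeans(v1o1, na.rm = TRUE)
    sdJsw <- apply(v1o1, 1, stats::sd, na.rm = TRUE)
    mapFiles <- list(
      mean_jsw = list(jsw = meanJsw),
      sd_jsw = list(jsw_sd = sdJsw),
      reproducibility_loa = list(loa = repro@loa,
                                 bias = repro@bias),
      repeatability_loa = list(loa = repeatability@loa,
                               bias = repeatability@bias))
    for (nm in names(mapFiles)) {
      p <- file.path(out, paste0(nm, ".vtk"))
      writeVTK(cohort@template, p, fields = mapFiles[[nm]])
      addFile(p, "stats")
    }
    spmPath <- file.path(out, "angulation_spm.vtk")
    writeVTK(cohort@template, spmPath,
             fields = list(F = spm@F, p_corrected = spm@pCorrected,
                           significant = as.numeric(spm@significant)))
    addFile(spmPath, "stats")
    state$stats <- list(repro = repro, repeatability = repeatability,
                        spm = spm, v1o1 = v1o1, v2o1 = v2o1, v1o2 = v1o2)
    logStage("stats", t0)
  }

  if ("report" %in% stages) {
    if (is.null(state$stats))
      stop("missing upstream artefact: stage 'report' requires statistics from stage 'stats'")
    t0 <- as.numeric(Sys.time())
    rp <- makeReport(state, write = TRUE)
    addFile(rp$path, "report")
    state$report <- rp$table
    logStage("report", t0)
  }

  manifestPath <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed, parameters = config[c("cohort", "measure",
                                                   "stats")],
         files = manifest),
    manifestPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$manifest <- manifest
  state$manifestPath <- manifestPath
  invisible(state)
}

#' Patch-level summary report
#'
#' One CSV row per patch: mean +/- SD JSW at each visit, inter-operator
#' reproducibility bias +/- LOA, and test-retest repeatability bias +/-
#' LOA, all in mm to two decimal places.
#'
#' @param run the list returned by \code{runPipeline} (stats stage done).
#' @param write write \code{report.csv} into the run's output directory.
#' @return list with the report data.frame and, when written, its path
#' @export
makeReport <- function(run, write = FALSE) {
  st <- run$stats
  if (is.null(st))
    stop("missing upstream artefact: report requires statistics from stage 'stats'")
  tmplPatch <- run$atlas@template
  w <- vertexAreas(tmplPatch@mesh)
  pm <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      keep <- !is.na(M[, j])
      sum(w[keep] * M[keep, j]) / sum(w[keep])
    }, 1)
  }
  m1 <- pm(st$v1o1); m2 <- pm(st$v2o1)
  f2 <- function(x) sprintf("%.2f", x)
  tab <- data.frame(
    patch = tmplPatch@label,
    jsw_visit1 = sprintf("%s ± %s", f2(mean(m1)), f2(stats::sd(m1))),
    jsw_visit2 = sprintf("%s ± %s", f2(mean(m2)), f2(stats::sd(m2))),
    reproducibility = sprintf("%s ± %s", f2(st$repro@patchBias),
                              f2(st$repro@patchLoa)),
    repeatability = sprintf("%s ± %s",
                            f2(st$repeatability@patchBias),
                            f2(st$repeatability@patchLoa)),
    stringsAsFactors = FALSE)
  path <- NULL
  if (write) {
    path <- file.path(run$config$outputDir, "report.csv")
    write.csv(tab, path, row.names = FALSE)
  }
  list(table = tab, path = path)
}
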