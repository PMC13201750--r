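#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [runPipeline()]. All
#' seeds for downstream stages are derived deterministically from the single
#' `seed`, and every output artifact records the configuration hash, so a
#' rerun with the same configuration is byte-identical for deterministic
#' stages.
#'
#' @param outputDir directory for artifacts (created if absent).
#' @param seed master integer seed.
#' @param nLeads cohort size to simulate.
#' @param voxelSize atlas voxel size in mm.
#' @param scenarios extension scenarios to score.
#' @param contactRadius binary-engagement sphere radius (mm).
#' @param vatRadius VAT sphere radius (mm, 1 mA approximation).
#' @param extensions virtual-extension arc lengths (mm).
#' @param trainScenario scenario whose engagement labels train the
#'   classifiers.
#' @param cvFolds cross-validation folds.
#' @param confidence confidence threshold for rules and the confident CV
#'   subset.
#' @param grid probability-map grid (see [ruleGrid()]).
#' @param rulePanel `c(x =, y =)` panel at which angle rules are extracted.
#' @param gpc a [gpcConfig()].
#' @param anatomy optional [anatomyParams()] override.
#' @param cohort optional [cohortParams()] override (its seed is replaced by
#'   a derived one).
#' @return List of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outputDir, seed = 1L, nLeads = 150L,
                           voxelSize = 0.25,
                           scenarios = c("implanted_only", "plus2mm",
                                         "plus4mm", "plus6mm"),
                           contactRadius = 1, vatRadius = 2,
                           extensions = c(2, 4, 6),
                           trainScenario = "plus6mm",
                           cvFolds = 5L, confidence = 0.95,
                           grid = ruleGrid(), rulePanel = c(x = 1.5, y = 0),
                           gpc = gpcConfig(), anatomy = NULL, cohort = NULL) {
  scenarios <- match.arg(scenarios, names(.SCENARIOS), several.ok = TRUE)
  stopifnot(contactRadius > 0, vatRadius > 0, cvFolds >= 2L,
            confidence > 0, confidence < 1,
            trainScenario %in% names(.SCENARIOS))
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 nLeads = as.integer(nLeads), voxelSize = voxelSize,
                 scenarios = scenarios, contactRadius = contactRadius,
                 vatRadius = vatRadius, extensions = extensions,
                 trainScenario = trainScenario, cvFolds = as.integer(cvFolds),
                 confidence = confidence, grid = grid,
                 rulePanel = rulePanel, gpc = gpc,
                 anatomy = anatomy, cohort = cohort),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the [pipelineConfig()] defaults;
#' unknown fields raise an error.
#'
#' @param path YAML file.
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), c(known, "grid"))
  if (length(unknown))
    stop(sprintf("unknown configuration fields: %s", paste(unknown, collapse = ", ")))
  if (!is.null(y$grid)) {
    g <- lapply(y$grid, unlist)
    ## YAML 1.1 resolves a bare key "y" to TRUE; map it back
    names(g)[names(g) %in% c("TRUE", "yes")] <- "y"
    y$grid <- do.call(ruleGrid, g)
  }
  if (!is.null(y$gpc)) y$gpc <- do.call(gpcConfig, y$gpc)
  if (!is.null(y$rulePanel)) {
    rp <- unlist(y$rulePanel)
    names(rp)[names(rp) %in% c("TRUE", "yes")] <- "y"
    y$rulePanel <- rp
  }
  do.call(pipelineConfig, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outputDir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full trajectory-analysis pipeline
#'
#' Chains simulate, features, engagement, summaries, classifier training and
#' cross-validation, probability-map rule extraction and the depth rule, and
#' writes all artifacts (NIfTI atlas, CSV tables, JSON reports) plus a run
#' manifest with the configuration hash, derived seeds, package version and
#' per-file checksums. Stages after `simulate` can also be driven by
#' externally supplied atlas/lead/frame files through the corresponding
#' readers; this driver always simulates.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return Invisible list with in-memory results of each stage.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (!config$trainScenario %in% config$scenarios)
    stop(sprintf("trainScenario '%s' is not among the configured scenarios",
                 config$trainScenario))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outputDir, ...)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  written <- character()

  ## --- simulate -------------------------------------------------------
  say("stage simulate: atlas at %.3g mm, %d leads", config$voxelSize, config$nLeads)
  ap <- config$anatomy %||% anatomyParams(voxelSize = config$voxelSize,
                                          seed = child_seed(config$seed, "anatomy"))
  atlas <- makeAtlas(ap)
  atlas <- buildCentralTarget(atlas)
  frame <- buildNativeFrame(ap$ac, ap$pc, ap$midlineVertex)
  cp <- config$cohort %||% cohortParams(nLeads = config$nLeads)
  cp$seed <- child_seed(config$seed, "cohort")
  cohort <- sampleCohort(atlas, cp, frame)
  leads <- lapply(cohort$leads, extendVirtual, extensions = config$extensions)
  writeAtlas(atlas, out("atlas.nii"))
  writeLeadTable(leads, out("leads.csv"))
  writeFrame(frame, out("frame.json"))
  utils::write.csv(cohort$truth, out("cohort_truth.csv"), row.names = FALSE)
  written <- c(written, "atlas.nii", "atlas.labels.json", "leads.csv",
               "frame.json", "cohort_truth.csv")

  ## --- features -------------------------------------------------------
  say("stage features")
  feats <- trajectoryFeatures(leads, atlas, frame)
  fout <- feats
  for (cl in c("x_mm", "y_mm", "ms_angle", "acpc_angle"))
    fout[[cl]] <- fixed6(fout[[cl]])
  utils::write.csv(fout, out("features.csv"), row.names = FALSE)
  written <- c(written, "features.csv")

  ## --- engage ---------------------------------------------------------
  say("stage engage: scenarios %s", paste(config$scenarios, collapse = ", "))
  eng <- engagementTable(leads, atlas, scenarios = config$scenarios,
                         radius = config$contactRadius)
  utils::write.csv(eng, out("engagement.csv"), row.names = FALSE)
  written <- c(written, "engagement.csv")

  ## --- summary --------------------------------------------------------
  say("stage summary")
  summ <- cohortSummary(eng, cohort$truth)
  utils::write.csv(summ, out("summary.csv"), row.names = FALSE)
  prof <- rbind(depthProfile(leads, atlas, frame, "SNr", radius = config$vatRadius),
                depthProfile(leads, atlas, frame, "SNc", radius = config$vatRadius))
  utils::write.csv(prof, out("depth_profile.csv"), row.names = FALSE)
  written <- c(written, "summary.csv", "depth_profile.csv")

  ## --- train / cross-validate ----------------------------------------
  say("stage train: labels from scenario %s", config$trainScenario)
  lab <- eng[eng$scenario == config$trainScenario, ]
  lab <- lab[match(feats$lead_id, lab$lead_id), ]
  gpcCfg <- config$gpc
  gpcCfg$seed <- child_seed(config$seed, "gpc")
  cv <- list()
  models <- list()
  for (tgt in c("SNr", "SNc")) {
    labels <- if (tgt == "SNr") lab$snr else lab$snc
    models[[tgt]] <- trainGpc(feats, labels, target = tgt, config = gpcCfg)
    cv[[tgt]] <- crossValidate(feats, labels, k = config$cvFolds,
                               confidenceThreshold = config$confidence,
                               seed = child_seed(config$seed, paste0("cv", tgt)),
                               target = tgt, config = gpcCfg)
  }
  write_json_artifact(lapply(cv, function(x)
    x[c("k", "n", "accuracy", "confidentAccuracy", "confidentFraction",
        "confidenceThreshold", "seed")]), out("cv_report.json"))
  written <- c(written, "cv_report.json")

  ## --- rule map -------------------------------------------------------
  say("stage rulemap")
  maps <- lapply(models, probabilityMap, grid = config$grid,
                 threshold = config$confidence)
  rules <- lapply(maps, extractRules, x = config$rulePanel[["x"]],
                  y = config$rulePanel[["y"]])
  write_json_artifact(lapply(maps, function(m)
    list(axes = m@axes, threshold = m@threshold, target = m@target,
         prob = m@prob)), out("rule_maps.json"))
  write_json_artifact(lapply(rules, function(r)
    list(summary = r$summary, bounds = r$bounds, n_cells = nrow(r$cells))),
    out("rules.json"))
  written <- c(written, "rule_maps.json", "rules.json")

  ## --- depth ----------------------------------------------------------
  say("stage depth")
  dd <- depthRuleData(leads, atlas, frame, radius = config$contactRadius)
  depthRule <- fitDepthRule(dd$depth_mm, dd$in_sn, level = config$confidence)
  write_json_artifact(unclass(depthRule), out("depth_rule.json"))
  written <- c(written, "depth_rule.json")

  ## --- manifest -------------------------------------------------------
  manifest <- list(
    package = "nigratarget",
    version = as.character(utils::packageVersion("nigratarget")),
    config_hash = config_hash(config),
    seed = config$seed,
    derived_seeds = list(anatomy = child_seed(config$seed, "anatomy"),
                         cohort = child_seed(config$seed, "cohort"),
                         gpc = child_seed(config$seed, "gpc")),
    files = lapply(stats::setNames(written, written), function(f)
      unname(tools::md5sum(out(f)))))
  write_json_artifact(manifest, out("manifest.json"))
  say("pipeline complete: %d artifacts in %s", length(written) + 1L, config$outputDir)
  invisible(list(atlas = atlas, frame = frame, cohort = cohort, leads = leads,
                 features = feats, engagement = eng, summary = summ,
                 profile = prof, models = models, cv = cv, maps = maps,
                 rules = rules, depthRule = depthRule, manifest = manifest))
}
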