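## End-to-end orchestration: validate inputs, run every stage, write every
## artifact and a machine-readable summary, with structured logging.

#' Pipeline configuration
#'
#' Collects input paths and every tunable of the full analysis. Accepts a
#' directory holding the standard file set (`design.tsv`, `growth.tsv`,
#' `features.tsv`, `samples.tsv`, `masses.tsv`, `pathways.tsv`) or
#' explicit per-file paths. Unknown keys and out-of-range tunables are
#' rejected.
#'
#' @param inputDir Directory with the standard input files; individual
#'   paths below override its defaults.
#' @param design,growth,features,samples,masses,pathways Optional explicit
#'   file paths.
#' @param outDir Output directory for all result tables.
#' @param alpha Significance level for Welch tests (0 < alpha < 1,
#'   default 0.05).
#' @param mixotrophyThreshold Minimum consumed fraction (default 0.10).
#' @param tolPpm Annotation mass tolerance in ppm (default 10).
#' @param producedMin Production threshold on normalized intensity
#'   (default 0).
#' @param noGrowthThresholdOd Final OD750 below which growth is called
#'   completely inhibited (default 0.05).
#' @param dayFinal Final-OD day (default 10).
#' @param expWindow Exponential-phase regression window (default 0-4 d).
#' @param pcaComponents Components to keep in the PCA (default 5, capped
#'   at the data dimension).
#' @param seed Integer seed recorded in the manifest; the analysis itself
#'   is deterministic.
#' @return A validated list of class `PipelineConfig`.
#' @export
screenConfig <- function(inputDir = NULL, design = NULL, growth = NULL,
                         features = NULL, samples = NULL, masses = NULL,
                         pathways = NULL, outDir = "exoscreen_out",
                         alpha = 0.05, mixotrophyThreshold = 0.10,
                         tolPpm = 10, producedMin = 0,
                         noGrowthThresholdOd = 0.05, dayFinal = 10,
                         expWindow = c(0, 4), pcaComponents = 5L,
                         seed = 1L) {
  path <- function(explicit, name)
    if (!is.null(explicit)) explicit else if (!is.null(inputDir))
      file.path(inputDir, name) else
        stop(sprintf("no path for '%s' and no inputDir", name),
             call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  assertFraction(mixotrophyThreshold, "mixotrophyThreshold")
  if (tolPpm <= 0) stop("tolPpm must be positive", call. = FALSE)
  if (noGrowthThresholdOd < 0) stop("noGrowthThresholdOd must be >= 0",
                                    call. = FALSE)
  if (length(expWindow) != 2L || expWindow[1] >= expWindow[2])
    stop("expWindow must be an increasing pair of days", call. = FALSE)
  cfg <- list(design = path(design, "design.tsv"),
              growth = path(growth, "growth.tsv"),
              features = path(features, "features.tsv"),
              samples = path(samples, "samples.tsv"),
              masses = path(masses, "masses.tsv"),
              pathways = path(pathways, "pathways.tsv"),
              outDir = outDir, alpha = alpha,
              mixotrophyThreshold = mixotrophyThreshold,
              tolPpm = tolPpm, producedMin = producedMin,
              noGrowthThresholdOd = noGrowthThresholdOd,
              dayFinal = dayFinal, expWindow = as.numeric(expWindow),
              pcaComponents = assertCount(pcaComponents, "pcaComponents"),
              seed = assertCount(seed, "seed", min = 0L))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [screenConfig()]; unknown keys are
#' rejected.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `PipelineConfig`.
#' @export
readScreenConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(screenConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(screenConfig, vals)
}

stageLog <- function(manifest, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(manifest, sprintf("[%s] %s", stage, msg))
}

#' Run the full screen analysis
#'
#' Executes every stage on the configured inputs: validation, growth
#' summarization and effect classification, exact-mass annotation,
#' LOD-based normalization, consumption/mixotrophy calling, exudate
#' ranking, pathway scoring, and PCA of the exometabolome profiles
#' (no-growth conditions excluded). Writes `effects.tsv`,
#' `annotations.tsv`, `norm.tsv`, `provenance.tsv`, `consumption.tsv`,
#' `exudate_ranks.tsv`, `pathway_scores.tsv`, `pca_scores.tsv`,
#' `pca_loadings.tsv`, a machine-readable `summary.json` and a run
#' manifest logging stage parameters, row counts and input MD5 hashes.
#' Identical inputs and configuration yield identical outputs; any stage
#' error aborts with the stage name.
#'
#' @param config A `PipelineConfig` from [screenConfig()] or
#'   [readScreenConfig()].
#' @return Invisibly, a list with every stage result plus `summary`
#'   (condition/effect/mixotrophy counts and top-10 exudate labels).
#' @export
runScreen <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  stage <- "validate"
  res <- tryCatch({
    inputs <- list(design = readDesign(config$design),
                   growth = readGrowthCurves(config$growth),
                   features = readFeatureMatrix(config$features,
                                                config$samples),
                   masses = readMassTable(config$masses),
                   pathways = readPathwayDB(config$pathways))
    for (f in c("design", "growth", "features", "samples", "masses",
                "pathways"))
      manifest <- stageLog(manifest, "validate", "%s md5 %s", f,
                           unname(tools::md5sum(config[[f]])))

    stage <- "growth"
    summaries <- summarizeGrowth(inputs$growth, dayFinal = config$dayFinal,
                                 expWindow = config$expWindow)
    effects <- classifyGrowth(summaries, controlId(inputs$design),
                              alpha = config$alpha,
                              noGrowthThresholdOd = config$noGrowthThresholdOd)
    manifest <- stageLog(manifest, "growth",
                         "%d conditions classified (alpha=%g, noGrowthOd=%g)",
                         nrow(effects), config$alpha,
                         config$noGrowthThresholdOd)

    stage <- "annotate"
    annotations <- annotateIons(inputs$features, inputs$masses,
                                tolPpm = config$tolPpm)
    lm_ <- labelIonMap(annotations, inputs$features)
    manifest <- stageLog(manifest, "annotate",
                         "%d/%d ions annotated to %d labels (tol %g ppm)",
                         sum(nzchar(annotations$label)), nrow(annotations),
                         nrow(lm_), config$tolPpm)

    stage <- "normalize"
    lod <- computeLod(inputs$features, lm_)
    norm <- normalizeExometabolome(inputs$features, lm_, inputs$design,
                                   lod = lod)
    manifest <- stageLog(manifest, "normalize", "%d labels x %d conditions",
                         nrow(norm), ncol(norm))

    stage <- "consumption"
    consumption <- consumptionCalls(inputs$features, lm_, inputs$design,
                                    threshold = config$mixotrophyThreshold,
                                    alpha = config$alpha)
    mixo <- attr(consumption, "mixotrophic_metabolites")
    manifest <- stageLog(manifest, "consumption",
                         "%d calls, %d mixotrophic metabolites",
                         nrow(consumption), length(mixo))

    stage <- "rank"
    ranks <- rankExudates(norm)

    stage <- "pathways"
    pathScores <- scorePathways(norm, inputs$pathways,
                                producedMin = config$producedMin)
    manifest <- stageLog(manifest, "pathways", "%d scores, %d undefined conditions",
                         nrow(pathScores),
                         length(attr(pathScores, "undefined_conditions")))

    stage <- "pca"
    noGrowth <- effects$condition_id[effects$effect_class ==
                                       "complete_inhibition"]
    k <- min(config$pcaComponents,
             ncol(norm) - length(intersect(noGrowth, colnames(norm))) - 1L,
             nrow(norm))
    pca <- exoPca(norm, nComponents = k, exclude = noGrowth)
    manifest <- stageLog(manifest, "pca",
                         "%d components on %d conditions (excluded %d no-growth)",
                         k, nrow(pca$scores), length(noGrowth))

    list(inputs = inputs, summaries = summaries, effects = effects,
         annotations = annotations, labelMap = lm_, lod = lod, norm = norm,
         consumption = consumption, ranks = ranks,
         pathwayScores = pathScores, pca = pca)
  }, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))

  summary <- list(
    n_conditions = nrow(designTable(res$inputs$design)),
    n_supplemented = sum(!is.na(designTable(res$inputs$design)$metabolite_id)),
    n_enhanced = sum(res$effects$effect_class == "enhanced"),
    n_inhibited = sum(res$effects$effect_class %in%
                        c("inhibited", "complete_inhibition")),
    n_complete_inhibition = sum(res$effects$effect_class ==
                                  "complete_inhibition"),
    n_mixotrophic_metabolites =
      length(attr(res$consumption, "mixotrophic_metabolites")),
    mixotrophic_metabolites =
      attr(res$consumption, "mixotrophic_metabolites"),
    top10_exudates = res$ranks$label[seq_len(min(10L, nrow(res$ranks)))])
  res$summary <- summary

  out <- function(name) file.path(config$outDir, name)
  writeTsv(res$effects, out("effects.tsv"))
  writeTsv(res$annotations, out("annotations.tsv"))
  nm <- normValues(res$norm)
  writeTsv(cbind(data.frame(label = rownames(nm)),
                 as.data.frame(nm, check.names = FALSE)), out("norm.tsv"))
  pv <- provenance(res$norm)
  writeTsv(cbind(data.frame(label = rownames(pv)),
                 as.data.frame(pv, check.names = FALSE)),
           out("provenance.tsv"))
  writeTsv(res$consumption, out("consumption.tsv"))
  writeTsv(res$ranks, out("exudate_ranks.tsv"))
  writeTsv(res$pathwayScores, out("pathway_scores.tsv"))
  writeTsv(cbind(data.frame(condition_id = rownames(res$pca$scores)),
                 as.data.frame(res$pca$scores)), out("pca_scores.tsv"))
  writeTsv(cbind(data.frame(label = rownames(res$pca$loadings)),
                 as.data.frame(res$pca$loadings)), out("pca_loadings.tsv"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(manifest, out("run_manifest.txt"))
  invisible(res)
}
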