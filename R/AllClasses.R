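#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

SAMPLE_CLASSES <- c("supernatant_day10", "background_medium",
                    "supplemented_reference")
GROWTH_CLASSES <- c("enhanced", "inhibited", "none", "complete_inhibition")
PROVENANCE_FLAGS <- c("measured", "below_lod_reassigned", "supplement_masked")

## ---------------------------------------------------------------------------
## ExperimentDesign

#' ExperimentDesign: enumerated culture conditions of a screen
#'
#' Holds one row per culture condition: every (metabolite, concentration)
#' pair plus exactly one unsupplemented control. Construct with
#' [ExperimentDesign()] or [generateDesign()]; read/write with
#' [readDesign()] / [writeDesign()].
#'
#' @slot conditions `data.frame` with columns `condition_id` (unique),
#'   `metabolite_id` (`NA` for the control), `concentration_uM` (`NA` for
#'   the control), `n_replicates`, `unmeasurable` (logical; whether the
#'   supplement is outside LC-MS coverage).
#' @aliases ExperimentDesign
#' @export
setClass("ExperimentDesign", representation(conditions = "data.frame"))

setValidity("ExperimentDesign", function(object) {
  d <- object@conditions
  need <- c("condition_id", "metabolite_id", "concentration_uM",
            "n_replicates", "unmeasurable")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$condition_id))
    return("condition_id values must be unique")
  ctrl <- is.na(d$metabolite_id)
  if (sum(ctrl) != 1L)
    return("exactly one control row (metabolite_id = NA) required")
  if (!is.na(d$concentration_uM[ctrl]))
    return("control row must have NA concentration")
  sup <- d[!ctrl, ]
  if (anyDuplicated(sup[, c("metabolite_id", "concentration_uM")]))
    return("(metabolite_id, concentration_uM) pairs must be unique")
  if (any(!is.na(sup$concentration_uM) & sup$concentration_uM <= 0))
    return("concentrations must be positive")
  if (any(d$n_replicates < 1L))
    return("n_replicates must be >= 1")
  TRUE
})

#' Construct an ExperimentDesign
#'
#' @param conditions `data.frame` with one row per condition; see
#'   the class description for required columns. An `unmeasurable` column is
#'   added (all `FALSE`) when absent.
#' @return An [ExperimentDesign-class] object.
#' @export
ExperimentDesign <- function(conditions) {
  if (!"unmeasurable" %in% names(conditions))
    conditions$unmeasurable <- FALSE
  rownames(conditions) <- NULL
  new("ExperimentDesign", conditions = conditions)
}

#' @describeIn ExperimentDesign-class Show a one-line summary.
#' @param object An `ExperimentDesign`.
#' @export
setMethod("show", "ExperimentDesign", function(object) {
  d <- object@conditions
  cat(sprintf("ExperimentDesign: %d conditions (%d supplemented + control), %d metabolites\n",
              nrow(d), sum(!is.na(d$metabolite_id)),
              length(unique(d$metabolite_id[!is.na(d$metabolite_id)]))))
})

## ---------------------------------------------------------------------------
## GroundTruth

#' GroundTruth: planted truth behind a synthetic screen
#'
#' Records what the synthetic generator planted, so recovery can be checked:
#' the true growth class and carrying-capacity multiplier per condition, the
#' true drawdown fraction per supplemented condition, and the truly exuded
#' metabolites (with fold over background) per condition.
#'
#' @slot growth `data.frame(condition_id, growth_class, od_multiplier)`,
#'   one row per condition; `growth_class` one of `enhanced`, `inhibited`,
#'   `none`, `complete_inhibition`.
#' @slot drawdown `data.frame(condition_id, metabolite_id, fraction)` with
#'   `fraction` in `[0, 1]`.
#' @slot exudation `data.frame(condition_id, metabolite_id, fold)` with
#'   `fold > 1` the planted intensity fold over background medium.
#' @aliases GroundTruth
#' @export
setClass("GroundTruth", representation(growth = "data.frame",
                                       drawdown = "data.frame",
                                       exudation = "data.frame"))

setValidity("GroundTruth", function(object) {
  g <- object@growth
  if (!all(c("condition_id", "growth_class", "od_multiplier") %in% names(g)))
    return("growth slot needs condition_id, growth_class, od_multiplier")
  if (anyDuplicated(g$condition_id))
    return("one growth record per condition required")
  if (!all(g$growth_class %in% GROWTH_CLASSES))
    return(paste("growth_class must be one of:",
                 paste(GROWTH_CLASSES, collapse = ", ")))
  dd <- object@drawdown
  if (nrow(dd) && (any(dd$fraction < 0) || any(dd$fraction > 1)))
    return("drawdown fractions must lie in [0, 1]")
  ex <- object@exudation
  if (nrow(ex) && any(ex$fold <= 0))
    return("exudation folds must be positive")
  TRUE
})

#' Construct a GroundTruth
#'
#' @param growth,drawdown,exudation See [GroundTruth-class]. Empty
#'   data.frames are allowed for `drawdown` and `exudation`.
#' @return A [GroundTruth-class] object.
#' @export
GroundTruth <- function(growth,
                        drawdown = data.frame(condition_id = character(),
                                              metabolite_id = character(),
                                              fraction = numeric()),
                        exudation = data.frame(condition_id = character(),
                                               metabolite_id = character(),
                                               fold = numeric())) {
  new("GroundTruth", growth = growth, drawdown = drawdown,
      exudation = exudation)
}

#' @describeIn GroundTruth-class Show a one-line summary.
#' @param object A `GroundTruth`.
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d conditions (%s), %d drawdown records, %d exudation records\n",
              nrow(object@growth),
              paste(sprintf("%d %s", as.vector(table(object@growth$growth_class)[GROWTH_CLASSES]),
                            GROWTH_CLASSES), collapse = ", "),
              nrow(object@drawdown), nrow(object@exudation)))
})

## ---------------------------------------------------------------------------
## FeatureMatrix

#' FeatureMatrix: ion-by-sample LC-MS intensity matrix
#'
#' A [SummarizedExperiment-class] subclass holding the processed untargeted
#' LC-MS feature table of a screen: one `intensity` assay (nonnegative, no
#' missing cells; absent measurements are explicit zeros), ion metadata
#' (`ion_id`, `mz` in Daltons, `polarity`) as `rowData`, and sample metadata
#' (`sample_id`, `condition_id` -- `NA` for background medium --,
#' `replicate`, `sample_class`) as `colData`. `sample_class` is one of
#' `supernatant_day10` (cell-free culture supernatant after 10 days),
#' `background_medium` (uninoculated BG-11), `supplemented_reference`
#' (sterile medium with the supplement at nominal concentration).
#'
#' @aliases FeatureMatrix
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' required")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (anyNA(x)) return("intensities must not contain NA (use explicit 0)")
  if (any(x < 0)) return("intensities must be nonnegative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ion_id", "mz", "polarity") %in% names(rd)))
    return("rowData needs ion_id, mz, polarity")
  if (any(rd$mz <= 0)) return("mz must be positive")
  if (anyDuplicated(rd$ion_id)) return("ion_id must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "condition_id", "replicate", "sample_class") %in%
           names(cd)))
    return("colData needs sample_id, condition_id, replicate, sample_class")
  if (anyDuplicated(cd$sample_id)) return("sample_id must be unique")
  if (!all(cd$sample_class %in% SAMPLE_CLASSES))
    return(paste("sample_class must be one of:",
                 paste(SAMPLE_CLASSES, collapse = ", ")))
  if (!any(cd$sample_class == "background_medium"))
    return("at least one background_medium sample required")
  TRUE
})

#' Construct a FeatureMatrix
#'
#' @param intensity Numeric matrix, ions as rows, samples as columns.
#' @param ions `data.frame` with `ion_id`, `mz`, `polarity`; one row per
#'   intensity row.
#' @param samples `data.frame` with `sample_id`, `condition_id`,
#'   `replicate`, `sample_class`; one row per intensity column.
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(intensity, ions, samples) {
  dimnames(intensity) <- list(ions$ion_id, samples$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = ions, colData = samples)
  new("FeatureMatrix", se)
}

#' @describeIn FeatureMatrix-class Show a summary with sample-class counts.
#' @param object A `FeatureMatrix`.
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  tab <- table(factor(cd$sample_class, levels = SAMPLE_CLASSES))
  cat(sprintf("FeatureMatrix: %d ions x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%d %s", as.vector(tab), names(tab)),
                    collapse = ", ")))
})

## ---------------------------------------------------------------------------
## NormalizedExometabolome

#' NormalizedExometabolome: metabolite-by-condition normalized intensities
#'
#' A [SummarizedExperiment-class] subclass produced by
#' [normalizeExometabolome()]: rows are annotated metabolite labels (isobars
#' collapsed), columns are culture conditions. Assay `norm` holds values on
#' the 0--1 scale where 0 is background-medium intensity and 1 the highest
#' post-masking sample intensity of that metabolite; assay `provenance`
#' flags each cell as `measured`, `below_lod_reassigned` (every replicate
#' below the limit of detection) or `supplement_masked` (the condition's own
#' supplement, forced to 0).
#'
#' @aliases NormalizedExometabolome
#' @export
setClass("NormalizedExometabolome", contains = "SummarizedExperiment")

setValidity("NormalizedExometabolome", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("norm", "provenance") %in% an))
    return("assays 'norm' and 'provenance' required")
  x <- SummarizedExperiment::assay(object, "norm")
  if (anyNA(x)) return("normalized values must not be NA")
  if (any(x < 0) || any(x > 1)) return("normalized values must lie in [0, 1]")
  pv <- SummarizedExperiment::assay(object, "provenance")
  if (!all(pv %in% PROVENANCE_FLAGS))
    return(paste("provenance flags must be one of:",
                 paste(PROVENANCE_FLAGS, collapse = ", ")))
  if (any(x[pv == "supplement_masked"] != 0))
    return("supplement_masked cells must be exactly 0")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("label", "metabolite_ids", "ion_id") %in% names(rd)))
    return("rowData needs label, metabolite_ids, ion_id")
  TRUE
})

#' @describeIn NormalizedExometabolome-class Show a summary.
#' @param object A `NormalizedExometabolome`.
#' @export
setMethod("show", "NormalizedExometabolome", function(object) {
  pv <- SummarizedExperiment::assay(object, "provenance")
  cat(sprintf("NormalizedExometabolome: %d metabolites x %d conditions (%d masked, %d below-LOD cells)\n",
              nrow(object), ncol(object),
              sum(pv == "supplement_masked"),
              sum(pv == "below_lod_reassigned")))
})
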