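## Accessor generics: users read slots through these, never with @.

#' Accessors for screen objects
#'
#' @description
#' `designTable()` returns the condition table of an
#' [ExperimentDesign-class]; `conditionIds()` its condition ids;
#' `controlId()` the id of the unsupplemented control.
#' `intensities()` returns the intensity assay of a [FeatureMatrix-class];
#' `normValues()` and `provenance()` the normalized-value and provenance
#' assays of a [NormalizedExometabolome-class].
#'
#' @param x An `ExperimentDesign`, `FeatureMatrix` or
#'   `NormalizedExometabolome` as appropriate.
#' @return `designTable`: a `data.frame`; `conditionIds`: character vector;
#'   `controlId`: a single string; `intensities`, `normValues`: numeric
#'   matrix; `provenance`: character matrix.
#' @name accessors
#' @aliases designTable conditionIds controlId intensities normValues
#'   provenance
#' @examples
#' d <- generateDesign(syntheticConfig(nMetabolites = 2))
#' conditionIds(d)
#' controlId(d)
NULL

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setMethod("designTable", "ExperimentDesign", function(x) x@conditions)

#' @rdname accessors
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))
#' @rdname accessors
#' @export
setMethod("conditionIds", "ExperimentDesign",
          function(x) x@conditions$condition_id)

#' @rdname accessors
#' @export
setGeneric("controlId", function(x) standardGeneric("controlId"))
#' @rdname accessors
#' @export
setMethod("controlId", "ExperimentDesign",
          function(x) x@conditions$condition_id[is.na(x@conditions$metabolite_id)])

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "FeatureMatrix",
          function(x) SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setMethod("normValues", "NormalizedExometabolome",
          function(x) SummarizedExperiment::assay(x, "norm"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "NormalizedExometabolome",
          function(x) SummarizedExperiment::assay(x, "provenance"))

#' Ground-truth accessors
#'
#' `trueGrowth()`, `trueDrawdown()` and `trueExudation()` return the three
#' record tables of a [GroundTruth-class].
#'
#' @param x A `GroundTruth`.
#' @return A `data.frame`.
#' @name truth-accessors
#' @aliases trueGrowth trueDrawdown trueExudation
NULL

#' @rdname truth-accessors
#' @export
setGeneric("trueGrowth", function(x) standardGeneric("trueGrowth"))
#' @rdname truth-accessors
#' @export
setMethod("trueGrowth", "GroundTruth", function(x) x@growth)

#' @rdname truth-accessors
#' @export
setGeneric("trueDrawdown", function(x) standardGeneric("trueDrawdown"))
#' @rdname truth-accessors
#' @export
setMethod("trueDrawdown", "GroundTruth", function(x) x@drawdown)

#' @rdname truth-accessors
#' @export
setGeneric("trueExudation", function(x) standardGeneric("trueExudation"))
#' @rdname truth-accessors
#' @export
setMethod("trueExudation", "GroundTruth", function(x) x@exudation)
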