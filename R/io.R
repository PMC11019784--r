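## Tab-separated readers and writers for every pipeline artifact. All
## readers validate strictly and reject rather than coerce; every error
## names the file, row and field.

readTsv <- function(path, required, file.label = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    ioStop(file.label, 1, paste(miss, collapse = ","),
           "missing required column(s)")
  df
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

checkNumeric <- function(x, file, field, positive = FALSE,
                         allow.na = FALSE) {
  bad <- which(is.na(x) & !allow.na)
  if (length(bad))
    ioStop(file, bad + 1L, field, "malformed or missing number")
  if (positive) {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      ioStop(file, bad + 1L, field, "value must be positive")
  }
  x
}

## ---------------------------------------------------------------------------

#' Read and write an experimental design table
#'
#' `design.tsv` is tab-separated with header columns `condition_id`,
#' `metabolite_id` (empty for the control row), `concentration_uM` (empty
#' for control), `n_replicates` and optional `unmeasurable` (true/false).
#' `writeDesign()` followed by `readDesign()` is the identity.
#'
#' @param path File path.
#' @param design An [ExperimentDesign-class].
#' @return `readDesign`: an [ExperimentDesign-class]. `writeDesign`: the
#'   path, invisibly.
#' @export
readDesign <- function(path) {
  f <- basename(path)
  df <- readTsv(path, c("condition_id", "metabolite_id",
                        "concentration_uM", "n_replicates"))
  if (!"unmeasurable" %in% names(df)) df$unmeasurable <- FALSE
  dup <- which(duplicated(df$condition_id))
  if (length(dup))
    ioStop(f, dup + 1L, "condition_id", "duplicate condition id")
  nctrl <- sum(is.na(df$metabolite_id))
  if (nctrl != 1L)
    ioStop(f, which(is.na(df$metabolite_id)) + 1L, "metabolite_id",
           sprintf("expected exactly one control row, found %d", nctrl))
  df$concentration_uM <- checkNumeric(
    suppressWarnings(as.numeric(df$concentration_uM)), f,
    "concentration_uM", positive = TRUE, allow.na = TRUE)
  bad <- which(!is.na(df$metabolite_id) & is.na(df$concentration_uM))
  if (length(bad))
    ioStop(f, bad + 1L, "concentration_uM",
           "supplemented row lacks a concentration")
  df$n_replicates <- checkNumeric(
    suppressWarnings(as.integer(df$n_replicates)), f, "n_replicates",
    positive = TRUE)
  df$unmeasurable <- as.logical(df$unmeasurable)
  ExperimentDesign(df)
}

#' @rdname readDesign
#' @export
writeDesign <- function(design, path) {
  writeTsv(designTable(design), path)
}

## ---------------------------------------------------------------------------

#' Read and write growth-curve tables
#'
#' `growth.tsv` is long-format tab-separated with columns `condition_id`,
#' `replicate`, `day`, `od750`. Times must be nonnegative and OD values
#' nonnegative; within each (condition, replicate) trace, days must be
#' strictly ascending.
#'
#' @param path File path.
#' @param curves Long `data.frame` as returned by
#'   [generateGrowthCurves()].
#' @return `readGrowthCurves`: the validated `data.frame`;
#'   `writeGrowthCurves`: the path, invisibly.
#' @export
readGrowthCurves <- function(path) {
  f <- basename(path)
  df <- readTsv(path, c("condition_id", "replicate", "day", "od750"))
  df$day <- checkNumeric(suppressWarnings(as.numeric(df$day)), f, "day")
  df$od750 <- checkNumeric(suppressWarnings(as.numeric(df$od750)), f,
                           "od750")
  bad <- which(df$day < 0)
  if (length(bad)) ioStop(f, bad + 1L, "day", "negative time")
  bad <- which(df$od750 < 0)
  if (length(bad)) ioStop(f, bad + 1L, "od750", "negative OD750")
  for (key in split(seq_len(nrow(df)),
                    paste(df$condition_id, df$replicate))) {
    if (is.unsorted(df$day[key], strictly = TRUE))
      ioStop(f, key[1] + 1L, "day",
             "days must be strictly ascending within a replicate trace")
  }
  df
}

#' @rdname readGrowthCurves
#' @export
writeGrowthCurves <- function(curves, path) {
  writeTsv(curves[, c("condition_id", "replicate", "day", "od750")], path)
}

## ---------------------------------------------------------------------------

#' Read and write a feature matrix with its sample sidecar
#'
#' The feature matrix is wide tab-separated text: metadata columns
#' `ion_id`, `mz`, `polarity`, then one intensity column per sample. The
#' sidecar `samples.tsv` holds `sample_id`, `condition_id` (empty for
#' background medium), `replicate`, `sample_class`. The sample columns of
#' the matrix must match the sidecar's `sample_id` set exactly.
#'
#' @param pathMatrix,pathSamples File paths for the wide matrix and the
#'   sample metadata sidecar.
#' @param fm A [FeatureMatrix-class].
#' @return `readFeatureMatrix`: a [FeatureMatrix-class];
#'   `writeFeatureMatrix`: `pathMatrix`, invisibly.
#' @export
readFeatureMatrix <- function(pathMatrix, pathSamples) {
  fM <- basename(pathMatrix)
  fS <- basename(pathSamples)
  mat <- readTsv(pathMatrix, c("ion_id", "mz", "polarity"))
  if (!nrow(mat)) ioStop(fM, 2, "ion_id", "no ions")
  smp <- readTsv(pathSamples, c("sample_id", "condition_id", "replicate",
                                "sample_class"))
  sampleCols <- setdiff(names(mat), c("ion_id", "mz", "polarity"))
  if (!setequal(sampleCols, smp$sample_id) ||
      length(sampleCols) != nrow(smp))
    ioStop(fS, seq_len(nrow(smp)) + 1L, "sample_id",
           "matrix sample columns do not match sample metadata")
  mat$mz <- checkNumeric(suppressWarnings(as.numeric(mat$mz)), fM, "mz",
                         positive = TRUE)
  X <- as.matrix(mat[, smp$sample_id, drop = FALSE])
  suppressWarnings(storage.mode(X) <- "numeric")
  if (anyNA(X))
    ioStop(fM, which(apply(is.na(X), 1, any)) + 1L, "intensity",
           "malformed intensity")
  if (any(X < 0))
    ioStop(fM, which(apply(X < 0, 1, any)) + 1L, "intensity",
           "negative intensity")
  smp$replicate <- checkNumeric(
    suppressWarnings(as.integer(smp$replicate)), fS, "replicate")
  FeatureMatrix(X, mat[, c("ion_id", "mz", "polarity")], smp)
}

#' @rdname readFeatureMatrix
#' @export
writeFeatureMatrix <- function(fm, pathMatrix, pathSamples) {
  rd <- as.data.frame(SummarizedExperiment::rowData(fm))
  out <- cbind(rd[, c("ion_id", "mz", "polarity")],
               as.data.frame(intensities(fm), check.names = FALSE))
  writeTsv(out, pathMatrix)
  writeTsv(as.data.frame(SummarizedExperiment::colData(fm)), pathSamples)
  invisible(pathMatrix)
}

## ---------------------------------------------------------------------------

#' Read and write a metabolite mass table
#'
#' `masses.tsv` holds `metabolite_id` (unique) and
#' `monoisotopic_mass_da` (positive neutral monoisotopic mass, Daltons).
#'
#' @param path File path.
#' @param masses A mass-table `data.frame`.
#' @return `readMassTable`: the validated `data.frame`; `writeMassTable`:
#'   the path, invisibly.
#' @export
readMassTable <- function(path) {
  f <- basename(path)
  df <- readTsv(path, c("metabolite_id", "monoisotopic_mass_da"))
  dup <- which(duplicated(df$metabolite_id))
  if (length(dup))
    ioStop(f, dup + 1L, "metabolite_id", "duplicate metabolite id")
  df$monoisotopic_mass_da <- checkNumeric(
    suppressWarnings(as.numeric(df$monoisotopic_mass_da)), f,
    "monoisotopic_mass_da", positive = TRUE)
  df
}

#' @rdname readMassTable
#' @export
writeMassTable <- function(masses, path) {
  writeTsv(masses[, c("metabolite_id", "monoisotopic_mass_da")], path)
}

## ---------------------------------------------------------------------------

#' Read and write a pathway membership table
#'
#' `pathways.tsv` holds the many-to-many mapping `metabolite_id`,
#' `pathway_id`; duplicate rows are rejected.
#'
#' @param path File path.
#' @param db A membership `data.frame`.
#' @return `readPathwayDB`: the validated `data.frame`; `writePathwayDB`:
#'   the path, invisibly.
#' @export
readPathwayDB <- function(path) {
  f <- basename(path)
  df <- readTsv(path, c("metabolite_id", "pathway_id"))
  dup <- which(duplicated(df[, c("metabolite_id", "pathway_id")]))
  if (length(dup))
    ioStop(f, dup + 1L, "metabolite_id,pathway_id",
           "duplicate membership row")
  df
}

#' @rdname readPathwayDB
#' @export
writePathwayDB <- function(db, path) {
  writeTsv(db[, c("metabolite_id", "pathway_id")], path)
}

## ---------------------------------------------------------------------------

#' Write a full synthetic screen to a directory
#'
#' Emits the standard file set consumed by [runScreen()]: `design.tsv`,
#' `growth.tsv`, `features.tsv`, `samples.tsv`, `masses.tsv`,
#' `pathways.tsv`.
#'
#' @param screen A list as returned by [generateScreen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScreen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDesign(screen$design, file.path(dir, "design.tsv"))
  writeGrowthCurves(screen$growth, file.path(dir, "growth.tsv"))
  writeFeatureMatrix(screen$features, file.path(dir, "features.tsv"),
                     file.path(dir, "samples.tsv"))
  writeMassTable(screen$masses, file.path(dir, "masses.tsv"))
  writePathwayDB(screen$pathways, file.path(dir, "pathways.tsv"))
  invisible(dir)
}

#' Validate a screen input directory
#'
#' Reads every standard file in `dir` through the strict readers and
#' checks cross-file consistency (design conditions present in growth and
#' sample tables).
#'
#' @param dir Directory holding `design.tsv`, `growth.tsv`,
#'   `features.tsv`, `samples.tsv`, `masses.tsv`, `pathways.tsv`.
#' @return Invisibly, a list of the validated objects.
#' @export
validateScreenDir <- function(dir) {
  design <- readDesign(file.path(dir, "design.tsv"))
  growth <- readGrowthCurves(file.path(dir, "growth.tsv"))
  fm <- readFeatureMatrix(file.path(dir, "features.tsv"),
                          file.path(dir, "samples.tsv"))
  masses <- readMassTable(file.path(dir, "masses.tsv"))
  db <- readPathwayDB(file.path(dir, "pathways.tsv"))
  miss <- setdiff(conditionIds(design), unique(growth$condition_id))
  if (length(miss))
    stop("conditions missing from growth curves: ",
         paste(miss, collapse = ", "), call. = FALSE)
  cd <- SummarizedExperiment::colData(fm)
  miss <- setdiff(conditionIds(design),
                  unique(cd$condition_id[cd$sample_class ==
                                           "supernatant_day10"]))
  if (length(miss))
    stop("conditions missing supernatant samples: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(list(design = design, growth = growth, features = fm,
                 masses = masses, pathways = db))
}
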