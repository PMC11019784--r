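## Small in-code fixtures shared across test files.

## Minimal feature matrix built by hand: nIons x (bg + supernatant)
## samples, optional reference samples.
makeFeatureMatrix <- function(intensity, sampleCond, sampleClass,
                              mz = NULL, replicate = NULL) {
  n <- nrow(intensity)
  if (is.null(mz)) mz <- 100 + seq_len(n)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(sampleCond),
                            paste(sampleCond, sampleClass),
                            FUN = seq_along)
  }
  FeatureMatrix(
    intensity,
    ions = data.frame(ion_id = sprintf("ion%03d", seq_len(n)), mz = mz,
                      polarity = "negative", stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = sprintf("s%02d", seq_along(sampleCond)),
      condition_id = sampleCond, replicate = replicate,
      sample_class = sampleClass, stringsAsFactors = FALSE))
}

## A design with the given supplemented condition ids (metabolite, conc).
makeDesign <- function(metabolites, conc = 100, nReplicates = 3L) {
  ExperimentDesign(data.frame(
    condition_id = c(sprintf("%s_%guM", metabolites, conc), "control"),
    metabolite_id = c(metabolites, NA),
    concentration_uM = c(rep(conc, length(metabolites)), NA),
    n_replicates = nReplicates, unmeasurable = FALSE,
    stringsAsFactors = FALSE))
}

## Tiny generator config used by several recovery tests.
tinyConfig <- function(...) {
  syntheticConfig(metabolites = "glucose", concentrationsUm = 100,
                  nIons = 1L, extraMetabolites = NULL, ...)
}
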