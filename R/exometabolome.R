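## The normalization and mixotrophy-calling core: limit-of-detection
## thresholding against background medium, supplement masking, 0-1
## scaling, substrate-drawdown calls and exudate ranking.

#' Per-metabolite limit of detection from background medium
#'
#' For each annotated metabolite label (through its representative ion),
#' the limit of detection is the mean intensity across uninoculated
#' background-medium samples plus three times their standard deviation
#' (sample SD, n-1 denominator).
#'
#' @param fm A [FeatureMatrix-class] with at least two background-medium
#'   samples.
#' @param labelMap Output of [labelIonMap()].
#' @return A `data.frame` with one row per label: `label`, `ion_id`,
#'   `background_mean`, `background_sd`, `lod`.
#' @examples
#' ## background replicates 100, 100, 110 -> mean 103.33, sd 5.774,
#' ## lod = 103.33 + 3 * 5.774 = 120.65
#' @export
computeLod <- function(fm, labelMap) {
  cd <- SummarizedExperiment::colData(fm)
  bg <- which(cd$sample_class == "background_medium")
  if (length(bg) < 2L)
    stop("at least 2 background_medium samples required for the LOD",
         call. = FALSE)
  X <- intensities(fm)[labelMap$ion_id, bg, drop = FALSE]
  mu <- rowMeans(X)
  sdv <- apply(X, 1, sd)
  data.frame(label = labelMap$label, ion_id = labelMap$ion_id,
             background_mean = mu, background_sd = sdv,
             lod = mu + 3 * sdv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize the exometabolome between 0 and 1
#'
#' Applies the three-step normalization to every annotated metabolite
#' label, in order: (1) any supernatant intensity below the limit of
#' detection is reassigned the background-medium mean; (2) in samples of a
#' condition whose own supplement belongs to the label, the intensity is
#' reassigned the background mean (supplement masking); (3) intensities
#' are scaled to `(I - bg_mean) / (I_max - bg_mean)`, where `I_max` is the
#' maximum post-masking intensity across all individual day-10 supernatant
#' samples, and clipped to [0, 1]. A label whose `I_max` does not exceed
#' its LOD is never produced and maps to all zeros. Replicates are
#' averaged per condition after scaling. Cell provenance is
#' `supplement_masked` for masked condition cells, `below_lod_reassigned`
#' when every replicate fell below the LOD, else `measured`.
#'
#' @param fm A [FeatureMatrix-class].
#' @param labelMap Output of [labelIonMap()].
#' @param lod Output of [computeLod()] (recomputed when `NULL`).
#' @param design The [ExperimentDesign-class] of the screen.
#' @return A [NormalizedExometabolome-class], metabolite labels by
#'   conditions.
#' @export
normalizeExometabolome <- function(fm, labelMap, design, lod = NULL) {
  if (is.null(lod)) lod <- computeLod(fm, labelMap)
  stopifnot(identical(lod$label, labelMap$label))
  cd <- SummarizedExperiment::colData(fm)
  sup <- which(cd$sample_class == "supernatant_day10")
  if (!length(sup)) stop("no supernatant_day10 samples", call. = FALSE)
  d <- designTable(design)
  sampleCond <- cd$condition_id[sup]
  sampleMet <- d$metabolite_id[match(sampleCond, d$condition_id)]
  conds <- d$condition_id[d$condition_id %in% sampleCond]

  X <- intensities(fm)[labelMap$ion_id, sup, drop = FALSE]
  members <- labelMembers(labelMap$metabolite_ids)
  nL <- nrow(labelMap)

  belowLod <- X < lod$lod                      # step 1
  X[belowLod] <- lod$background_mean[row(X)[belowLod]]
  masked <- matrix(FALSE, nL, length(sup))     # step 2
  for (i in seq_len(nL)) {
    hit <- !is.na(sampleMet) & sampleMet %in% members[[i]]
    if (any(hit)) {
      X[i, hit] <- lod$background_mean[i]
      masked[i, hit] <- TRUE
    }
  }
  iMax <- apply(X, 1, max)                     # step 3
  produced <- iMax > lod$lod
  denom <- ifelse(produced, iMax - lod$background_mean, 1)
  N <- (X - lod$background_mean) / denom
  N[!produced, ] <- 0
  N <- pmin(pmax(N, 0), 1)

  ## replicate means per condition, flags aggregated
  condIdx <- lapply(conds, function(id) which(sampleCond == id))
  normMat <- vapply(condIdx, function(j)
    rowMeans(N[, j, drop = FALSE]), numeric(nL))
  maskFlag <- vapply(condIdx, function(j)
    apply(masked[, j, drop = FALSE], 1, all), logical(nL))
  lodFlag <- vapply(condIdx, function(j)
    apply(belowLod[, j, drop = FALSE], 1, all), logical(nL))
  if (nL == 1L) {  # vapply drops to vector symmetry
    normMat <- matrix(normMat, nrow = 1L)
    maskFlag <- matrix(maskFlag, nrow = 1L)
    lodFlag <- matrix(lodFlag, nrow = 1L)
  }
  normMat[maskFlag] <- 0
  prov <- matrix("measured", nL, length(conds))
  prov[lodFlag] <- "below_lod_reassigned"
  prov[maskFlag] <- "supplement_masked"
  dimnames(normMat) <- dimnames(prov) <- list(labelMap$label, conds)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(norm = normMat, provenance = prov),
    rowData = S4Vectors::DataFrame(label = labelMap$label,
                                   metabolite_ids = labelMap$metabolite_ids,
                                   ion_id = labelMap$ion_id),
    colData = S4Vectors::DataFrame(condition_id = conds,
                                   row.names = conds))
  new("NormalizedExometabolome", se)
}

#' Call substrate consumption and mixotrophy
#'
#' For every measurable supplemented (metabolite, concentration) pair:
#' `fraction_consumed = max(0, 1 - mean(day-10 supernatant) /
#' mean(sterile supplemented-medium reference))` on the supplement's
#' representative ion, with a two-sided Welch t test between the
#' supernatant and reference replicate intensities. A condition is called
#' mixotrophic when the reduction is at least `threshold` (default 10%)
#' and `p < alpha`; a metabolite is mixotrophic overall when the call
#' holds at either concentration. Supplements flagged unmeasurable in the
#' design are excluded.
#'
#' @param fm A [FeatureMatrix-class] with supplemented-reference samples.
#' @param labelMap Output of [labelIonMap()].
#' @param design The [ExperimentDesign-class].
#' @param threshold Minimum consumed fraction (default 0.10).
#' @param alpha Significance level (default 0.05).
#' @return A `data.frame` with one row per measurable supplemented
#'   condition: `condition_id`, `metabolite_id`, `concentration_uM`,
#'   `fraction_consumed`, `p_value`, `is_mixotrophic`, plus attribute
#'   `mixotrophic_metabolites` (character vector of overall calls).
#' @export
consumptionCalls <- function(fm, labelMap, design, threshold = 0.10,
                             alpha = 0.05) {
  d <- designTable(design)
  d <- d[!is.na(d$metabolite_id) & !d$unmeasurable, , drop = FALSE]
  cd <- SummarizedExperiment::colData(fm)
  X <- intensities(fm)
  members <- labelMembers(labelMap$metabolite_ids)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    met <- d$metabolite_id[i]
    cid <- d$condition_id[i]
    li <- which(vapply(members, function(m) met %in% m, logical(1)))
    if (!length(li))
      stop(sprintf("supplement '%s' not resolvable to an annotated ion; flag it unmeasurable in the design",
                   met), call. = FALSE)
    ion <- labelMap$ion_id[li[1]]
    supIdx <- cd$sample_class == "supernatant_day10" &
      cd$condition_id == cid & !is.na(cd$condition_id)
    refIdx <- cd$sample_class == "supplemented_reference" &
      cd$condition_id == cid & !is.na(cd$condition_id)
    if (!any(refIdx))
      stop(sprintf("no supplemented_reference samples for condition '%s'",
                   cid), call. = FALSE)
    s <- X[ion, supIdx]; r <- X[ion, refIdx]
    frac <- max(0, 1 - mean(s) / mean(r))
    p <- welchTTest(s, r)$p_value
    data.frame(condition_id = cid, metabolite_id = met,
               concentration_uM = d$concentration_uM[i],
               fraction_consumed = frac, p_value = p,
               is_mixotrophic = frac >= threshold & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mets <- sort(unique(out$metabolite_id[out$is_mixotrophic]))
  attr(out, "mixotrophic_metabolites") <- mets
  out
}

#' Rank exuded metabolites by summed normalized intensity
#'
#' Sums each metabolite label's normalized intensity over all conditions
#' and ranks descending (rank 1 = most exuded); ties break
#' lexicographically by label. `n_producing_conditions` counts conditions
#' with a normalized value above zero.
#'
#' @param norm A [NormalizedExometabolome-class].
#' @return A `data.frame` sorted by rank: `label`,
#'   `summed_normalized_intensity`, `n_producing_conditions`, `rank`.
#' @export
rankExudates <- function(norm) {
  X <- normValues(norm)
  if (!nrow(X)) stop("normalized matrix is empty", call. = FALSE)
  s <- rowSums(X)
  out <- data.frame(label = rownames(X),
                    summed_normalized_intensity = s,
                    n_producing_conditions = rowSums(X > 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$summed_normalized_intensity, out$label), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
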