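## Exact-mass annotation of negative-mode ions, with isobar collapsing.

#' Neutral mass from an m/z value
#'
#' For a singly deprotonated negative-mode ion [M-H]-, the neutral
#' monoisotopic mass is `m/z * charge + charge * 1.007276 Da` (the proton
#' mass added back per charge).
#'
#' @param mz Observed m/z in Daltons (positive).
#' @param charge Charge state (integer >= 1, default 1).
#' @return Neutral mass in Daltons.
#' @examples
#' neutralMassFromMz(130.087353)  # leucine [M-H]- -> 131.094629
#' @export
neutralMassFromMz <- function(mz, charge = 1L) {
  if (any(mz <= 0)) stop("mz must be positive", call. = FALSE)
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  mz * charge + charge * PROTON_MASS_DA
}

#' Annotate ions by exact mass
#'
#' Matches each ion's inferred neutral mass ([M-H]- assumed) against a
#' metabolite mass table within a ppm tolerance. When several isobaric
#' metabolites match one ion they are collapsed into a single ambiguous
#' label (ids sorted and joined with ";", e.g. `isoleucine;leucine`). Ions
#' with no match are retained with an empty label so downstream stages can
#' carry unannotated features. Output is independent of ion and mass-table
#' ordering.
#'
#' @param ions Either a [FeatureMatrix-class] or a `data.frame` with
#'   `ion_id` and `mz`.
#' @param masses Mass table `data.frame(metabolite_id,
#'   monoisotopic_mass_da)`.
#' @param tolPpm Match tolerance in parts per million (default 10).
#' @return A `data.frame` with one row per ion: `ion_id`, `mz`, `label`
#'   (empty string when unannotated), `metabolite_ids` (";"-joined) and
#'   `ppm_error` (";"-joined signed errors, one per match).
#' @export
annotateIons <- function(ions, masses, tolPpm = 10) {
  if (tolPpm <= 0) stop("tolPpm must be positive", call. = FALSE)
  if (is(ions, "FeatureMatrix"))
    ions <- as.data.frame(SummarizedExperiment::rowData(ions))
  neutral <- neutralMassFromMz(ions$mz)
  mtab <- masses[order(masses$metabolite_id), ]
  rows <- lapply(seq_along(neutral), function(i) {
    ppm <- (neutral[i] - mtab$monoisotopic_mass_da) /
      mtab$monoisotopic_mass_da * 1e6
    hit <- which(abs(ppm) <= tolPpm)
    data.frame(
      ion_id = ions$ion_id[i], mz = ions$mz[i],
      label = paste(mtab$metabolite_id[hit], collapse = ";"),
      metabolite_ids = paste(mtab$metabolite_id[hit], collapse = ";"),
      ppm_error = paste(sprintf("%.4g", ppm[hit]), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Split a ";"-joined member list.
labelMembers <- function(x) strsplit(x, ";", fixed = TRUE)

#' Map annotated metabolite labels to representative ions
#'
#' When several ions carry the same annotation label, downstream analyses
#' use the ion with the maximal summed intensity across all samples for
#' that label; ties break by ion id.
#'
#' @param annotations Output of [annotateIons()].
#' @param fm The [FeatureMatrix-class] the annotations refer to.
#' @return A `data.frame` with one row per annotated label: `label`,
#'   `metabolite_ids`, `ion_id` (the representative ion).
#' @export
labelIonMap <- function(annotations, fm) {
  ann <- annotations[nzchar(annotations$label), , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(label = character(), metabolite_ids = character(),
                      ion_id = character(), stringsAsFactors = FALSE))
  tot <- rowSums(intensities(fm))
  names(tot) <- rownames(fm)
  rows <- lapply(split(ann, ann$label), function(g) {
    g <- g[order(-tot[g$ion_id], g$ion_id), ]
    g[1, c("label", "metabolite_ids", "ion_id")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  out
}
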