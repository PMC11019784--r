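## Per-condition metabolic pathway importance: which pathways are most
## represented among the metabolites a culture exudes.

#' Score pathway representation per condition
#'
#' A metabolite is "produced" in a condition when its normalized intensity
#' exceeds `producedMin` (default 0, i.e. above the limit of detection
#' after supplement masking). Labels collapsing several isobaric
#' metabolites contribute each member. Per condition, each pathway's score
#' is the number of produced metabolites belonging to it divided by a
#' condition-level denominator: with `denominator = "distinct"` (default)
#' the number of distinct produced metabolites mapping to at least one
#' pathway, so scores are interpretable fractions in [0, 1]; with
#' `"multiplicity"` the sum of per-pathway produced counts, weighting
#' metabolites by how many pathways they join. Pathways are ranked by
#' score descending within each condition, ties broken by pathway id.
#' Conditions with no produced pathway-mapped metabolite are emitted with
#' no pathway rows and flagged in the `undefined_conditions` attribute.
#'
#' @param norm A [NormalizedExometabolome-class].
#' @param db Pathway membership `data.frame(metabolite_id, pathway_id)`.
#' @param producedMin Production threshold on normalized intensity
#'   (default 0, strict inequality).
#' @param denominator `"distinct"` or `"multiplicity"` (see above).
#' @return A `data.frame` with columns `condition_id`, `pathway_id`,
#'   `n_produced_in_pathway`, `score`, `rank`; attribute
#'   `undefined_conditions` lists conditions with no produced mapped
#'   metabolites.
#' @export
scorePathways <- function(norm, db, producedMin = 0,
                          denominator = c("distinct", "multiplicity")) {
  denominator <- match.arg(denominator)
  if (!nrow(db)) stop("pathway membership table is empty", call. = FALSE)
  X <- normValues(norm)
  members <- labelMembers(
    SummarizedExperiment::rowData(norm)$metabolite_ids)
  pathways <- sort(unique(db$pathway_id))
  undef <- character(0)
  rows <- list()
  for (cid in colnames(X)) {
    produced <- unique(unlist(members[X[, cid] > producedMin]))
    mapped <- intersect(produced, db$metabolite_id)
    counts <- vapply(pathways, function(p)
      length(intersect(mapped, db$metabolite_id[db$pathway_id == p])),
      integer(1))
    den <- if (denominator == "distinct") length(mapped) else sum(counts)
    if (den == 0) {
      undef <- c(undef, cid)
      next
    }
    sc <- counts / den
    ord <- order(-sc, pathways)
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = cid, pathway_id = pathways[ord],
      n_produced_in_pathway = counts[ord], score = sc[ord],
      rank = seq_along(pathways), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition_id = character(), pathway_id = character(),
               n_produced_in_pathway = integer(), score = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "undefined_conditions") <- undef
  out
}
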