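## PCA of normalized exometabolome profiles across conditions, and
## extraction of extreme-loading metabolites.

#' PCA of exometabolome condition profiles
#'
#' Rows are conditions (replicate means, one profile per condition),
#' columns are metabolite labels. Columns are mean-centered across
#' conditions without variance scaling (values already share the 0-1
#' normalized scale); the decomposition is by singular values via
#' [stats::prcomp()]. A deterministic sign convention is applied: within
#' each component, the largest-magnitude loading is made positive (ties
#' broken by metabolite label), with scores flipped to match, so output is
#' reproducible across runs and platforms. Conditions classified as
#' complete inhibition can be excluded via `exclude` -- cultures that never
#' grew have no exometabolome and would otherwise cluster as an artifact.
#'
#' @param norm A [NormalizedExometabolome-class].
#' @param nComponents Number of components to keep (default: all,
#'   `min(conditions, metabolites)` after centering).
#' @param exclude Character vector of condition ids to drop before the
#'   decomposition (e.g. no-growth conditions).
#' @return A list of class `PcaResult`: `scores` (condition x component),
#'   `loadings` (metabolite x component, orthonormal columns),
#'   `explained_variance_fraction`, `center` (column means).
#' @export
exoPca <- function(norm, nComponents = NULL, exclude = character(0)) {
  X <- t(normValues(norm))
  X <- X[!rownames(X) %in% exclude, , drop = FALSE]
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("PCA needs at least 2 conditions and 2 metabolites", call. = FALSE)
  maxComp <- min(nrow(X) - 1L, ncol(X))
  if (is.null(nComponents)) nComponents <- maxComp
  if (nComponents > maxComp)
    stop(sprintf("nComponents (%d) exceeds min dimension (%d)",
                 nComponents, maxComp), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  load <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  ## deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(load))) {
    i <- order(-abs(load[, j]), rownames(load))[1]
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  res <- list(scores = scores, loadings = load,
              explained_variance_fraction = evf[k],
              center = pc$center)
  class(res) <- "PcaResult"
  res
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf("PcaResult: %d conditions x %d metabolites, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores),
              100 * x$explained_variance_fraction[1],
              if (length(x$explained_variance_fraction) > 1)
                100 * x$explained_variance_fraction[2] else NA))
  invisible(x)
}

#' Extract extreme-loading metabolites of a component
#'
#' Returns the `k` metabolites with the most positive and the `k` with the
#' most negative loading on one component, each ordered by loading
#' magnitude with ties broken by metabolite label. Metabolites with
#' loadings of the opposite sign never enter the respective list, so fewer
#' than `k` may be returned; `k` larger than the metabolite count
#' truncates with a warning.
#'
#' @param res A `PcaResult` from [exoPca()].
#' @param component Component index (1-based).
#' @param k Number of metabolites per direction (default 5).
#' @return A list with `positive` and `negative`, each a `data.frame`
#'   (`label`, `loading`).
#' @export
topLoadings <- function(res, component, k = 5L) {
  if (component < 1L || component > ncol(res$loadings))
    stop(sprintf("component %d not in result (1..%d)", component,
                 ncol(res$loadings)), call. = FALSE)
  v <- res$loadings[, component]
  if (k > length(v)) {
    warning(sprintf("k = %d exceeds the %d metabolites; truncating", k,
                    length(v)))
    k <- length(v)
  }
  pos <- v[v > 0]
  neg <- v[v < 0]
  posOut <- if (length(pos) && k > 0) {
    ord <- names(pos)[order(-pos, names(pos))][seq_len(min(k, length(pos)))]
    data.frame(label = ord, loading = unname(v[ord]),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(), loading = numeric(),
                    stringsAsFactors = FALSE)
  negOut <- if (length(neg) && k > 0) {
    ord <- names(neg)[order(neg, names(neg))][seq_len(min(k, length(neg)))]
    data.frame(label = ord, loading = unname(v[ord]),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(), loading = numeric(),
                    stringsAsFactors = FALSE)
  list(positive = posOut, negative = negOut)
}
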