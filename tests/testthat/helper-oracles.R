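## Independent oracles, written as plain scalar loops so they share no
## code path with the vectorized implementations they check.

## Spreadsheet-style normalization: per metabolite label, walk the samples
## one by one through LOD reassignment, supplement masking and 0-1
## scaling, then average replicates per condition.
oracleNormalize <- function(intensity, bgCols, supCols, sampleCond,
                            condSupplement, labelMembers) {
  nL <- nrow(intensity)
  conds <- unique(sampleCond)
  out <- matrix(0, nL, length(conds), dimnames = list(rownames(intensity),
                                                      conds))
  for (i in seq_len(nL)) {
    bg <- intensity[i, bgCols]
    mu <- sum(bg) / length(bg)
    sdv <- sqrt(sum((bg - mu)^2) / (length(bg) - 1))
    lod <- mu + 3 * sdv
    vals <- numeric(length(supCols))
    for (j in seq_along(supCols)) {
      v <- intensity[i, supCols[j]]
      if (v < lod) v <- mu
      supp <- condSupplement[[sampleCond[j]]]
      if (!is.null(supp) && !is.na(supp) && supp %in% labelMembers[[i]])
        v <- mu
      vals[j] <- v
    }
    iMax <- max(vals)
    for (j in seq_along(vals)) {
      if (iMax <= lod) vals[j] <- 0
      else {
        x <- (vals[j] - mu) / (iMax - mu)
        vals[j] <- min(max(x, 0), 1)
      }
    }
    for (cid in conds) {
      sel <- which(sampleCond == cid)
      m <- mean(vals[sel])
      supp <- condSupplement[[cid]]
      if (!is.null(supp) && !is.na(supp) && supp %in% labelMembers[[i]])
        m <- 0
      out[i, cid] <- m
    }
  }
  out
}

## Definitional pathway scoring: enumerate produced metabolites and count
## memberships pathway by pathway.
oraclePathwayScores <- function(producedByCond, db) {
  res <- list()
  for (cid in names(producedByCond)) {
    produced <- producedByCond[[cid]]
    mapped <- character(0)
    for (m in produced)
      if (m %in% db$metabolite_id) mapped <- union(mapped, m)
    if (length(mapped) == 0) next
    for (p in sort(unique(db$pathway_id))) {
      count <- 0L
      for (m in mapped)
        if (any(db$metabolite_id == m & db$pathway_id == p))
          count <- count + 1L
      res[[length(res) + 1L]] <- data.frame(
        condition_id = cid, pathway_id = p, n = count,
        score = count / length(mapped), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

## Eigen-decomposition PCA oracle on the covariance matrix.
oraclePcaVariances <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  ev
}
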