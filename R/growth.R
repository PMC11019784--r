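## Growth-curve summaries and per-condition effect classification against
## the unsupplemented control.

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test between two replicate groups:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom. Implemented in closed form so
#' the zero-variance limits of noiseless synthetic data are well defined:
#' when both group variances are zero, equal means give `p = 1` (no
#' evidence of difference) and unequal means give `t = +/-Inf`, `p = 0`
#' (the difference is exact). Cross-checked against [stats::t.test()] on
#' nondegenerate inputs in the test suite.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @return A list with `statistic` (t), `df` (Welch-Satterthwaite, real)
#'   and `p_value` (two-sided).
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4, p = 0.288
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("groups must not contain NA", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (dm == 0)
      return(list(statistic = 0, df = na + nb - 2, p_value = 1))
    return(list(statistic = sign(dm) * Inf, df = na + nb - 2, p_value = 0))
  }
  se2 <- va / na + vb / nb
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Summarize growth curves per condition
#'
#' Computes, per condition, the mean and SD of the final-day OD750 across
#' replicates and the R-squared of a linear regression of `ln(OD750)` on
#' time over the exponential window (default days 0-4, endpoints
#' inclusive; days are used as sampled, without interpolation).
#' Nonpositive OD values inside the window are excluded from the log
#' regression and flagged. A regression with zero OD variance (flat trace)
#' has undefined R-squared and is reported as 0 with `r2_flag`.
#'
#' @param curves Long growth table (`condition_id`, `replicate`, `day`,
#'   `od750`).
#' @param dayFinal Day of the final-OD summary (default 10).
#' @param expWindow Two-element numeric, the exponential-phase regression
#'   window in days (default `c(0, 4)`).
#' @return A `data.frame` with one row per condition: `condition_id`,
#'   `final_od_mean`, `final_od_sd`, `n_replicates`, `exp_phase_r2`,
#'   `r2_flag` (TRUE when R-squared is a reported convention, not a fit),
#'   plus a list-column `final_od_values` holding the replicate final ODs
#'   used by [classifyGrowth()].
#' @export
summarizeGrowth <- function(curves, dayFinal = 10, expWindow = c(0, 4)) {
  conds <- unique(curves$condition_id)
  rows <- lapply(conds, function(id) {
    g <- curves[curves$condition_id == id, ]
    fin <- g$od750[g$day == dayFinal]
    if (!length(fin))
      stop(sprintf("condition '%s' has no timepoint at day %g", id,
                   dayFinal), call. = FALSE)
    if (length(fin) < 2L)
      stop(sprintf("condition '%s' has fewer than 2 replicates at day %g",
                   id, dayFinal), call. = FALSE)
    w <- g[g$day >= expWindow[1] & g$day <= expWindow[2], ]
    flag <- any(w$od750 <= 0)
    w <- w[w$od750 > 0, ]
    if (nrow(w) >= 3L && var(w$day) > 0 && var(log(w$od750)) > 0) {
      fit <- lm(log(od750) ~ day, data = w)
      y <- log(w$od750)
      r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    } else {
      r2 <- 0
      flag <- TRUE
    }
    data.frame(condition_id = id,
               final_od_mean = mean(fin), final_od_sd = sd(fin),
               n_replicates = length(fin),
               exp_phase_r2 = r2, r2_flag = flag,
               final_od_values = I(list(fin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify growth effects against the control
#'
#' For each supplemented condition: `complete_inhibition` when the final
#' mean OD750 is below `noGrowthThresholdOd`; otherwise `enhanced` when
#' the Welch test against the control is significant (`p < alpha`) and the
#' mean exceeds the control mean, `inhibited` when significant and below,
#' else `none`. Per-condition p values are reported uncorrected, mirroring
#' a per-condition screening readout; `fdr = TRUE` applies
#' Benjamini-Hochberg across conditions before thresholding.
#'
#' @param summaries Output of [summarizeGrowth()] (must include the
#'   control and the `final_od_values` list-column).
#' @param controlId Condition id of the unsupplemented control.
#' @param alpha Significance level (default 0.05).
#' @param noGrowthThresholdOd Final mean OD750 below which a condition is
#'   called completely inhibited regardless of the test (default 0.05,
#'   i.e. less than five times the 0.01 inoculum).
#' @param fdr Apply Benjamini-Hochberg correction across conditions
#'   (default `FALSE`).
#' @return A `data.frame` with one row per non-control condition:
#'   `condition_id`, `p_value`, `fold_change` (condition mean / control
#'   mean) and `effect_class`.
#' @export
classifyGrowth <- function(summaries, controlId, alpha = 0.05,
                           noGrowthThresholdOd = 0.05, fdr = FALSE) {
  ci <- match(controlId, summaries$condition_id)
  if (is.na(ci))
    stop(sprintf("control condition '%s' not in summaries", controlId),
         call. = FALSE)
  ctrl <- summaries$final_od_values[[ci]]
  rest <- summaries[-ci, , drop = FALSE]
  p <- vapply(rest$final_od_values,
              function(v) welchTTest(v, ctrl)$p_value, numeric(1))
  pAdj <- if (fdr) stats::p.adjust(p, "BH") else p
  fc <- rest$final_od_mean / mean(ctrl)
  cls <- ifelse(rest$final_od_mean < noGrowthThresholdOd,
                "complete_inhibition",
         ifelse(pAdj < alpha & rest$final_od_mean > mean(ctrl), "enhanced",
         ifelse(pAdj < alpha & rest$final_od_mean < mean(ctrl), "inhibited",
                "none")))
  data.frame(condition_id = rest$condition_id,
             p_value = p,
             fold_change = fc,
             effect_class = cls,
             stringsAsFactors = FALSE)
}
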