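lmap <- function(labels, ions = NULL) {
  data.frame(label = labels, metabolite_ids = labels,
             ion_id = if (is.null(ions)) sprintf("ion%03d",
                                                 seq_along(labels)) else ions,
             stringsAsFactors = FALSE)
}

test_that("limit of detection is background mean plus three SDs", {
  X <- rbind(c(100, 100, 100, 500), c(100, 100, 110, 500))
  fm <- makeFeatureMatrix(X, sampleCond = c(NA, NA, NA, "c1"),
                          sampleClass = c(rep("background_medium", 3),
                                          "supernatant_day10"))
  lod <- computeLod(fm, lmap(c("a", "b")))
  expect_equal(lod$lod[1], 100)                      # SD 0
  expect_equal(lod$background_mean[2], 103.33333, tolerance = 1e-6)
  expect_equal(lod$background_sd[2], 5.7735027, tolerance = 1e-6)
  expect_equal(lod$lod[2], 120.65384, tolerance = 1e-6)
  ## linearity: doubling the spread doubles lod - mean
  X2 <- rbind(c(100, 100, 120, 500))
  fm2 <- makeFeatureMatrix(X2, sampleCond = c(NA, NA, NA, "c1"),
                           sampleClass = c(rep("background_medium", 3),
                                           "supernatant_day10"))
  lod2 <- computeLod(fm2, lmap("a"))
  expect_equal(lod2$lod - lod2$background_mean,
               2 * (lod$lod[2] - lod$background_mean[2]), tolerance = 1e-9)
  ## fewer than two background samples is an error
  fm1 <- makeFeatureMatrix(rbind(c(100, 500)), sampleCond = c(NA, "c1"),
                           sampleClass = c("background_medium",
                                           "supernatant_day10"))
  expect_error(computeLod(fm1, lmap("a")), "background_medium")
})

## One metabolite per row; bg samples all exactly 100 so LOD = mean = 100.
normFixture <- function(X, conds, design, nBg = 2) {
  bg <- matrix(100, nrow(X), nBg)
  fm <- makeFeatureMatrix(cbind(bg, X),
                          sampleCond = c(rep(NA, nBg), conds),
                          sampleClass = c(rep("background_medium", nBg),
                                          rep("supernatant_day10",
                                              length(conds))))
  normalizeExometabolome(fm, lmap(rownames(X)), design)
}

test_that("normalization maps the stated worked examples", {
  design <- makeDesign("glucose")
  ## one metabolite, three conditions at 100/150/200 -> 0 / 0.5 / 1
  X <- matrix(c(100, 150, 200), 1,
              dimnames = list("met_a", NULL))
  n <- normFixture(X, c("control", "control", "glucose_100uM"), design)
  ## max over individual samples = 200; condition means after scaling
  expect_equal(normValues(n)["met_a", "control"], mean(c(0, 0.5)))
  expect_equal(normValues(n)["met_a", "glucose_100uM"], 1.0)

  ## below-LOD reassignment: lod from bg [100,100,110]
  bg <- matrix(c(100, 100, 110), 1, 3)
  fm <- makeFeatureMatrix(cbind(bg, matrix(c(115, 300), 1)),
                          sampleCond = c(NA, NA, NA, "control", "control"),
                          sampleClass = c(rep("background_medium", 3),
                                          rep("supernatant_day10", 2)))
  n2 <- normalizeExometabolome(fm, lmap("met_a"), design)
  ## 115 < lod 120.65 -> reassigned to 103.33 -> scaled to 0
  v <- normValues(n2)["met_a", "control"]
  expect_equal(v, mean(c(0, (300 - 103.33333) / (300 - 103.33333))),
               tolerance = 1e-6)

  ## supplement masking: glucose in its own condition is exactly 0
  X3 <- rbind(glucose = c(5000, 200), met_b = c(400, 400))
  n3 <- normFixture(X3, c("glucose_100uM", "control"), design)
  expect_equal(normValues(n3)["glucose", "glucose_100uM"], 0)
  expect_equal(provenance(n3)["glucose", "glucose_100uM"],
               "supplement_masked")
  expect_equal(normValues(n3)["glucose", "control"], 1)
})

test_that("normalization agrees with the step-by-step oracle to 1e-12", {
  set.seed(77)
  design <- makeDesign(c("glucose", "valine"))
  condSupp <- list(glucose_100uM = "glucose", valine_100uM = "valine",
                   control = NA)
  for (rep_ in 1:25) {
    nIons <- sample(1:5, 1)
    conds <- rep(c("glucose_100uM", "valine_100uM", "control"), each = 2)
    labels <- c("glucose", "valine", "met_c", "met_d",
                "met_e")[seq_len(nIons)]
    nBg <- sample(2:3, 1)
    bg <- matrix(runif(nIons * nBg, 50, 150), nIons)
    X <- matrix(runif(nIons * length(conds), 10, 1000), nIons,
                dimnames = list(labels, NULL))
    fm <- makeFeatureMatrix(cbind(bg, X),
                            sampleCond = c(rep(NA, nBg), conds),
                            sampleClass = c(rep("background_medium", nBg),
                                            rep("supernatant_day10",
                                                length(conds))))
    got <- normValues(normalizeExometabolome(fm, lmap(labels), design))
    want <- oracleNormalize(cbind(bg, X), bgCols = seq_len(nBg),
                            supCols = nBg + seq_along(conds),
                            sampleCond = conds,
                            condSupplement = condSupp,
                            labelMembers = as.list(labels))
    expect_equal(got, want[, colnames(got), drop = FALSE],
                 tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("normalization is invariant to per-metabolite intensity scale", {
  design <- makeDesign("glucose")
  X <- rbind(met_a = c(150, 220, 370))
  conds <- c("control", "glucose_100uM", "glucose_100uM")
  n1 <- normValues(normFixture(X, conds, design))
  bg <- matrix(100 * 7, 1, 2)
  fm <- makeFeatureMatrix(cbind(bg, X * 7),
                          sampleCond = c(NA, NA, conds),
                          sampleClass = c(rep("background_medium", 2),
                                          rep("supernatant_day10", 3)))
  n2 <- normValues(normalizeExometabolome(fm, lmap("met_a"), design))
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("never-produced metabolites normalize to all zeros", {
  design <- makeDesign("glucose")
  X <- rbind(met_a = c(100, 100, 100))
  n <- normFixture(X, c("control", "glucose_100uM", "glucose_100uM"),
                   design)
  expect_true(all(normValues(n) == 0))
})

test_that("isobaric supplement labels are masked in every member's condition", {
  design <- makeDesign(c("leucine", "valine"))
  X <- rbind("isoleucine;leucine" = c(900, 500, 400))
  n <- normFixture(X, c("leucine_100uM", "valine_100uM", "control"),
                   design)
  expect_equal(normValues(n)["isoleucine;leucine", "leucine_100uM"], 0)
  expect_equal(provenance(n)["isoleucine;leucine", "leucine_100uM"],
               "supplement_masked")
  expect_gt(normValues(n)["isoleucine;leucine", "valine_100uM"], 0)
})

consumptionFixture <- function(supVals, refVals, met = "glucose",
                               conc = 100) {
  design <- makeDesign(met, conc = conc)
  cid <- sprintf("%s_%guM", met, conc)
  X <- matrix(c(100, 100, supVals, refVals), 1,
              dimnames = list(met, NULL))
  fm <- makeFeatureMatrix(
    X, sampleCond = c(NA, NA, rep(cid, length(supVals)),
                      rep(cid, length(refVals))),
    sampleClass = c(rep("background_medium", 2),
                    rep("supernatant_day10", length(supVals)),
                    rep("supplemented_reference", length(refVals))))
  consumptionCalls(fm, lmap(met), design)
}

test_that("consumption fraction and mixotrophy thresholds are applied", {
  cc <- consumptionFixture(c(400, 400, 400), c(1000, 1000, 1001))
  expect_equal(cc$fraction_consumed, 1 - 400 / mean(c(1000, 1000, 1001)),
               tolerance = 1e-12)
  expect_true(cc$is_mixotrophic)

  ## 5% reduction never qualifies, whatever the p value
  cc <- consumptionFixture(c(950, 950, 950), c(1000, 1000, 1001))
  expect_false(cc$is_mixotrophic)
  expect_lt(cc$fraction_consumed, 0.10)

  ## increase clamps to zero consumption
  cc <- consumptionFixture(c(1200, 1210, 1190), c(1000, 1000, 1001))
  expect_equal(cc$fraction_consumed, 0)

  ## missing reference samples abort with the condition named
  design <- makeDesign("glucose")
  fm <- makeFeatureMatrix(matrix(c(100, 100, 400), 1,
                                 dimnames = list("glucose", NULL)),
                          sampleCond = c(NA, NA, "glucose_100uM"),
                          sampleClass = c("background_medium",
                                          "background_medium",
                                          "supernatant_day10"))
  expect_error(consumptionCalls(fm, lmap("glucose"), design),
               "glucose_100uM")
})

test_that("mixotrophy recovery on the generator: planted 0.30 called, 0 not", {
  nCalled <- 0L; nFalse <- 0L
  for (s in 1:40) {
    cfg <- tinyConfig(noiseCv = 0.05, seed = s)
    design <- generateDesign(cfg)
    mkTruth <- function(frac) GroundTruth(
      growth = data.frame(condition_id = conditionIds(design),
                          growth_class = "none", od_multiplier = 1,
                          stringsAsFactors = FALSE),
      drawdown = if (frac > 0) data.frame(condition_id = "glucose_100uM",
                                          metabolite_id = "glucose",
                                          fraction = frac,
                                          stringsAsFactors = FALSE)
                 else data.frame(condition_id = character(),
                                 metabolite_id = character(),
                                 fraction = numeric()))
    masses <- configMassTable(cfg)
    for (frac in c(0.30, 0)) {
      fm <- generateFeatureMatrix(design, mkTruth(frac), masses, cfg)
      lm_ <- labelIonMap(annotateIons(fm, masses), fm)
      cc <- consumptionCalls(fm, lm_, design)
      if (frac > 0) nCalled <- nCalled + cc$is_mixotrophic
      else nFalse <- nFalse + cc$is_mixotrophic
    }
  }
  expect_gte(nCalled, 38)  # >= 95% power at planted drawdown 0.30
  expect_lte(nFalse, 2)    # <= 5% false calls at zero drawdown
})

test_that("exudate ranking sums, orders and counts producing conditions", {
  X <- rbind(high = rep(1, 10),
             mid = c(rep(0.5, 6), rep(0, 4)),
             zero = rep(0, 10))
  pv <- matrix("measured", 3, 10)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(norm = X, provenance = pv),
    rowData = S4Vectors::DataFrame(label = rownames(X),
                                   metabolite_ids = rownames(X),
                                   ion_id = sprintf("i%d", 1:3)),
    colData = S4Vectors::DataFrame(condition_id = sprintf("c%d", 1:10)))
  colnames(se) <- sprintf("c%d", 1:10)
  norm <- new("NormalizedExometabolome", se)
  r <- rankExudates(norm)
  expect_equal(r$label, c("high", "mid", "zero"))
  expect_equal(r$summed_normalized_intensity, c(10, 3, 0))
  expect_equal(r$rank, 1:3)
  expect_equal(r$n_producing_conditions, c(10L, 6L, 0L))
  ## condition order does not change the sums
  r2 <- rankExudates(norm[, sample(10)])
  expect_equal(r2, r)
})

test_that("planted top exuders are recovered by the ranking", {
  set.seed(9)
  pool <- data.frame(metabolite_id = sprintf("p%02d", 1:100),
                     monoisotopic_mass_da = 300 + 2.5 * (1:100))
  cfg <- syntheticConfig(metabolites = c("glucose", "valine", "serine"),
                         concentrationsUm = c(100, 5000), nIons = 103,
                         extraMetabolites = pool, noiseCv = 0.05,
                         seed = 21)
  design <- generateDesign(cfg)
  planted <- sprintf("p%02d", 1:10)
  conds <- setdiff(conditionIds(design), "control")
  exu <- expand.grid(condition_id = conds, metabolite_id = planted,
                     stringsAsFactors = FALSE)
  exu$fold <- 30
  truth <- GroundTruth(
    growth = data.frame(condition_id = conditionIds(design),
                        growth_class = "none", od_multiplier = 1,
                        stringsAsFactors = FALSE),
    exudation = exu)
  fm <- generateFeatureMatrix(design, truth, configMassTable(cfg), cfg)
  lm_ <- labelIonMap(annotateIons(fm, configMassTable(cfg)), fm)
  norm <- normalizeExometabolome(fm, lm_, design)
  top10 <- rankExudates(norm)$label[1:10]
  expect_setequal(top10, planted)
})
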