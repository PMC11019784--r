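test_that("design enumeration yields one condition per pair plus control", {
  d65 <- generateDesign(syntheticConfig(nMetabolites = 32))
  expect_equal(nrow(designTable(d65)), 65L)
  expect_equal(sum(!is.na(designTable(d65)$metabolite_id)), 64L)
  expect_equal(length(controlId(d65)), 1L)

  d2 <- generateDesign(syntheticConfig(metabolites = "glucose",
                                       concentrationsUm = 100))
  expect_equal(nrow(designTable(d2)), 2L)

  d0 <- generateDesign(syntheticConfig(nMetabolites = 0))
  expect_equal(conditionIds(d0), "control")
})

test_that("duplicate metabolites and unknown supplements are rejected", {
  expect_error(syntheticConfig(metabolites = c("glucose", "glucose")),
               "duplicate")
  expect_error(syntheticConfig(metabolites = "unobtainium"), "unknown")
  expect_error(syntheticConfig(concentrationsUm = c(100, 100)), "duplicate")
})

test_that("generation is bit-identical under an identical config", {
  cfg <- syntheticConfig(nMetabolites = 3, nIons = 50, seed = 42)
  a <- generateScreen(cfg)
  b <- generateScreen(cfg)
  expect_identical(a$growth, b$growth)
  expect_identical(intensities(a$features), intensities(b$features))
  c2 <- generateScreen(syntheticConfig(nMetabolites = 3, nIons = 50,
                                       seed = 43))
  expect_false(identical(intensities(a$features), intensities(c2$features)))
})

test_that("noiseless growth curves follow the logistic closed form", {
  cfg <- syntheticConfig(metabolites = c("glucose", "lysine", "valine"),
                         concentrationsUm = 5000, noiseCv = 0,
                         growthRate = 2)
  design <- generateDesign(cfg)
  truth <- GroundTruth(growth = data.frame(
    condition_id = conditionIds(design),
    growth_class = c("enhanced", "complete_inhibition", "none", "none"),
    od_multiplier = c(1.5, 0, 1, 1), stringsAsFactors = FALSE))
  g <- generateGrowthCurves(design, truth, cfg)
  expect_equal(unique(g$od750[g$day == 0]), 0.01)
  expect_equal(g$od750[g$condition_id == "lysine_5000uM" & g$day == 10],
               rep(0.01, 3))
  ## saturated logistic: OD(10) ratio equals the capacity multiplier
  r <- mean(g$od750[g$condition_id == "glucose_5000uM" & g$day == 10]) /
    mean(g$od750[g$condition_id == "control" & g$day == 10])
  expect_equal(r, 1.5, tolerance = 1e-6)
})

test_that("feature matrix encodes drawdown and exudation exactly at zero noise", {
  cfg <- syntheticConfig(metabolites = c("glucose", "valine"),
                         concentrationsUm = 100, nIons = 4,
                         extraMetabolites = data.frame(
                           metabolite_id = "x01",
                           monoisotopic_mass_da = 300.1234),
                         noiseCv = 0)
  design <- generateDesign(cfg)
  truth <- GroundTruth(
    growth = data.frame(condition_id = conditionIds(design),
                        growth_class = "none", od_multiplier = 1,
                        stringsAsFactors = FALSE),
    drawdown = data.frame(condition_id = "glucose_100uM",
                          metabolite_id = "glucose", fraction = 0.6,
                          stringsAsFactors = FALSE),
    exudation = data.frame(condition_id = "valine_100uM",
                           metabolite_id = "x01", fold = 10,
                           stringsAsFactors = FALSE))
  fm <- generateFeatureMatrix(design, truth, configMassTable(cfg), cfg)
  X <- intensities(fm)
  cd <- SummarizedExperiment::colData(fm)
  rd <- SummarizedExperiment::rowData(fm)
  expect_true(all(X > 0))
  gIon <- rd$ion_id[which.min(abs(rd$mz - (180.063388 - 1.007276)))]
  xIon <- rd$ion_id[which.min(abs(rd$mz - (300.1234 - 1.007276)))]
  ref <- X[gIon, cd$sample_class == "supplemented_reference" &
             cd$condition_id == "glucose_100uM"]
  sup <- X[gIon, cd$sample_class == "supernatant_day10" &
             cd$condition_id == "glucose_100uM"]
  expect_equal(unique(ref), 100 * 200)         # 200 x concentration
  expect_equal(unique(sup), unique(ref) * 0.4) # 60% drawdown
  ## valine condition: glucose ion stays at baseline
  bg <- X[, cd$sample_class == "background_medium"][, 1]
  expect_equal(unique(X[gIon, cd$sample_class == "supernatant_day10" &
                          cd$condition_id == "valine_100uM"]),
               unname(bg[gIon]))
  ## exudation: fold 10 over background, only in the planted condition
  expect_equal(unique(X[xIon, cd$sample_class == "supernatant_day10" &
                          cd$condition_id == "valine_100uM"]),
               unname(bg[xIon]) * 10)
  expect_equal(unique(X[xIon, cd$sample_class == "supernatant_day10" &
                          cd$condition_id == "glucose_100uM"]),
               unname(bg[xIon]))
})

test_that("zero drawdown leaves the supplement at reference intensity", {
  cfg <- tinyConfig(noiseCv = 0)
  design <- generateDesign(cfg)
  truth <- GroundTruth(growth = data.frame(
    condition_id = conditionIds(design), growth_class = "none",
    od_multiplier = 1, stringsAsFactors = FALSE))
  fm <- generateFeatureMatrix(design, truth, configMassTable(cfg), cfg)
  cd <- SummarizedExperiment::colData(fm)
  X <- intensities(fm)
  expect_equal(
    unique(X[1, cd$sample_class == "supernatant_day10" &
               cd$condition_id == "glucose_100uM"]),
    unique(X[1, cd$sample_class == "supplemented_reference"]))
})

test_that("planting an exudate missing from the mass table is an error", {
  cfg <- tinyConfig()
  design <- generateDesign(cfg)
  truth <- GroundTruth(
    growth = data.frame(condition_id = conditionIds(design),
                        growth_class = "none", od_multiplier = 1,
                        stringsAsFactors = FALSE),
    exudation = data.frame(condition_id = "glucose_100uM",
                           metabolite_id = "ghost", fold = 5,
                           stringsAsFactors = FALSE))
  expect_error(generateFeatureMatrix(design, truth, configMassTable(cfg),
                                     cfg),
               "missing from mass table")
})

test_that("empirical replicate CV converges to the configured noise CV", {
  cfg <- syntheticConfig(metabolites = "glucose", concentrationsUm = 100,
                         nIons = 10, extraMetabolites = NULL,
                         nBackgroundSamples = 1000L, noiseCv = 0.2,
                         seed = 11)
  design <- generateDesign(cfg)
  truth <- GroundTruth(growth = data.frame(
    condition_id = conditionIds(design), growth_class = "none",
    od_multiplier = 1, stringsAsFactors = FALSE))
  fm <- generateFeatureMatrix(design, truth, configMassTable(cfg), cfg)
  cd <- SummarizedExperiment::colData(fm)
  bg <- intensities(fm)[, cd$sample_class == "background_medium"]
  cv <- apply(bg, 1, sd) / rowMeans(bg)
  expect_true(all(abs(cv - 0.2) / 0.2 < 0.10))
})

test_that("planted truth is recoverable from noiseless output", {
  cfg <- syntheticConfig(nMetabolites = 6, nIons = 45, noiseCv = 0,
                         seed = 3)
  scr <- generateScreen(cfg)
  tg <- trueGrowth(scr$truth)
  ## growth classes by direct inspection of final OD
  fin <- scr$growth[scr$growth$day == 10, ]
  finMean <- tapply(fin$od750, fin$condition_id, mean)
  ctrl <- finMean[["control"]]
  for (i in seq_len(nrow(tg))) {
    cls <- tg$growth_class[i]
    v <- finMean[[tg$condition_id[i]]]
    if (cls == "complete_inhibition") expect_equal(v, 0.01)
    if (cls == "enhanced") expect_gt(v, ctrl)
    if (cls == "inhibited") expect_lt(v, ctrl)
    if (cls == "none") expect_equal(v, ctrl)
  }
  ## drawdown fractions by direct inspection of the supplement ion
  cd <- SummarizedExperiment::colData(scr$features)
  X <- intensities(scr$features)
  rd <- SummarizedExperiment::rowData(scr$features)
  dd <- trueDrawdown(scr$truth)
  d <- designTable(scr$design)
  for (i in seq_len(nrow(dd))) {
    m <- dd$metabolite_id[i]
    mass <- scr$masses$monoisotopic_mass_da[scr$masses$metabolite_id == m]
    ion <- rd$ion_id[which.min(abs(rd$mz - (mass - 1.007276)))]
    cidx <- dd$condition_id[i]
    sup <- mean(X[ion, cd$sample_class == "supernatant_day10" &
                    cd$condition_id == cidx])
    ref <- mean(X[ion, cd$sample_class == "supplemented_reference" &
                    cd$condition_id == cidx])
    expect_equal(1 - sup / ref, dd$fraction[i], tolerance = 1e-12)
  }
})
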