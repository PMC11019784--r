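## Synthetic screen generator: designs, OD750 growth curves and LC-MS
## feature matrices with planted, recoverable ground truth.

#' Configuration of the synthetic screen generator
#'
#' Collects every knob of the generator. Defaults reproduce the default
#' screen design: 32 supplements at 100 uM and 5 mM plus an unsupplemented
#' control, three biological replicates, 925 detected ions, three
#' uninoculated background-medium samples, and 5% multiplicative
#' measurement noise.
#'
#' @param nMetabolites Number of supplements, taken in order from
#'   [supplementPanel()] (0..32). Ignored when `metabolites` is given.
#' @param metabolites Optional character vector of supplement ids
#'   (subset of the panel) overriding `nMetabolites`.
#' @param concentrationsUm Supplement concentrations in micromolar
#'   (default `c(100, 5000)`).
#' @param nReplicates Biological replicates per condition (default 3).
#' @param nIons Total ions in the feature matrix, annotatable plus noise
#'   ions (default 925). Must be at least the number of distinct measurable
#'   masses in the mass table.
#' @param nBackgroundSamples Uninoculated background-medium samples
#'   (default 3; at least 2 so the background SD is defined).
#' @param noiseCv Coefficient of variation of the multiplicative log-normal
#'   intensity noise, also used as the relative SD of additive OD noise.
#'   `0` is the exact noiseless limit (useful for closure tests).
#' @param growthRate Shared logistic growth rate per day (default 1.0);
#'   carrying capacities differ per condition via the planted multiplier.
#' @param extraMetabolites `data.frame(metabolite_id,
#'   monoisotopic_mass_da)` of non-supplement metabolites available for
#'   planting exudation; default [exudatePool()]. `NULL` for none.
#' @param seed Master integer seed; per-stage streams are derived from it.
#' @return A list of class `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig()
#' design <- generateDesign(cfg)
#' design
#' @export
syntheticConfig <- function(nMetabolites = 32L,
                            metabolites = NULL,
                            concentrationsUm = c(100, 5000),
                            nReplicates = 3L,
                            nIons = 925L,
                            nBackgroundSamples = 3L,
                            noiseCv = 0.05,
                            growthRate = 1.0,
                            extraMetabolites = exudatePool(),
                            seed = 1L) {
  panel <- supplementPanel()
  if (is.null(metabolites)) {
    nMetabolites <- assertCount(nMetabolites, "nMetabolites", min = 0L)
    if (nMetabolites > nrow(panel))
      stop("nMetabolites exceeds the supplement panel size (",
           nrow(panel), ")", call. = FALSE)
    metabolites <- panel$metabolite_id[seq_len(nMetabolites)]
  }
  if (anyDuplicated(metabolites))
    stop("duplicate metabolite names in config", call. = FALSE)
  if (!all(metabolites %in% panel$metabolite_id))
    stop("unknown supplement(s): ",
         paste(setdiff(metabolites, panel$metabolite_id), collapse = ", "),
         call. = FALSE)
  if (any(concentrationsUm <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (anyDuplicated(concentrationsUm))
    stop("duplicate concentrations in config", call. = FALSE)
  if (length(noiseCv) != 1L || is.na(noiseCv) || noiseCv < 0)
    stop("noiseCv must be a single nonnegative number", call. = FALSE)
  cfg <- list(
    metabolites = as.character(metabolites),
    concentrationsUm = as.numeric(concentrationsUm),
    nReplicates = assertCount(nReplicates, "nReplicates"),
    nIons = assertCount(nIons, "nIons"),
    nBackgroundSamples = assertCount(nBackgroundSamples,
                                     "nBackgroundSamples", min = 2L),
    noiseCv = as.numeric(noiseCv),
    growthRate = as.numeric(growthRate),
    extraMetabolites = extraMetabolites,
    seed = assertCount(seed, "seed", min = 0L))
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticConfig: %d supplements x {%s} uM + control, %d replicates, %d ions, noise CV %.3g, seed %d\n",
    length(x$metabolites), paste(x$concentrationsUm, collapse = ", "),
    x$nReplicates, x$nIons, x$noiseCv, x$seed))
  invisible(x)
}

#' Mass table implied by a generator configuration
#'
#' Union of the configured supplements' masses and the extra (exudate-pool)
#' metabolites.
#'
#' @param config A [syntheticConfig()] object.
#' @return `data.frame(metabolite_id, monoisotopic_mass_da)`.
#' @export
configMassTable <- function(config) {
  panel <- supplementPanel()
  mt <- panel[panel$metabolite_id %in% config$metabolites,
              c("metabolite_id", "monoisotopic_mass_da")]
  if (!is.null(config$extraMetabolites))
    mt <- rbind(mt, config$extraMetabolites[
      !config$extraMetabolites$metabolite_id %in% mt$metabolite_id, ])
  rownames(mt) <- NULL
  mt
}

#' Enumerate the experimental design
#'
#' One condition per (supplement, concentration) pair plus exactly one
#' unsupplemented control; with the default 32 supplements at two
#' concentrations this yields 65 conditions (64 supplemented). Deterministic
#' given the configuration.
#'
#' @param config A [syntheticConfig()] object.
#' @return An [ExperimentDesign-class].
#' @examples
#' nrow(designTable(generateDesign(syntheticConfig())))  # 65
#' @export
generateDesign <- function(config) {
  stopifnot(is(config, "SyntheticConfig") || is.list(config))
  panel <- supplementPanel()
  mets <- config$metabolites
  grid <- expand.grid(metabolite_id = mets,
                      concentration_uM = config$concentrationsUm,
                      stringsAsFactors = FALSE)
  ## order: metabolite-major, then concentration, stable across platforms
  grid <- grid[order(match(grid$metabolite_id, mets), grid$concentration_uM), ]
  d <- data.frame(
    condition_id = c(sprintf("%s_%guM", grid$metabolite_id,
                             grid$concentration_uM), "control"),
    metabolite_id = c(grid$metabolite_id, NA_character_),
    concentration_uM = c(grid$concentration_uM, NA_real_),
    n_replicates = config$nReplicates,
    stringsAsFactors = FALSE)
  d$unmeasurable <- !is.na(d$metabolite_id) &
    d$metabolite_id %in% panel$metabolite_id[panel$unmeasurable]
  ExperimentDesign(d)
}

## ---------------------------------------------------------------------------
## Default planted truth: emulates the study-scale screen outcome structure.

#' Default planted ground truth for the full screen
#'
#' Plants a study-scale outcome structure on a design: seven
#' growth-enhancing conditions (all at 5 mM, final-OD multipliers 1.20-1.53
#' with glucose highest), 15 completely growth-inhibiting conditions (12 at
#' 5 mM), 21 partially inhibiting conditions, drawdown of 15 of the 27
#' measurable supplements, a ubiquitous oxidative-stress exudate
#' (hydroxy-formylkynurenine, planted in 44 of the 50 growing conditions),
#' a set of frequently produced glutathione-related exudates,
#' condition-specific five-metabolite exudation signatures for glucose and
#' valine at 5 mM, and seeded random filler exudation in every growing
#' condition. Conditions absent from `design` are silently skipped, so the
#' same function serves reduced designs.
#'
#' @param design An [ExperimentDesign-class].
#' @param seed Integer seed for the random filler exudation (default 1).
#' @param fillerExudates Number of filler-pool metabolites exuded per
#'   growing condition (default 8).
#' @param masses Optional mass table; when given, planted exudation is
#'   restricted to metabolites present in it (so reduced screens whose
#'   mass table lacks some named exudates stay consistent).
#' @return A [GroundTruth-class].
#' @export
defaultGroundTruth <- function(design, seed = 1L, fillerExudates = 8L,
                               masses = NULL) {
  d <- designTable(design)
  cond <- function(met, conc) {
    id <- d$condition_id[!is.na(d$metabolite_id) & d$metabolite_id %in% met &
                           d$concentration_uM == conc]
    id
  }
  enhanced <- c(glucose = 1.53, proline = 1.43, acetate = 1.35,
                taurine = 1.30, asparagine = 1.25, gluconate = 1.22,
                glycine = 1.20)
  complete5 <- c("citrate", "fructose", "glutamine", "glutarate",
                 "glutamate", "succinate", "malate", "methionine",
                 "propionate", "threonine", "lysine", "trimethylamine")
  complete01 <- c("lysine", "propionate", "threonine")
  partial5 <- c(valine = 0.50, histidine = 0.60, phenylalanine = 0.60,
                serine = 0.70, alanine = 0.70, arginine = 0.75,
                leucine = 0.65, sucrose = 0.80, lactate = 0.75,
                glycerol = 0.80, urea = 0.70, methanol = 0.80,
                ammonia = 0.60)
  partial01 <- c(citrate = 0.80, glutamate = 0.80, glutamine = 0.80,
                 methionine = 0.75, succinate = 0.80, malate = 0.80,
                 histidine = 0.80, leucine = 0.80)

  growth <- data.frame(condition_id = d$condition_id,
                       growth_class = "none", od_multiplier = 1.0,
                       stringsAsFactors = FALSE)
  setClassTo <- function(ids, cls, mult) {
    i <- match(ids, growth$condition_id)
    i <- i[!is.na(i)]
    growth$growth_class[i] <<- cls
    growth$od_multiplier[i] <<- mult
  }
  for (m in names(enhanced))
    setClassTo(cond(m, 5000), "enhanced", enhanced[[m]])
  setClassTo(cond(complete5, 5000), "complete_inhibition", 0)
  setClassTo(cond(complete01, 100), "complete_inhibition", 0)
  for (m in names(partial5))
    setClassTo(cond(m, 5000), "inhibited", partial5[[m]])
  for (m in names(partial01))
    setClassTo(cond(m, 100), "inhibited", partial01[[m]])

  ## drawdown: the 15 consumed supplements; never in complete-inhibition
  ## conditions (no cells, no uptake)
  consumed <- c("glucose", "sucrose", "gluconate", "malate", "citrate",
                "arginine", "asparagine", "glutamate", "glutamine",
                "glycine", "leucine", "methionine", "proline", "serine",
                "valine")
  dd <- list()
  for (m in consumed) {
    for (conc in c(100, 5000)) {
      id <- cond(m, conc)
      if (!length(id)) next
      cls <- growth$growth_class[match(id, growth$condition_id)]
      if (cls == "complete_inhibition") next
      if (m == "proline" && conc == 5000) next  # consumed at 100 uM only
      frac <- if (m == "glucose") ifelse(conc == 100, 0.9, 0.6)
              else ifelse(conc == 100, 0.6, 0.3)
      dd[[length(dd) + 1L]] <- data.frame(condition_id = id,
                                          metabolite_id = m,
                                          fraction = frac,
                                          stringsAsFactors = FALSE)
    }
  }
  drawdown <- if (length(dd)) do.call(rbind, dd) else
    data.frame(condition_id = character(), metabolite_id = character(),
               fraction = numeric())

  ## exudation
  growing <- growth$condition_id[growth$growth_class != "complete_inhibition"]
  ex <- list()
  addEx <- function(ids, met, fold) {
    ids <- intersect(ids, growing)
    if (!length(ids)) return(invisible())
    ex[[length(ex) + 1L]] <<- data.frame(condition_id = ids,
                                         metabolite_id = met, fold = fold,
                                         stringsAsFactors = FALSE)
  }
  skip6 <- c(cond("ammonia", 100), cond("methanol", 100), cond("urea", 100),
             cond("methanol", 5000), cond("urea", 5000),
             cond("glycerol", 100))
  addEx(setdiff(growing, skip6), "hydroxy_formylkynurenine", 20)
  freq <- list(glutathione = 35, dihydroneopterin = 32,
               formylglutathione = 30, lactoylglutathione = 28,
               beta_cyanoalanine = 26)
  for (m in names(freq))
    addEx(growing[seq_len(min(freq[[m]], length(growing)))], m, 12)
  ## condition-specific signatures (5 mM glucose and valine)
  for (m in c("gluconate", "methyltetrahydrofolate_5", "formylglutathione",
              "phosphoglycolate_2", "itaconate"))
    addEx(cond("glucose", 5000), m, 60)
  for (m in c("isopropylmalate", "ketovaline", "hydroxyglutarate",
              "isoleucine", "glutarate"))
    addEx(cond("valine", 5000), m, 60)
  ## seeded filler exudation for inter-condition variability
  pool <- exudatePool()
  filler <- pool$metabolite_id[grepl("^x\\d+$", pool$metabolite_id)]
  if (fillerExudates > 0L && length(filler)) {
    set.seed(stageSeed(seed, "truth_filler"))
    for (id in growing)
      addEx(id, sample(filler, min(fillerExudates, length(filler))),
            fold = round(runif(min(fillerExudates, length(filler)), 3, 8), 2))
  }
  exudation <- if (length(ex)) do.call(rbind, ex) else
    data.frame(condition_id = character(), metabolite_id = character(),
               fold = numeric())
  if (!is.null(masses))
    exudation <- exudation[exudation$metabolite_id %in%
                             masses$metabolite_id, , drop = FALSE]
  ## collapse duplicate (condition, metabolite) plantings to the max fold
  if (nrow(exudation)) {
    key <- paste(exudation$condition_id, exudation$metabolite_id)
    exudation <- do.call(rbind, lapply(split(exudation, key), function(g)
      g[which.max(g$fold), ]))
    rownames(exudation) <- NULL
  }
  GroundTruth(growth = growth, drawdown = drawdown, exudation = exudation)
}

## ---------------------------------------------------------------------------
## Growth curves

#' Simulate OD750 growth curves
#'
#' Logistic growth sampled daily over days 0..10, inoculated at OD750 0.01,
#' with a shared rate and a per-condition carrying capacity equal to the
#' planted multiplier (control capacity 1.0). Complete-inhibition
#' conditions stay flat at the inoculum. Additive Gaussian noise with SD
#' `noiseCv * OD`, truncated below at a small positive floor.
#'
#' @param design An [ExperimentDesign-class].
#' @param truth A [GroundTruth-class] covering every design condition.
#' @param config A [syntheticConfig()] object.
#' @return Long `data.frame(condition_id, replicate, day, od750)`.
#' @export
generateGrowthCurves <- function(design, truth, config) {
  d <- designTable(design)
  g <- trueGrowth(truth)
  if (!all(d$condition_id %in% g$condition_id))
    stop("ground truth missing conditions: ",
         paste(setdiff(d$condition_id, g$condition_id), collapse = ", "),
         call. = FALSE)
  days <- 0:10
  od0 <- 0.01
  r <- config$growthRate
  set.seed(stageSeed(config$seed, "growth"))
  out <- list()
  for (i in seq_len(nrow(d))) {
    id <- d$condition_id[i]
    gi <- g[match(id, g$condition_id), ]
    K <- if (gi$growth_class == "complete_inhibition") NA_real_ else
      gi$od_multiplier
    mu <- if (is.na(K)) rep(od0, length(days)) else
      K * od0 * exp(r * days) / (K + od0 * (exp(r * days) - 1))
    for (rep_ in seq_len(d$n_replicates[i])) {
      od <- mu + rnorm(length(days), 0, config$noiseCv * mu)
      od <- pmax(od, 1e-4)
      out[[length(out) + 1L]] <- data.frame(
        condition_id = id, replicate = rep_, day = days, od750 = od,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---------------------------------------------------------------------------
## Feature matrix

#' Simulate the processed LC-MS feature matrix
#'
#' Emulates the processed negative-mode LC-QTOF-MS output of the screen.
#' Each distinct measurable metabolite mass yields one ion at the [M-H]-
#' m/z (isobaric metabolites share an ion, as they would co-elute into one
#' aligned feature); the remaining ions up to `nIons` are unannotatable
#' noise ions at random m/z kept at least 30 ppm away from every known
#' mass. Background-medium samples carry each ion's baseline. Supplemented
#' reference samples carry the supplement ion at `200 x concentration (uM)`.
#' Day-10 supernatants reflect planted drawdown (supplement ion at
#' `reference x (1 - fraction)`, floored at baseline) and planted exudation
#' (metabolite ion at `baseline x fold`). Multiplicative log-normal noise
#' with CV `noiseCv` is applied to every cell. Metabolites flagged
#' unmeasurable produce no ions. Complete-inhibition conditions receive
#' neither drawdown nor exudation.
#'
#' @param design An [ExperimentDesign-class].
#' @param truth A [GroundTruth-class].
#' @param masses `data.frame(metabolite_id, monoisotopic_mass_da)`; every
#'   planted exuded metabolite must appear in it.
#' @param config A [syntheticConfig()] object.
#' @return A [FeatureMatrix-class].
#' @export
generateFeatureMatrix <- function(design, truth, masses, config) {
  if (!nrow(masses)) stop("mass table is empty", call. = FALSE)
  d <- designTable(design)
  panel <- supplementPanel()
  unmeasurable <- panel$metabolite_id[panel$unmeasurable]
  ex <- trueExudation(truth)
  missing <- setdiff(ex$metabolite_id, masses$metabolite_id)
  if (length(missing))
    stop("planted exuded metabolite(s) missing from mass table: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)

  measurable <- masses[!masses$metabolite_id %in% unmeasurable, ]
  ## one ion per distinct mass; isobars (within 5 ppm) share the ion
  ord <- order(measurable$monoisotopic_mass_da, measurable$metabolite_id)
  measurable <- measurable[ord, ]
  grp <- cumsum(c(TRUE, diff(measurable$monoisotopic_mass_da) /
                    measurable$monoisotopic_mass_da[-1] > 5e-6))
  ionMass <- tapply(measurable$monoisotopic_mass_da, grp, function(x) x[1])
  nAnn <- length(ionMass)
  if (config$nIons < nAnn)
    stop(sprintf("nIons (%d) smaller than the %d distinct measurable masses",
                 config$nIons, nAnn), call. = FALSE)
  metIon <- structure(as.integer(grp), names = measurable$metabolite_id)

  set.seed(stageSeed(config$seed, "features"))
  ## noise-ion m/z: uniform in the acquisition range, >= 30 ppm from any
  ## known [M-H]- m/z
  annMz <- as.numeric(ionMass) - PROTON_MASS_DA
  nNoise <- config$nIons - nAnn
  noiseMz <- numeric(0)
  while (length(noiseMz) < nNoise) {
    cand <- runif(nNoise - length(noiseMz) + 10L, 50, 1700)
    ok <- vapply(cand, function(z)
      min(abs(z - annMz) / z) > 30e-6, logical(1))
    noiseMz <- c(noiseMz, cand[ok])
  }
  noiseMz <- noiseMz[seq_len(nNoise)]
  mz <- c(annMz, noiseMz)
  ions <- data.frame(ion_id = sprintf("ion%04d", seq_along(mz)),
                     mz = mz, polarity = "negative",
                     stringsAsFactors = FALSE)

  ## baseline background intensity per ion (log-uniform 10^2.5 .. 10^4).
  ## Ions of measurable supplements get a low baseline (10^2.5 .. 10^3):
  ## the uninoculated medium does not contain the supplement, so only
  ## instrument/medium background is seen there, well below the
  ## supplemented-reference level even after strong drawdown.
  baseline <- 10^runif(config$nIons, 2.5, 4)
  supIons <- unique(metIon[intersect(names(metIon), d$metabolite_id)])
  baseline[supIons] <- 10^runif(length(supIons), 2.5, 3)

  ## sample sheet: supernatants, background, references
  sup <- d[rep(seq_len(nrow(d)), d$n_replicates), ]
  supRep <- unlist(lapply(d$n_replicates, seq_len))
  samples <- data.frame(
    sample_id = sprintf("sup_%s_r%d", sup$condition_id, supRep),
    condition_id = sup$condition_id, replicate = supRep,
    sample_class = "supernatant_day10", stringsAsFactors = FALSE)
  samples <- rbind(samples, data.frame(
    sample_id = sprintf("bg_r%d", seq_len(config$nBackgroundSamples)),
    condition_id = NA_character_,
    replicate = seq_len(config$nBackgroundSamples),
    sample_class = "background_medium", stringsAsFactors = FALSE))
  supd <- d[!is.na(d$metabolite_id), ]
  refRep <- unlist(lapply(supd$n_replicates, seq_len))
  refCond <- supd[rep(seq_len(nrow(supd)), supd$n_replicates), ]
  samples <- rbind(samples, data.frame(
    sample_id = sprintf("ref_%s_r%d", refCond$condition_id, refRep),
    condition_id = refCond$condition_id, replicate = refRep,
    sample_class = "supplemented_reference", stringsAsFactors = FALSE))

  X <- matrix(baseline, nrow = config$nIons, ncol = nrow(samples))
  gmap <- trueGrowth(truth)
  refIntensity <- function(conc) 200 * conc
  for (j in seq_len(nrow(samples))) {
    cid <- samples$condition_id[j]
    if (is.na(cid)) next
    di <- d[match(cid, d$condition_id), ]
    cls <- gmap$growth_class[match(cid, gmap$condition_id)]
    if (samples$sample_class[j] == "supplemented_reference") {
      if (!di$unmeasurable && di$metabolite_id %in% names(metIon))
        X[metIon[[di$metabolite_id]], j] <- refIntensity(di$concentration_uM)
      next
    }
    ## supernatant_day10
    if (!is.na(di$metabolite_id) && !di$unmeasurable &&
        di$metabolite_id %in% names(metIon)) {
      frac <- 0
      if (!is.na(cls) && cls != "complete_inhibition") {
        dd <- trueDrawdown(truth)
        hit <- dd$condition_id == cid & dd$metabolite_id == di$metabolite_id
        if (any(hit)) frac <- dd$fraction[hit][1]
      }
      X[metIon[[di$metabolite_id]], j] <-
        max(refIntensity(di$concentration_uM) * (1 - frac),
            baseline[metIon[[di$metabolite_id]]])
    }
    if (!is.na(cls) && cls != "complete_inhibition") {
      hits <- ex[ex$condition_id == cid, ]
      for (k in seq_len(nrow(hits))) {
        m <- hits$metabolite_id[k]
        if (m %in% names(metIon)) {
          i <- metIon[[m]]
          X[i, j] <- max(X[i, j], baseline[i] * hits$fold[k])
        }
      }
    }
  }
  X <- X * matrix(lognormalNoise(length(X), config$noiseCv), nrow = nrow(X))
  FeatureMatrix(X, ions, samples)
}

#' Generate a complete synthetic screen
#'
#' Convenience wrapper producing every artifact of one synthetic screen:
#' design, ground truth, growth curves, feature matrix, mass table and
#' pathway membership. Fully deterministic given the configuration.
#'
#' @param config A [syntheticConfig()] object.
#' @param truth Optional [GroundTruth-class]; default
#'   `defaultGroundTruth(design, seed = config$seed)`.
#' @return A list with elements `config`, `design`, `truth`, `growth`
#'   (long curve table), `features` ([FeatureMatrix-class]), `masses`,
#'   `pathways`.
#' @examples
#' scr <- generateScreen(syntheticConfig(nMetabolites = 2, nIons = 40,
#'                                       extraMetabolites = NULL))
#' scr$features
#' @export
generateScreen <- function(config, truth = NULL) {
  design <- generateDesign(config)
  masses <- configMassTable(config)
  if (is.null(truth))
    truth <- defaultGroundTruth(design, seed = config$seed,
                                masses = masses)
  list(config = config,
       design = design,
       truth = truth,
       growth = generateGrowthCurves(design, truth, config),
       features = generateFeatureMatrix(design, truth, masses, config),
       masses = masses,
       pathways = defaultPathwayDB())
}
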