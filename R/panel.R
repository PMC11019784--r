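## Built-in metabolite panel and pathway membership used by the synthetic
## screen generator. Monoisotopic neutral masses are sums of IUPAC atomic
## monoisotopic masses for the compound's molecular formula.

#' Supplement panel of the screen
#'
#' The 32 supplemented metabolites of the default screen design: sugars,
#' organic acids, amino acids, C1 compounds and two polyols, each supplied at
#' two concentrations alongside an unsupplemented control. Five compounds
#' (urea, trimethylamine, methanol, ammonia, acetate) are flagged
#' `unmeasurable`: they fall outside the coverage of the negative-mode LC-MS
#' method (too small, poorly ionizing, or below the acquisition mass range)
#' and are excluded from consumption analysis.
#'
#' @return A `data.frame` with columns `metabolite_id`, `class`,
#'   `monoisotopic_mass_da` (neutral monoisotopic mass in Daltons) and
#'   `unmeasurable` (logical).
#' @examples
#' p <- supplementPanel()
#' nrow(p)            # 32 supplements
#' sum(!p$unmeasurable) # 27 measurable by LC-MS
#' @export
supplementPanel <- function() {
  p <- data.frame(
    metabolite_id = c(
      "glucose", "fructose", "sucrose",
      "gluconate", "malate", "citrate", "succinate", "glutarate",
      "propionate", "acetate", "lactate",
      "glycerol", "taurine",
      "urea", "methanol", "ammonia", "trimethylamine",
      "alanine", "arginine", "asparagine", "glutamate", "glutamine",
      "glycine", "histidine", "leucine", "lysine", "methionine",
      "phenylalanine", "proline", "serine", "threonine", "valine"),
    class = c(
      rep("sugar", 3), rep("organic_acid", 8), rep("other", 2),
      rep("C1_compound", 4), rep("amino_acid", 15)),
    monoisotopic_mass_da = c(
      180.063388, 180.063388, 342.116212,
      196.058303, 134.021523, 192.027003, 118.026609, 132.042259,
      74.036779, 60.021129, 90.031694,
      92.047344, 125.014664,
      60.032363, 32.026215, 17.026549, 59.073499,
      89.047678, 174.111676, 132.053492, 147.053158, 146.069142,
      75.032028, 155.069477, 131.094629, 146.105528, 149.051050,
      165.078979, 115.063329, 105.042593, 119.058243, 117.078979),
    stringsAsFactors = FALSE)
  p$unmeasurable <- p$metabolite_id %in%
    c("urea", "trimethylamine", "methanol", "ammonia", "acetate")
  p
}

#' Exudate pool of the synthetic screen
#'
#' Metabolites the synthetic generator can plant as exuded compounds:
#' thirteen named exudates typical of cyanobacterial supernatants (oxidative
#' stress markers, glutathione conjugates, branched-chain amino-acid
#' pathway intermediates, folates) plus twenty-four synthetic filler
#' metabolites (`x01`..`x24`) with arbitrary collision-free masses.
#' Isoleucine is deliberately isobaric with the supplemented leucine so the
#' annotation stage exercises isobar collapsing.
#'
#' @return A `data.frame` with columns `metabolite_id` and
#'   `monoisotopic_mass_da`.
#' @export
exudatePool <- function() {
  named <- data.frame(
    metabolite_id = c(
      "hydroxy_formylkynurenine", "dihydroneopterin", "glutathione",
      "formylglutathione", "lactoylglutathione", "beta_cyanoalanine",
      "methyltetrahydrofolate_5", "phosphoglycolate_2", "itaconate",
      "isopropylmalate", "ketovaline", "hydroxyglutarate", "isoleucine"),
    monoisotopic_mass_da = c(
      252.074621, 255.096754, 307.083806,
      335.078721, 379.104936, 114.042927,
      459.186632, 155.982375, 130.026609,
      176.068473, 116.047344, 148.037173, 131.094629),
    stringsAsFactors = FALSE)
  i <- 1:24
  filler <- data.frame(
    metabolite_id = sprintf("x%02d", i),
    ## deterministic, >50 ppm away from every named mass
    monoisotopic_mass_da = 200.1234 + 11.777 * i + 0.391 * (i * i %% 7),
    stringsAsFactors = FALSE)
  rbind(named, filler)
}

#' Default metabolite mass table
#'
#' The union of the supplement panel and the exudate pool: every metabolite
#' the synthetic generator can place in a sample, with its neutral
#' monoisotopic mass. This is the table the annotation stage matches ion
#' masses against.
#'
#' @return A `data.frame` with columns `metabolite_id` and
#'   `monoisotopic_mass_da`, one unique id per row.
#' @export
defaultMassTable <- function() {
  p <- supplementPanel()
  rbind(p[, c("metabolite_id", "monoisotopic_mass_da")], exudatePool())
}

#' Default pathway membership table
#'
#' A synthetic, BioCyc-style many-to-many metabolite-to-pathway membership
#' table covering the default mass table: central carbon and TCA-related
#' pathways, glutathione and folate metabolism, branched-chain amino-acid
#' metabolism, photorespiration, and four generic pools holding the filler
#' metabolites. It emulates the structure of a curated pathway database for
#' scoring; it is not a curated reconstruction.
#'
#' @return A `data.frame` with columns `metabolite_id` and `pathway_id`.
#' @export
defaultPathwayDB <- function() {
  memb <- list(
    tca_cycle = c("citrate", "succinate", "malate", "glutamate",
                  "itaconate", "glutarate"),
    glycolysis_oppp = c("glucose", "fructose", "sucrose", "gluconate",
                        "lactate"),
    glutathione_metabolism = c("glutathione", "formylglutathione",
                               "lactoylglutathione", "glycine", "glutamate",
                               "beta_cyanoalanine"),
    folate_biosynthesis = c("dihydroneopterin", "methyltetrahydrofolate_5",
                            "glycine", "serine", "methionine"),
    bcaa_metabolism = c("valine", "leucine", "isoleucine", "ketovaline",
                        "isopropylmalate", "hydroxyglutarate", "glutarate",
                        "threonine"),
    photorespiration = c("phosphoglycolate_2", "glycine", "serine",
                         "glycerol"),
    arginine_proline_metabolism = c("arginine", "glutamate", "glutamine",
                                    "proline", "ornithine"),
    aromatic_aa_metabolism = c("phenylalanine", "histidine",
                               "hydroxy_formylkynurenine"),
    sulfur_metabolism = c("taurine", "methionine", "glutathione"))
  memb$arginine_proline_metabolism <-
    setdiff(memb$arginine_proline_metabolism, "ornithine")
  db <- data.frame(
    metabolite_id = unlist(memb, use.names = FALSE),
    pathway_id = rep(names(memb), lengths(memb)),
    stringsAsFactors = FALSE)
  x <- sprintf("x%02d", 1:24)
  db <- rbind(db, data.frame(
    metabolite_id = x,
    pathway_id = sprintf("pool_p%d", (seq_along(x) - 1L) %% 4L + 1L),
    stringsAsFactors = FALSE))
  rownames(db) <- NULL
  db
}
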