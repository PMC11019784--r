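# ExoScreen

Growth and exometabolome analysis of nutrient-supplementation screens in
cyanobacteria and other phototrophs.

## The problem

A supplementation screen grows a phototroph (e.g. *Synechocystis* sp.
PCC 6803) with each of a panel of metabolites at two concentrations —
by default 32 compounds at 100 µM and 5 mM plus an unsupplemented
control, 65 conditions in triplicate — and profiles each culture by daily
OD₇₅₀ and by untargeted negative-mode LC-MS of the day-10 cell-free
supernatant. ExoScreen turns those two tabular readouts into:

- **Growth effects** — per condition, a two-sided Welch *t* test of
  final-day OD₇₅₀ against the control classifies the effect as
  *enhanced* / *inhibited* (p < α) or *complete_inhibition* (final mean
  OD₇₅₀ below a no-growth threshold), plus the R² of the ln(OD) ~ time
  regression over the exponential window (days 0–4).
- **Mixotrophy calls** — the consumed fraction of each supplement,
  `max(0, 1 − mean(supernatant) / mean(sterile reference))` on its
  [M−H]⁻ ion, called mixotrophic when the reduction is ≥ 10% with
  p < 0.05 at either concentration.
- **Normalized exometabolome** — each annotated metabolite scaled to
  [0, 1] where 0 is background medium and 1 the most concentrated sample,
  after limit-of-detection thresholding (LOD = background mean + 3 SD)
  and masking of each condition's own supplement.
- **Exudate ranks** — metabolites ordered by normalized intensity summed
  over conditions.
- **Pathway scores** — per condition, the fraction of produced
  pathway-mapped metabolites belonging to each pathway.
- **PCA** — condition profiles decomposed by SVD (mean-centered,
  unscaled) with deterministic signs and extreme-loading extraction.

A seeded synthetic-screen generator with planted ground truth (growth
classes, drawdown fractions, exudation signatures) makes the whole
pipeline testable end to end; all inputs and outputs are plain TSV.

## Worked example

```r
library(ExoScreen)

## simulate the default screen: 65 conditions x 3 replicates, 925 ions
scr <- generateScreen(syntheticConfig(seed = 7))
writeScreen(scr, "screen")

res <- runScreen(screenConfig(inputDir = "screen", outDir = "out"))
str(res$summary[c("n_conditions", "n_supplemented", "n_enhanced",
                  "n_complete_inhibition", "n_mixotrophic_metabolites")])
#> List of 5
#>  $ n_conditions             : int 65
#>  $ n_supplemented           : int 64
#>  $ n_enhanced               : int 13
#>  $ n_complete_inhibition    : int 15
#>  $ n_mixotrophic_metabolites: int 15

head(res$ranks, 3)
#>                      label summed_normalized_intensity n_producing_conditions rank
#> 1 hydroxy_formylkynurenine                    39.39477                     49    1
#> 2              glutathione                    30.59060                     47    2
#> 3         dihydroneopterin                    27.43683                     38    3
```

65 conditions (64 supplemented + control) were analyzed; at this seed the
classifier recovers all 7 planted growth enhancers plus 6 false positives
(the control triplicate landed low, and every condition shares it — see the
methods vignette), all 15 planted complete inhibitions, and exactly the 15
planted mixotrophic metabolites. The top-ranked exudates are the planted
oxidative-stress markers, led by hydroxy-formylkynurenine produced in 49
conditions. `out/` holds every stage table (`effects.tsv`,
`consumption.tsv`, `norm.tsv`, `exudate_ranks.tsv`, `pathway_scores.tsv`,
PCA scores/loadings, `summary.json`, run manifest).

The same stages are scriptable per step via
`inst/scripts/exoscreen.R <simulate|validate|growth|annotate|normalize|consumption|rank|pathways|pca|run-all>`.

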