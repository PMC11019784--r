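---
title: "Methods: growth and exometabolome analysis of a supplementation screen"
author: "ExoScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth and exometabolome analysis of a supplementation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ExoScreen)
```

# The experiment this package analyzes

ExoScreen analyzes high-throughput nutrient-supplementation screens of
phototrophs such as *Synechocystis* sp. PCC 6803. In such a screen, a panel
of metabolites (sugars, organic acids, amino acids, C1 compounds) is each
added to the growth medium at a low (100 µM) and a high (5 mM)
concentration, alongside an unsupplemented control; with the default
32-compound panel this yields 65 culture conditions in biological
triplicate. Two readouts are collected per condition: daily OD~750~ as a
biomass proxy (750 nm avoids pigment absorption bands), and a processed
negative-mode LC-MS feature table of the cell-free day-10 supernatant — the
exometabolome — together with uninoculated background-medium samples and
sterile supplemented-medium reference samples.

Three questions drive the analysis. Does a supplement enhance or inhibit
growth? Is the supplement itself consumed (mixotrophy)? And how does
supplementation reshape what the cells exude?

# Growth effects

Per condition, the final-day OD~750~ replicates are compared to the control
with a two-sided Welch (unequal-variance) *t* test; a condition is
*enhanced* or *inhibited* when *p* < α (default 0.05) with the mean above
or below the control, and *completely inhibited* when the final mean
OD~750~ falls below a no-growth threshold regardless of the test. Per-test
p values are uncorrected by default — the readout is a per-condition
screening call, and correcting would change the operating characteristics
users expect from it — but a Benjamini–Hochberg option (`fdr = TRUE`) is
exposed for reuse in settings where family-wise error matters. Because each
test shares the same three control replicates, false calls across
conditions are correlated: when the control happens to land low, several
true-null conditions can cross the threshold together. This is an inherent
property of the design, visible in the synthetic screens as a false-call
rate near (and occasionally above) α.

Exponential-phase quality is summarized by the R² of a linear regression of
ln(OD~750~) on time over days 0–4, endpoints inclusive, using days as
sampled without interpolation. Nonpositive ODs are excluded from the log
fit and flagged; a flat trace has undefined R² and is reported as 0 with a
flag rather than `NA`, so downstream tabulation never mixes types.

Two conventions make the Welch test well defined on noiseless synthetic
data: when both groups have zero variance, equal means give *p* = 1 and
unequal means give *p* = 0 (the difference is exact, not estimated). The
nondegenerate path is verified against `stats::t.test()` in the test suite.

**Defaults.** α = 0.05; final day = 10; exponential window = days 0–4;
no-growth threshold = OD~750~ 0.05, i.e. five times the 0.01 inoculum. The
threshold is our own scale-anchored choice — "no growth" needs an absolute
cutoff, and anchoring it to the inoculation density keeps it meaningful if
all ODs are rescaled.

# Exact-mass annotation

Ions are assumed singly deprotonated ([M−H]⁻; the acquisition is
negative-mode), so the neutral mass is m/z + 1.007276 Da. Each ion is
matched against a metabolite mass table within a ppm tolerance (default
10 ppm, exposed as a flag; no adduct list beyond [M−H]⁻ is modeled).
Isobaric matches are collapsed into one ambiguous label with the member ids
sorted and joined (e.g. `isoleucine;leucine`), which both makes output
order-independent and honestly represents that exact mass cannot separate
such pairs. Unmatched ions are retained as unannotated features. When
several ions carry one label, downstream stages use the ion with the
maximal summed intensity — a simple, deterministic proxy for "the ion that
carries the signal".

# Exometabolome normalization

The normalization maps every annotated metabolite onto a common 0–1 scale
in three ordered steps, applied per metabolite:

1. **Limit of detection.** LOD = mean + 3 SD of the background-medium
   intensities (sample SD, n−1). Supernatant intensities below the LOD are
   reassigned the background mean — they are indistinguishable from medium.
2. **Supplement masking.** In samples of a condition whose own supplement
   matches the metabolite's label, the intensity is reassigned the
   background mean. Without this, every supplemented condition would
   trivially "exude" its own supplement residue.
3. **Scaling.** Values become (I − bg_mean) / (I_max − bg_mean), where
   I_max is the maximum post-masking intensity over individual day-10
   supernatant samples (not condition means — the reference point is the
   single most concentrated sample), clipped to [0, 1]. A metabolite whose
   I_max never exceeds its LOD is never produced and maps to all zeros.

Replicates are averaged per condition *after* scaling; whether the study
averaged before or after is not recoverable from its description, and
scaling first keeps the max well defined at the sample level. Each cell
carries a provenance flag (`measured`, `below_lod_reassigned` when every
replicate fell below the LOD, `supplement_masked`), and masked cells are
exactly 0 by construction. Sterile supplemented-medium reference samples
are excluded from the normalization: they contain no culture, so they are
neither background nor exometabolome.

With only a handful of background samples the LOD is a fragile estimate:
three background replicates can cluster by chance, shrink the estimated SD,
and let baseline noise cross the threshold. The synthetic screens show this
as a few percent of false "produced" calls per metabolite — worth knowing
when interpreting production counts from any screen with few background
injections.

# Consumption and mixotrophy

For each measurable supplemented (metabolite, concentration) pair, the
consumed fraction is max(0, 1 − mean(day-10 supernatant) / mean(sterile
supplemented-medium reference)) on the supplement's representative ion,
with a Welch test between the two replicate sets. A condition is called
mixotrophic when the reduction is at least 10% *and* *p* < 0.05; a
metabolite is mixotrophic overall when either concentration qualifies.

The baseline choice deserves a note: day-0 culture supernatants are not
sampled in this design, so sterile supplemented medium at nominal
concentration is the only available uptake baseline, and it is the default.
Five panel compounds (urea, trimethylamine, methanol, ammonia, acetate)
fall outside the LC-MS method's coverage; they are flagged `unmeasurable`
in the design table and excluded from consumption analysis, leaving 27
eligible metabolites under the default panel.

# Exudate ranking and pathway scores

Metabolites are ranked by their normalized intensity summed over all
conditions (ties broken lexicographically so ranks are deterministic), with
the number of producing conditions (normalized value > 0) reported
alongside.

Pathway importance per condition divides the number of produced metabolites
in a pathway by the number of distinct produced metabolites mapping to at
least one pathway in that condition. The denominator wording is genuinely
ambiguous ("total detected across all pathways" could also mean the
multiplicity-weighted sum of per-pathway counts); we adopt the
distinct-count reading because it keeps scores in [0, 1] and interpretable
as fractions, and expose the multiplicity variant behind
`denominator = "multiplicity"`. "Produced" means normalized value strictly
above `producedMin` (default 0, i.e. anything above LOD after masking).
This is a descriptive representation score, not an enrichment test — no
null model is implied, so no hypergeometric machinery belongs here.

# PCA of condition profiles

Condition profiles (replicate means, one row per condition) are
mean-centered per metabolite without variance scaling — the values already
share the 0–1 scale, and unit-variance scaling would inflate metabolites
that barely vary. The decomposition uses singular values (`prcomp`). Signs
of principal components are arbitrary, so a deterministic convention is
applied: the largest-magnitude loading of each component is made positive,
ties broken by label. Conditions with complete growth inhibition are
excluded before the decomposition — a culture that never grew has no
exometabolome, and its all-zero profile would otherwise form an artifactual
cluster. Extreme-loading extraction returns the k most positive and k most
negative loadings per component (default k = 5), the standard way to read
which metabolites drive a separation.

# The synthetic screen generator

The generator exists so every stage is testable against known truth without
the study's deposited raw spectra. It emulates the *processed* data level:

* **Design**: the 32-supplement panel × {100 µM, 5 mM} + control,
  triplicate, with the five unmeasurable compounds flagged.
* **Growth**: logistic curves sampled daily over days 0–10 from an
  inoculum of OD~750~ 0.01, shared rate (default 1.0 d⁻¹, which makes the
  first four days effectively exponential and saturates by day 10), and a
  per-condition carrying capacity equal to the planted final-OD
  multiplier. Logistic is the simplest shape with both an exponential
  early phase and a plateau; no mechanistic claim is attached. OD noise is
  additive Gaussian with SD = CV × OD. Mid-experiment water
  replenishments of the real protocol are not simulated; their small
  dilution effect is treated as part of the noise.
* **Feature matrix**: one ion per distinct measurable mass at the [M−H]⁻
  m/z (isobars share an ion, as co-eluting isobars would in an aligned
  feature table), plus unannotatable noise ions at random m/z kept ≥30 ppm
  from every known mass, 925 ions in total by default. Background medium
  carries per-ion baselines (log-uniform 10^2.5^–10^4^ intensity units;
  supplement ions get low baselines, 10^2.5^–10^3^, because uninoculated
  medium does not contain the supplement). References carry the supplement
  ion at 200 × concentration (µM), supernatants reflect planted drawdown
  and exudation folds, and every cell receives multiplicative log-normal
  noise with unit mean and the configured CV.
* **Planted truth** (the default `defaultGroundTruth()`): 7 enhancing
  conditions, all at 5 mM, with final-OD multipliers 1.20–1.53; 15
  completely inhibiting conditions (12 at 5 mM); 21 partially inhibiting
  (multipliers 0.5–0.8); drawdown of 15 of the 27 measurable supplements
  (fractions 0.3–0.9, never in complete-inhibition conditions — no cells,
  no uptake); a ubiquitous oxidative-stress exudate planted in 44 of the
  50 growing conditions; frequently produced glutathione-related exudates;
  and five-metabolite exudation signatures exclusive to glucose and valine
  at 5 mM. Filler exudation (8 pool metabolites per growing condition,
  folds 3–8) provides inter-condition variability.

The replicate noise CV has no analogue reported for the original study; the
default of 0.05 is a typical replicate-level CV for targeted-feature LC-MS
intensities in our experience, chosen once and not tuned. A CV of exactly 0
is supported as the noiseless limit, in which every planted quantity is
recovered exactly — this is what the end-to-end closure tests use.

What the generator does **not** emulate: retention times, chromatographic
peak shapes, ion suppression, evaporation kinetics, batch effects, or
missingness structure. Passing tests therefore demonstrate correctness of
the analysis logic under the stated noise model, not robustness to every
artifact of real LC-MS data.

**Determinism.** One master seed; each stage derives its own stream from it
(a fixed integer hash of the stage name), so regenerating any single
artifact is reproducible independently of the others, and identical
configurations are bit-identical end to end.

# Numerical and degenerate-input conventions

* Welch test: zero-variance conventions as above; group size < 2 is an
  error, not `NA`.
* Normalization: clipping to [0, 1] after scaling; never-produced
  metabolites are all-zero rather than 0/0.
* Ranking and scoring ties break lexicographically; all orderings in
  output are deterministic.
* PCA sign convention as above; requesting more components than
  min(conditions − 1, metabolites) is an error.
* Readers reject rather than coerce; every validation error names file,
  row and field.

# Problem sizes in the test suite

The suite regenerates everything it tests: oracle comparisons run on
randomized ≤5-ion fixtures (dozens of repetitions), the Welch calibration
uses 10,000 null simulations at n = 3, mixotrophy recovery uses 200 seeded
single-supplement screens, pathway scoring is checked against brute-force
enumeration on 100 random instances, PCA signature recovery uses 20 seeded
13-condition screens, and the end-to-end closure test runs the full
65-condition, 1,000-ion screen in the noiseless limit. These sizes give
stable pass/fail behavior at the stated tolerances while keeping a full
run in well under a minute per file.

# Known limitations

* Exact-mass annotation with a single adduct cannot separate isobars and
  will mislabel ions whose true adduct differs; ambiguous labels make the
  first limitation explicit, nothing addresses the second.
* The LOD with few background samples is noisy (see above); production
  counts near zero should be read with that in mind.
* The consumed-fraction baseline (sterile supplemented medium) conflates
  uptake with any abiotic degradation over the culture period.
* Pathway scores are descriptive; comparing them across conditions with
  very different numbers of produced metabolites compares fractions with
  different denominators.
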