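# epidrift

Quantitative analysis of long-term clonal dynamics and fitness assays in
self-maintaining 3D epithelial cultures (epithelioids), for researchers
doing multicolor (confetti-style) lineage tracing, cell-competition
assays and pooled CRISPR fitness screens in stratified squamous
epithelium.

## What it computes

**Neutral drift.** In the single-progenitor model, progenitors divide at
rate λ and commit to balanced fates with symmetric-division probability
r, so labeled clone sizes perform a critical birth–death walk with rate
κ = rλ — the single parameter behind all summary curves:

- clone survival: P(t) = 1 / (1 + κt)
- surviving clone size: E[n | n > 0] = 1 + κt
- size distribution: geometric, P(n | n > 0) = (κt)^(n−1) / (1 + κt)^n

so survival × size = 1: the number of single-colored areas (SCA) falls,
the survivors grow, and the total labeled area stays constant.
`fitDriftKappa()` fits κ to observed weekly summary curves (amplitudes
anchored at the first observed week; bootstrap CI), `simBirthDeath()` is
the exact Gillespie counterpart, and `runLattice()` is a voter-model
lattice simulation of multicolor labeling in a confluent basal layer,
with SCA extracted as same-color connected components.

**SCA trajectories.** Weekly areas are averaged in windows A4–8, A10–13,
A15–19 and classified — in rule order — as Decay1, Decay2, Decay3,
Biphasic, Growing or Steady, with a matched-pairs Wilcoxon signed-rank
test (exact for small n) for comparisons between weeks.

**Culture metrics.** Relative fitness (proportion fold change in
competition), suprabasal/basal stratification ratio, barrier
permeability percentage, wound closure rate, and the punch-passage
expansion projection initialFold × splitFactor^rounds.

**CRISPR screens.** CPM normalization with pseudocount, per-guide log2
fold change across replicates, robust z-scores anchored on nontargeting
(NT) guides, cumulative-fraction depletion AUC of guide sets, and
permutation-based gene calls (FDR < 0.1 and >10% fold change) with
per-category summaries.

**Synthetic data.** Seeded generators for confetti cohorts (9 cultures ×
39 SCA, weeks 4–19), competition series (replicator dynamics + binomial
sampling) and negative-binomial screen counts (23 driver + 62 candidate +
50 essential genes, 3 replicates, 13% targeted fraction), so the whole
pipeline runs without any download. `runPipeline()` chains the stages
from a YAML config and writes a manifest with output checksums.

## Worked example

```r
library(epidrift)

# a synthetic confetti cohort (9 cultures x 39 SCA, weeks 4-19, kappa 0.25)
cohort <- simConfettiCohort(seed = 42)
fitDriftKappa(cohort, t0 = 0, seed = 42)
#> Single-parameter neutral-drift fit
#>   kappa_hat: 0.2470505 per week  [ 0.1754495 , 0.3892201 ]
#>   objective: 0.003194741 over 16 observations; t0 = 0 weeks

cls <- classifyCohort(cohort)
round(100 * as.numeric(cls$proportions), 1)
#> Decay1 43.9  Decay2 13.7  Decay3 6.6  Biphasic 14.8  Growing 12.8  Steady 8.3

# synthetic pooled screen: essential genes deplete, NT guides do not
tab <- simScreenCounts(seed = 42)
stats <- guideZScore(guideLog2FC(tab))
ess <- stats$guide_id[stats$category == "essential"]
depletionAUC(stats, ess, "essential")$auc
#> [1] 0.9224935
table(callGenes(stats, seed = 42)$direction)
#> depleted enriched unchanged
#>       49        5        81

expansionProjection(57, 16, 4, signif = 2)
#> [1] 3700000
```

The fitted `kappa_hat` recovers the generator's drift rate (0.25/week)
from the summary curves alone; the class proportions show the neutral
signature (decay classes dominate, sustained growth is rare); the
essential-set AUC ≈ 0.92 indicates strong depletion while unchanged
drivers/candidates and NT guides stay near neutral; and four rounds of
16-piece punch passaging on a 57-fold initial amplification project to
3.7 × 10⁶-fold expansion.

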