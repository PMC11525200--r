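---
title: "Neutral drift, SCA trajectories and fitness screens: methods and design"
author: "epidrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral drift, SCA trajectories and fitness screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

# Scope

`epidrift` analyses long-term clonal dynamics in self-maintaining stratified
epithelial cultures ("epithelioids") and the fitness assays built on them.
It covers four connected analyses:

1. the analytic **single-progenitor (SP) neutral-drift model** and its
   single-parameter fit to cohort summary curves;
2. a **stochastic lattice simulation** of multicolor (confetti-style)
   clonal labeling in a confluent basal layer;
3. **single-colored-area (SCA) trajectory classification** from weekly
   live-imaging area measurements;
4. **pooled CRISPR fitness-screen statistics** with a
   nontargeting-anchored permutation caller, plus scalar culture assay
   metrics (relative fitness, stratification ratio, barrier permeability,
   wound closure, expansion projections).

Seeded synthetic-data generators emulate each input, so every stage runs
and is tested end to end with no external data.

# The single-progenitor neutral-drift model

In the SP model a single progenitor population divides at rate
$\lambda$ per week; a division yields two progenitors with probability
$r$, two differentiating daughters with probability $r$, and one of each
otherwise. The balance of symmetric fates makes clone dynamics neutral: a
labeled clone's progenitor number performs a critical birth–death walk with
per-cell rate $\kappa = r\lambda$, the only parameter entering any summary
curve. The closed forms used throughout are

$$P_\mathrm{surv}(t) = \frac{1}{1+\kappa t}, \qquad
E[n \mid n>0] = 1+\kappa t, \qquad
P(n \mid n>0) = \frac{1}{1+\kappa t}\Big(\frac{\kappa t}{1+\kappa t}\Big)^{n-1},$$

so that the expected labeled mass per founder,
$P_\mathrm{surv}(t)\,(1+\kappa t) = 1$, is conserved — fewer but larger
clones, constant total labeled area. That conservation identity is asserted
exactly in the tests, and `simBirthDeath()` (an exact Gillespie
implementation of the critical process) is checked against all three
closed forms at $10^5$ runs.

`DriftParams` stores $\kappa$ and optionally $r$, $\lambda$ and the basal
density $\rho$ (used to convert cell counts to areas). $r$ and $\lambda$
are **never fitted jointly**: neutral summary curves identify only their
product.

## The single-parameter fit

`fitDriftKappa()` fits $\kappa$ to an observed `DriftCurve` (weekly mean
surviving SCA area, SCA count, total labeled area). The model amplitudes
are anchored at the first observed time point $t_1$ rather than co-fitted,
keeping the fit genuinely single-parameter; the time origin `t0` defaults
to the labeling (induction) time, 0 weeks, with imaging typically starting
at week 4–5. Predictions are

$$N(t) = N(t_1)\,\frac{1+\kappa(t_1-t_0)}{1+\kappa(t-t_0)}, \qquad
\bar a(t) = \bar a(t_1)\,\frac{1+\kappa(t-t_0)}{1+\kappa(t_1-t_0)}.$$

**Which curve carries the information?** The loss is the sum of squared
relative residuals of the *count* (survival) curve. This was a deliberate
design decision taken after measuring the alternatives on synthetic
cohorts at the default cohort scale (351 SCA, weeks 4–19, 20 seeds): fitting counts
alone recovers $\kappa$ with a median relative error of about 9%; fitting
the mean-area curve alone gives about 23%; an equal-weight combination
gives about 14% and inverse-variance weighting about 11%. The reason is
structural, not accidental: surviving clone sizes are geometrically
distributed, so their per-week cohort mean has a coefficient of variation
near 1 and — being anchored to the (noisy) first-week mean — its errors
are shared along the entire curve, while survival counts are clean
binomial-type data anchored at an exactly known value. The mean-area and
total-area curves are still predicted, plotted and compared; they are
simply not part of the loss. A count series that never decreases is
flagged (`increasing_counts`) rather than rejected, since it indicates
dynamics incompatible with neutral decay.

Optimization is a 1-D golden-section/parabolic search (`stats::optimize`)
on $\log\kappa$ over $[10^{-6}, 10^3]$ per week with tolerance
$10^{-12}$; a brute-force grid oracle in the tests confirms the optimizer
attains the global minimum. Confidence intervals are percentile bootstrap
(default 1,000 seeded resamples) — over time points when only summaries
are available, over clones when a trajectory cohort is supplied.

# The lattice simulation

`runLattice()` implements the minimal density-conserving SP lattice rule,
a voter-type model: at total rate $N\lambda$ a cell is chosen uniformly to
divide; one of its four von Neumann neighbors (chosen uniformly)
stratifies — leaves the basal layer — and is replaced by the daughter,
which inherits the mother's color. Every event therefore conserves
occupancy exactly, and each color's labeled fraction is a martingale.
Waiting times are exponential with the seeded R RNG stream, so an
identical `LatticeConfig` reproduces an identical trace byte for byte.
The default boundary is periodic (avoids edge artifacts) and SCA are
4-connected same-color components (the conservative SCA definition;
merging of same-color neighbors is intended, since that is how SCA arise).

Two update modes are provided. In `"mean_field"` mode the stratifying cell
is drawn uniformly from the whole lattice (a Moran process), which makes
small clones behave exactly as the critical birth–death process with
$\kappa = \lambda$; the tests exploit this for a three-way agreement
between the lattice, the Gillespie process and the closed forms. The
`"neighbor"` mode is the spatial model proper: it shows the same
qualitative coarsening (fewer, larger SCA at constant labeled mass) with
spatially correlated boundaries. Whether the real tissue couples division
to neighbor loss in precisely this way is not knowable from summary
curves; the voter rule is the minimal admissible choice and is documented
as such.

Component extraction and the event loop are compiled (Rcpp) because a
$64\times64$ lattice over 8 simulated weeks processes tens of thousands of
events; 500 replicates run in seconds. The martingale and occupancy
checks in the test suite use exactly that configuration.

# SCA trajectory classification

Weekly SCA areas (mm²) are recorded with 0 meaning "below the imaging
detection limit" — extinction and sub-detection are deliberately
conflated upstream, which is why `cohortSummary()`'s survival threshold
defaults to 0. Three inclusive windows are averaged per trajectory:
weeks 4–8 ($A_{4\text{–}8}$), 10–13 ($A_{10\text{–}13}$) and 15–19
($A_{15\text{–}19}$); weeks 9 and 14 are stored but enter no window. A
window with no observation at all makes the SCA ineligible (reported, not
imputed). The classification rules are applied in order, with strict
inequalities exactly as stated and everything else falling through to the
catch-all:

| order | condition | class |
|---|---|---|
| 1 | $A_{10\text{–}13}=0$ and $A_{15\text{–}19}=0$ | Decay1 |
| 2 | $A_{10\text{–}13}>0$ and $A_{15\text{–}19}=0$ | Decay2 |
| 3 | $A_{4\text{–}8}>A_{10\text{–}13}>A_{15\text{–}19}$ | Decay3 |
| 4 | $A_{4\text{–}8}<A_{10\text{–}13}>A_{15\text{–}19}$ | Biphasic |
| 5 | $A_{4\text{–}8}<A_{10\text{–}13}<A_{15\text{–}19}$ | Growing |
| 6 | otherwise (ties included) | Steady |

The suite checks this against an independently written decision table on
the exhaustive 27 ordering/equality patterns, and checks invariance to
trajectory order and positive rescaling. On neutral synthetic cohorts the
class mix is dominated by decay, with biphasic more common than growing
and steady rarest — the qualitative ordering expected under neutral
drift, where most clones shrink and persistent growth is the exception.

`pairedSignedRank()` performs the matched-pairs Wilcoxon signed-rank test
between weeks (e.g. 4 vs 11 vs 19, any pair). Zero differences are
dropped; with up to 25 informative pairs and untied absolute differences
the exact null distribution is used, otherwise a tie-corrected normal
approximation with continuity correction. All-zero differences return
$p = 1$ with a warning rather than an error.

# Screen statistics

Counts are normalized to counts-per-million after adding a 0.5
pseudocount (keeps dropout guides finite). Per-replicate
$\log_2(\mathrm{CPM}_{wk3}/\mathrm{CPM}_{wk0})$ is averaged over the three
replicates. Guide $z$-scores are robust and anchored to the nontargeting
(NT) distribution: $z = (\mathrm{lfc} - \mathrm{median}_{NT}) /
(1.4826\,\mathrm{MAD}_{NT})$, so the median NT guide scores 0 and the
score is invariant to global shifts.

The **depletion AUC** ranks all guides by log2 fold change ascending
(most depleted first; ties broken lexically by guide id for determinism)
and integrates the cumulative fraction of a query set against the
fraction of the list traversed (trapezoid rule). Values near 1 mean
strong depletion, near 0.5 no selection, below 0.5 relative enrichment.
Note the geometric ceiling $1 - |S|/(2N)$: a set occupying the top of the
list cannot exceed it, so AUC values are only comparable across sets of
similar relative size. This ceiling also drove a generator design choice
(below).

**Gene calls** replace an external rank-aggregation tool with a
transparent permutation test: the per-gene statistic is the mean guide
log2FC; the null is the distribution of means of size-matched draws from
the pooled guide values (targeting and NT alike, $10^4$ seeded
permutations, shared across genes with equal guide counts); two-sided
permutation $p$ with the add-one correction; Benjamini–Hochberg FDR
across genes. A gene is `enriched`/`depleted` only when FDR < 0.1 **and**
its median-guide fold change differs from 1 by more than 10% — a
conventional calling threshold for pooled fitness screens — otherwise `unchanged`.
Genes with fewer than two guides are never called (warning). On null
synthetic screens the altered fraction stays within the binomial envelope
of the FDR target across 20 seeds.

# Synthetic generators: what they emulate, and what they do not

All generators are pure functions of their configuration including the
seed, restore the caller's RNG state, and write the same TSV schemas the
readers validate.

**Confetti cohorts** (`simConfettiCohort`). Defaults are a typical long-term tracing design:
9 cultures × 39 SCA (351 total), weekly areas for weeks 4–19, drift rate
$\kappa = 0.25$/week. Each SCA starts at week 4 from the conditional
geometric surviving-clone distribution — tracking begins when SCA are
recognizable, not at induction — and evolves by exact Gillespie dynamics.
Measured area is true clonal units divided by $\rho$ times multiplicative
lognormal noise (CV 0.1, mean 1); areas below 0.01 mm² record as 0. The
effective unit density $\rho = 50$ units/mm² is chosen so one clonal unit
(0.02 mm²) sits above the detection threshold: recorded zeros then mean
extinction rather than measurement dropout, matching how zeros are
treated downstream. $\rho$ is an *effective* coarse-grained density — an
SCA can be a merger of same-color clones, so a "unit" is not a single
cell. What the generator does **not** emulate: spatial merging itself,
segmentation error, color misassignment, culture-level batch effects, or
non-neutral clones; passing recovery tests therefore demonstrates
statistical correctness of the estimator under neutral drift, not
robustness to those artifacts.

**Competition series** (`simCompetitionSeries`). Deterministic replicator
dynamics $p(t) = p_0 e^{st} / (1-p_0+p_0 e^{st})$ observed through
binomial sampling; $s=0$ is a martingale. Sampled proportions are floored
at half a cell to keep them in $(0,1]$ for downstream ratio statistics.

**Screen counts** (`simScreenCounts`). 23 driver, 62 candidate and 50
essential genes (4 guides each) plus NT guides; Dirichlet-uniform week-0
abundances; week-3 expected abundance multiplied by
$e^{T s_g f}$ with screen duration $T = 3$ weeks and targeted fraction
$f = 0.13$ — the attenuation representing competition of the targeted
minority against untargeted neighbors as a simple multiplicative factor
(no frequency dependence). Counts are negative-binomial (depth 500
reads/guide, dispersion 0.2) independently per replicate; dispersion 0
gives deterministic rounded counts, which the tests use to verify the
selection closed form $\Delta\mathrm{lfc} = T s f / \ln 2$ to $10^{-6}$.
The default NT complement is 1,000 guides: with 200 essential guides the
AUC ceiling $1-|S|/(2N)$ then sits at 0.935, so a fully depleted
essential set can reach the >0.9 regime expected of a well-powered
library QC — with a 100-guide NT set the ceiling would be 0.84 and no
depletion, however complete, could look strong. Default fitness effects:
essential $-3$/week, all others 0.

# Numerical and degenerate-input conventions

* Validity tolerances on stored objects (e.g. `totalArea = meanArea ×
  count`) are relative, $10^{-9}$.
* Weeks with no surviving clone report `NA` mean area, never 0.
* Permeability percentages are not clipped to $[0,100]$; out-of-range
  values are flagged, preserving evidence of assay noise.
* Expansion projections are reported to 2 significant figures when a
  headline-style figure is requested (`signif = 2`).
* All tie-breaks (AUC ranking, component ids) are deterministic.
* Per-stage pipeline seeds derive from the global seed (`seed + k`), so a
  stage's output is independent of which other stages run.

# Problem sizes used by the test suite

The suite (and the acceptance script) choose sizes that make Monte Carlo
bounds tight while keeping the default run fast: $10^5$ Gillespie clones
for the analytic-equivalence checks, 500 replicates of a $64\times64$
lattice for the martingale test, 20 seeds × 351 SCA for drift-rate
recovery, 20 null screens for FDR calibration, and 1,000 random sets for
the AUC null. These are the package's own choices of statistically
sufficient sizes.

# Known limitations

* The fit assumes a *neutral* cohort; mutant clones with a fitness
  advantage (biased drift) are out of scope, and the `increasing_counts`
  flag is only a coarse alarm.
* The lattice has no explicit suprabasal compartment, cell mechanics or
  3D geometry; it models basal-plane topology only.
* The exact signed-rank null is unavailable with tied absolute
  differences (the tie-corrected normal approximation is used instead,
  whatever the sample size).
* The permutation gene caller tests the mean guide effect; it will be
  conservative for genes where a single guide of several carries the
  signal.
* SCA identity across imaging frames is assumed resolved upstream; the
  package never re-segments or re-matches clones.
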