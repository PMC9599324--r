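---
title: "Community dynamics of the vaginal microbiome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community dynamics of the vaginal microbiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagidyn)
```

## The problem

Healthy vaginal microbiomes are usually dominated by a single *Lactobacillus*
species — most often *L. crispatus* or *L. iners* — but the dominant taxon can
change over time, and menstruation is a major destabilizing event. vagidyn
implements a complete analysis chain for longitudinal 16S amplicon studies
anchored to the menstrual cycle: samples are collected at six time points
(V1 = day 0, just after menstruation; D7, D14, D21; V2 = day 28, again just
after menstruation; V3 = day 42), across two treatment arms (placebo
vs. an oral supplement). The package answers three kinds of questions:

1. **Community typing** — which taxon (or pair) dominates each sample, and
   how often does a woman's dominant taxon shift across the cycle?
2. **Relative abundance differences (RAD)** — for a taxon of interest, how
   does its relative abundance change between time points within
   participants, and does that change differ between arms?
3. **Concordance** — can a cheap four-species qPCR panel predict the
   dominant *Lactobacillus* seen by sequencing?

## Community typing rules

Samples are aggregated to *Lactobacillus* subgenus groups
(`L_crispatus_group`, `L_iners_group`, `L_gasseri_group`,
`L_jensenii_group`, `L_pasteurii_group`) plus genera for everything else,
then classified:

* **Codominance first**: if the crispatus and iners groups each exceed 10%
  and jointly exceed 50%, the sample is `CRISP_INERS_CODOM`. Codominance is
  checked before single dominance so that, e.g., crispatus 45% / iners 12%
  is codominant even though crispatus alone would qualify.
* **Single dominance**: otherwise, if the most abundant taxon exceeds 40%,
  the sample takes that taxon's label — `CRISPATUS_DOM`, `INERS_DOM`, the
  merged `OTHER_LACTO_DOM` for the three rarer *Lactobacillus* groups, or
  `NON_LACTO` for any non-*Lactobacillus* taxon.
* **Residual**: nothing above 40% is `NON_LACTO`.

Thresholds are strict (`>`) by default: a taxon at exactly 40% does *not*
dominate. Survey descriptions of such rules sometimes use `>=`; the
`inclusive = TRUE` flag reproduces that reading. Ties at the top abundance
are broken alphabetically by taxon name so classification is deterministic.

"Shift" is deliberately reported two ways, because the two readings differ
and published summaries rarely say which they used: `n_transitions` counts
adjacent unequal labels in time order (the headline number), and
`n_deviations` counts samples that differ from the participant's modal
label (ties toward the earliest-occurring modal label). A participant is
stable iff both are zero.

Reported percentages are rounded half away from zero
(`report_percent(65, 200)` is 33, not 32), matching the convention used
when prevalences like 50/101 = 50% are printed; raw fractions are always
retained in the output tables.

## The RAD framework

For one taxon and a pair of time points, each participant contributes one
RAD: relative abundance at the later time point minus the earlier one.
Missing samples are never imputed; every comparison uses the
pairwise-complete participants.

`median_rad_matrix()` fills all 15 ordered time-point pairs with the median
RAD, a two-sided Wilcoxon signed-rank test on the paired abundances, and
Benjamini–Yekutieli (BY) adjustment across exactly the tested cells of that
one matrix (one taxon, one analysis — not across taxa). BY is the step-up
FDR procedure inflated by the harmonic constant `c(m) = sum(1/(1:m))`,
valid under the arbitrary dependence a shared-time-point matrix exhibits.

`differential_rad_matrix()` compares per-participant RADs between arms:
the effect size is the Hodges–Lehmann estimator — the median of all
pairwise between-arm differences — and significance a two-sided Wilcoxon
rank-sum test, again BY-adjusted. The sign convention
(`treatment_minus_placebo` by default) is explicit and flippable because
descriptions of "differential RAD" are commonly ambiguous about direction;
flipping negates the estimates and leaves p-values untouched.

Numerical conventions, all configurable where they are genuine choices:

* Signed-rank tests are exact for n ≤ 25 without ties or zero differences,
  otherwise a normal approximation with continuity correction. Zero
  differences are dropped (Wilcoxon's convention); `zero_method = "pratt"`
  keeps them in the ranking instead.
* Rank-sum tests are exact when the smaller arm has ≤ 10 observations and
  there are no ties. Cells where both arms carry identical constant values
  have no rank information and return p = 1.
* Cells with fewer than 2 complete pairs (or an empty arm) are left
  untested (`NA`) and excluded from the BY family.
* RADs are kept as fractions internally and reported in percentage points
  where headline numbers are printed.

`cross_sectional_test()` covers the complementary unpaired question
(do arms differ at one visit) with a tie-corrected Kruskal–Wallis test.

## Diversity and sample ordering

Alpha diversity is the inverse Simpson index `1/sum(p^2)` (effective number
of taxa), computed at ASV level by default — the level choice is exposed
because aggregated compositions give systematically lower values. Richness
counts observed ASVs and deliberately refuses relative input, where it
would be depth-confounded. Beta diversity is Bray–Curtis, which for
relative abundances is half the L1 distance; it is a semimetric, so tests
assert symmetry, range and identity but *not* the triangle inequality.
`distance_to_baseline()` references every sample to the same participant's
V1 sample; participants without a V1 are flagged, not imputed.

Composition bar plots are conventionally laid out by placing similar
samples next to each other. `order_by_neighbor_distance()` casts this as a
minimum-cost Hamiltonian path under Bray–Curtis: exact Held–Karp dynamic
programming up to 10 samples (the objective is NP-hard in general),
greedy nearest-neighbour from the best start refined by 2-opt beyond that.
A path equals its reversal, so the orientation starting at the
lexicographically smaller endpoint is returned, making output
deterministic.

## qPCR dominance prediction

The panel quantifies *L. crispatus*, *L. iners*, *L. gasseri* and
*L. jensenii* (CFU/mL). If the two largest concentrations are crispatus
and iners within a 2-fold ratio (strict, direction-free), the prediction
is codominance; otherwise the single largest species maps to its group.
The prediction depends only on concentration ranks plus that one ratio, so
it is invariant to rescaling — calibration offsets that multiply all four
concentrations cancel. The panel cannot express `NON_LACTO`, so agreement
with 16S typing is scored over *Lactobacillus*-typed samples by default,
with the non-*Lactobacillus* count reported separately and an alternative
denominator including them as automatic disagreements.

Note one structural caveat: the 16S codominance rule (10%/50%) and the
qPCR rule (<2-fold) are different definitions and need not agree near
their respective boundaries even with perfect measurements.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage is testable without
access to a real cohort. Defaults emulate the motivating study design:

* 18 placebo + 34 treatment participants, six time points, ~4% of samples
  missing (301 of 312), never a participant's whole series.
* Five community archetypes with assignment weights 15/52 (crispatus),
  15/52 (iners), 12/52 (codominant), 3/52 (other-*Lactobacillus*), 7/52
  (non-*Lactobacillus*). These are the disjoint baseline counts: published
  tallies of "≥40% dominated" women include codominant women in both
  single-taxon counts, so the overlapping 18/24/12 become 15/15/12 once
  codominance is its own class.
* Two-level Dirichlet noise: a personal base composition around the
  archetype mean (concentration 60), then a fresh draw per time point
  around the personal base (concentration 150). Neither concentration is
  identifiable from published summaries; they were chosen once to give
  realistic between-woman spread while keeping archetypes recognizable,
  and are exposed in the config.
* Menstrual perturbation at V1 and V2 only: a logit-scale shift of −0.5 on
  the crispatus group (a 7–12 percentage-point drop over its typical
  abundance range, matching the reported 6.76–10.05% post-menstrual
  reduction of lactobacilli), and +0.4 jointly on *Gardnerella* and
  *Streptococcus*. Effects act on the logit scale so compositions stay on
  the simplex. In the single-dominant archetypes the minority partner of
  the crispatus/iners pair sits at 5%, safely below the 10% codominance
  threshold, so label flips reflect real composition changes rather than
  threshold chatter.
* Treatment effects (zero by default) act in the treatment arm at
  post-baseline time points only — supplementation starts right after the
  V1 swab, and a time-constant arm effect would cancel out of every RAD.
* Reads are multinomial at depth 10,000; qPCR values are total load
  (lognormal, mean 10^9.8 CFU/mL, the observed scale for vaginal
  lactobacilli) × species abundance × lognormal noise (0.2 log10 units).
* Each participant consumes an RNG stream derived from (seed, participant
  index), so adding or removing participants never changes the others'
  draws, and the caller's RNG state is untouched.

The generator returns the latent truth (compositions, archetypes, latent
dominance labels, dropout flags) for recovery testing.

**What the generator does not emulate.** Real cohorts show more
within-woman dynamics than the defaults produce (the motivating study saw
69% of women shift at least once; the defaults give ~10%, because the
generator's archetypes are well separated and its defaults are calibrated
to the menstrual RAD magnitudes, not to the shift distribution). It also
has no hormonal covariates, no read-depth variation, no contamination, and
its taxa are a fixed 11-ASV universe. Passing recovery tests therefore
demonstrates that the statistics detect effects of the modelled kind at
study scale — not that real vaginal dynamics are this clean.

## Validation strategy

The test suite pairs every estimator with an independent oracle: the
Hodges–Lehmann estimate against explicit enumeration of all pairwise
differences; BY adjustment against a hand-written step-up implementation
and a worked three-value example (c(3) = 11/6 gives
{0.0550, 0.0550, 0.0917} from {0.01, 0.02, 0.05}); the exact signed-rank
p = 0.0625 for five uniformly positive differences (2 of 32 sign
patterns); Kruskal–Wallis H = 27/7 ≈ 3.857 on {1,2,3} vs {4,5,6}; the
ordering heuristic against brute force over all paths up to n = 8; and
inverse Simpson / Bray–Curtis against vegan. Monte-Carlo checks run at
study scale (n = 52): the injected menstrual effect is recovered
(negative crispatus D7→V2 median RAD, BY-adjusted p < 0.05) in ≥ 90% of
50 replicates while iners stays below half the crispatus magnitude; with
all effects zero, BY-significant cells occur in well under 5% of matrix
cells across 200 replicates, and observed stability matches truth-derived
stability within 5 percentage points. Replicate counts (50/200) keep the
whole suite a few minutes long while leaving the binomial error on those
rates far below the asserted margins.

## Known limitations

* Community typing is threshold-based, not probabilistic; samples near
  40%/10%/50% flip labels under resampling noise. The two-way shift
  reporting partly mitigates, but a nearest-centroid or model-based typing
  is out of scope.
* BY correction is applied per matrix (one taxon, one analysis). Scanning
  many taxa still multiplies families; callers doing taxon-wide screens
  should correct across taxa themselves.
* The qPCR panel covers only four species; samples dominated by anything
  else are structurally unpredictable from the panel and are reported, not
  scored, by default.
* No prevalence filtering is applied anywhere; rare-taxon noise flows into
  ASV-level diversity metrics (richness especially) exactly as observed.
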