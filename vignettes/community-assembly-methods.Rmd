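---
title: "Methods: succession and assembly analysis of plastisphere communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: succession and assembly analysis of plastisphere communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastisphere)
```

# The scientific question

Microbial biofilms that form on plastic particles in lakes — the
*plastisphere* — are seeded from the surrounding water and then reshaped by
colonisation time, by the surrounding environment, and by the polymer the
biofilm grows on. This package implements the statistical machinery used to
characterise that succession from marker-gene (ASV) count tables:

* **alpha diversity** — species richness and Faith's phylogenetic diversity
  per sample, tracked over colonisation time;
* **beta-diversity partitioning** — pairwise Sørensen dissimilarity split
  into species turnover (the Simpson component, `beta_sim`) and nestedness
  (`beta_sne`), summarised by `beta_ratio = beta_sim / beta_sor`;
* **assembly null models** — the between-community mean nearest taxon
  distance (βMNTD), its standardised effect size against a tip-shuffling
  null (βNTI), and Raup–Crick with Bray–Curtis (RCbray), classified into
  ecological assembly processes;
* **succession statistics** — time-decay of community similarity
  (temporal turnover rate), PERMANOVA across design factors, Mantel tests
  against environmental distances, and a convergence-trend statistic for
  between-polymer differences over time.

A synthetic study generator emulating a 4-lake × 8-polymer × 5-timepoint
colonisation experiment (plus particle-associated and free-living water
fractions) provides ground truth for every stage.

# Models and procedures

## Beta-diversity partition and the beta-ratio

For a sample pair with `a` shared taxa and `b`, `c` taxa unique to either
side, the package computes the pairwise Baselga decomposition

* `beta_sor = (b + c) / (2a + b + c)` (total Sørensen dissimilarity),
* `beta_sim = min(b, c) / (a + min(b, c))` (turnover),
* `beta_sne = beta_sor − beta_sim` (nestedness),
* `beta_ratio = beta_sim / beta_sor`.

A mean `beta_ratio` above 0.5 in a group of pairs means beta diversity is
dominated by species replacement rather than by richness differences; the
call at exactly 0.5 is "nestedness" because the rule is a strict
inequality. The pairwise (not multiple-site) decomposition is used, averaged
over within-cell pairs, because the per-stage summaries are means over
cross-polymer pairs at one lake and day; whether all within-lake pairs or
only cross-polymer pairs enter a cell is switchable (`pairs = "all"` /
`"cross_polymer"`, the latter being the default since the stage-wise
comparison targets substrate-driven differences). Pairs with identical
incidence (`beta_sor = 0`) have no defined ratio; they are excluded and
counted.

## Assembly null models

βMNTD between communities x and y is
`0.5 * (Σ_i f_i min_j d_ij + Σ_j g_j min_i d_ij)` where `d` is the
patristic distance and `f`, `g` are relative abundances (uniform over
present taxa in the unweighted variant). The abundance-weighted variant is
the default. βNTI standardises the observed βMNTD against `n_null`
shuffles of taxon labels across the pool's tips; each pair receives its own
independent, seeded shuffles. Pairs whose null distribution has zero
standard deviation (e.g. both communities occupying every pool tip) are
flagged undefined and excluded from classification with a warning.

RCbray reassembles each community `n_null` times from the regional pool,
preserving its observed richness (taxon inclusion probability proportional
to pool occupancy, each drawn taxon seeded with one read) and its observed
total (remaining reads filled multinomially by the pool's mean relative
abundance over the drawn taxa). The score is the position of the observed
Bray–Curtis within that null, rescaled to [−1, 1], with ties counted at
half weight (mid-p convention).

Classification of a pair follows the standard two-stage rule: βNTI > +2 is
heterogeneous selection and βNTI < −2 homogeneous selection; within the
stochastic band, RCbray > +0.95 is dispersal limitation, RCbray < −0.95
homogenizing dispersal, and anything else drift. Boundary values (exactly
±2, exactly ±0.95) fall on the stochastic/drift side because the published
thresholds are strict inequalities. The defaults `n_null = 999`,
thresholds 2 and 0.95, and abundance weighting follow the established
framework; all are configurable.

**Null pool scope.** The null pool is all samples of one lake by default
(`pool_scope = "per_lake"`), *including* the water-fraction samples when
they are part of the supplied table. This matters: the water communities
carry the taxa that selection has filtered out of the plastisphere, and
without them a clade-restricted plastisphere would define a pool in which
its own restriction is invisible. A `"global"` scope is available.

## Time-decay, PERMANOVA, Mantel, convergence

Time-decay regresses `log10(similarity)` on `log10(Δt)` over within-group
pairs (similarity is 1 − Sørensen by convention in the pipeline); the slope
magnitude is the temporal turnover rate, with the sign retained. The
log-log form is the standard distance-decay formulation; a linear option is
provided and the transform used is recorded in the output. Pairs with zero
or negative similarity are excluded from the log fit rather than patched
with a pseudocount (an arbitrary constant would dominate the slope), and
pairs at Δt = 0 are likewise excluded because the log abscissa is undefined
there; both exclusions are counted in the report. A group whose pairs all
sit at one time distance cannot be fit and raises an error; constant
similarity yields slope 0 with `r_squared` reported as 0 by convention
(nothing explained).

PERMANOVA uses sequential (Type-I) sums of squares in the order the terms
are supplied — main effects before interactions, matching the usual
adonis-style tables — with p-values from free label permutations (seeded),
optionally restricted within strata blocks; restricted permutation is also
the mechanism offered for nested time-within-environment questions. An
explicit permutation matrix can be supplied, which is how the tests compare
the permutation p against full enumeration at n = 4. The Mantel test is the
correlation of off-diagonal distances with joint row/column permutation.

The convergence trend computes, per lake, the mean Bray–Curtis
dissimilarity between samples of *different* polymers at each day, then the
OLS slope of that mean against day; a negative slope is a convergence call
(substrate identity matters less and less as the biofilms mature).

# The synthetic study generator

`generate_study()` emulates the sampled design of a multi-lake colonisation
experiment: one pooled sample per lake × polymer × day (the default
4 × 8 × 5 design gives 160 plastisphere samples) plus per-lake
particle-associated (WP) and free-living (WF) water samples at each day
(40 water samples). All randomness derives from one seed; identical
configurations are byte-identical.

Mechanism, in order:

1. a shared log-normal base composition over the taxon pool (sd 1.2 on the
   log scale, a typical rank-abundance steepness for amplicon surveys);
2. per-lake species pools — the base perturbed by a log-normal factor with
   sd `pool_divergence`;
3. per-polymer enrichment factors (sd `polymer_effect`) acting on the
   starting composition of each lake × polymer series;
4. temporal convergence — the composition at day t is
   `(1 − m(t)) · start + m(t) · attractor` with `m(t) = 1 − exp(−κ t)` and
   an attractor *shared by all lakes and polymers*, so κ > 0 directly
   encodes cross-polymer and cross-lake convergence and κ = 0 disables it;
5. an assembly regime shaping how counts are drawn (below);
6. multinomial read counts at the configured sequencing depth; every
   sample's total equals the depth before any pruning;
7. environmental variables per lake × day with a lake effect plus a day
   trend, mixed with noise by `env_coupling`.

**Assembly regimes.** Each sample draws a fixed number of taxa (a
`sample_richness` fraction of the pool) and fills reads multinomially; the
regimes differ only in the weights:

* *homogeneous selection* multiplies the weights of one clade's tips by
  `exp(selection_strength)`. The clade is chosen as the phylogenetically
  tightest clade holding roughly a quarter of the tips — a small, deep
  clade is what makes selected communities measurably clustered relative to
  the pool, whereas a half-pool clade is nearly as dispersed as the pool
  itself. Which clade members arrive in a given sample stays random, so
  two selected communities overlap only partially and their non-shared
  taxa carry the within-clade signal.
* *dispersal limitation* multiplies the weights by per-sample log-normal
  noise with sd `selection_strength`, so each community is dominated by its
  own random taxa: observed Bray–Curtis then exceeds what richness- and
  abundance-preserving random assembly predicts, which is exactly the
  RCbray signature, while remaining phylogenetically unstructured.
* *neutral* draws taxa uniformly and fills from the unmodified pool
  composition — deliberately the same assembly law the RCbray null uses, so
  neutral data are the calibration instrument for both null models.

`sample_richness = 1` is a special case: plain multinomial sampling of the
full mixture composition with no membership subsampling. This is the
configuration used for convergence analyses, where the signal of interest
lives in the composition rather than in membership turnover.

Default intensities (chosen once, as the generator's ground-truth
conditions): `selection_strength` 4 for homogeneous selection, 2 for
dispersal limitation, 0 under neutrality; `sample_richness` 0.3;
`pool_divergence` 1; `polymer_effect` 0.5; `convergence_rate` 0.05 per day.

**What the generator does not emulate.** Real plastisphere data have
compositional sequencing noise, chimeras and contamination, taxon-specific
amplification bias, temporal autocorrelation of the water source, and
polymer-by-time interactions beyond a static enrichment factor. Passing
the package's recovery and calibration checks on synthetic data therefore
demonstrates the correctness and calibration of the *statistics*, not that
any particular real dataset satisfies their assumptions.

# Numerical choices and degenerate inputs

* Counts are validated as non-negative integers; all-zero samples and taxa
  are dropped with a warning, so downstream code may assume positive sample
  totals. Relative abundances are always derived, never stored.
* Trees must carry finite, non-negative branch lengths; tips absent from
  the table are pruned with a warning, while table taxa missing from the
  tree are an error (the analysis would silently change meaning).
* The taxon rows of the community matrix are put in a canonical order
  inside the null-model functions, so results are invariant to the input
  row order even at fixed seeds.
* RCbray tie counting uses half weight with an absolute tolerance of 1e-12
  on Bray–Curtis equality (counts are integers, so ties are exact rationals).
* Groups with a single sample report a missing (not zero) standard
  deviation in alpha trajectories; cells with fewer than two samples are
  skipped with a warning in beta-ratio summaries.
* Every stochastic function takes a seed; the pipeline derives per-stage
  seeds from one master seed by a fixed offset table (`derive_seed`), so a
  single integer reproduces an entire run.
* Optional rarefaction to a common depth is provided (seeded,
  `rarefy_counts()`) but off by default: no depth normalisation is applied
  before distance computation unless explicitly requested, and reports
  state the depths used.

# Demonstration problem sizes

The shipped tests and the acceptance script exercise every stage at sizes
chosen to make Monte-Carlo properties measurable while staying desk-scale;
these are the package's documented demonstration conditions:

* **Null-model calibration** uses neutral-regime datasets of one lake ×
  4 polymers × 5 days (20 plastisphere samples, 300-taxon pool, depth
  3000, even pools), pooled over several independent datasets for βNTI
  (each tree contributes its own null-shape wobble, so pooling across
  trees is what stabilises the tail estimate), and one 100-sample dataset
  for RCbray (the RC null's occupancy weights are estimated from the data;
  with few samples that estimate is noisy and both null communities of a
  pair share it, which biases RC upward — the bias shrinks roughly as
  1/S, hence the larger sample count). With 999 randomisations the
  measured |βNTI| > 2 and |RCbray| > 0.95 rates sit near the nominal 5%.
  The βNTI z-tail runs slightly conservative (the permutation null is
  mildly right-skewed, so a ±2 z-cut captures a little less than the
  normal-theory 4.6%); the rank-based tail is closer to nominal.
* **Regime recovery** uses 20 seeds per regime at one lake × 4 polymers ×
  3 days with a 200-taxon pool, richness fraction 0.1 and strength 6 for
  homogeneous selection (partial clade overlap maximises the within-clade
  signal) and richness 0.3, strength 3 for dispersal limitation; 199
  randomisations per pair; water samples included in the null pool.
* **Convergence detection** uses 20 seeds of a 2-lake × 8-polymer × 5-day
  design at `sample_richness = 1`, κ = 0.05 against a κ = 0 control.
* **Statistical calibration** uses 500 replicates each for PERMANOVA
  (n = 20, four groups, 99 permutations) and Mantel (n = 30, 99
  permutations); with 99 permutations the rejection rule p ≤ 0.05 has an
  exact 5% level under the null.

# Known limitations

* βNTI's ±2 cut is a z-score criterion; its tail mass depends on the
  shape of the permutation null, which varies with tree geometry. On trees
  with a few long pendant branches the criterion is conservative.
* The RCbray null estimates pool occupancy and abundance from the data;
  with few samples this induces a positive bias (see above). This is a
  property of the plug-in null, not of the implementation.
* The pairwise beta-ratio summarises cells by the mean over pairs;
  multiple-site decompositions answer a related but different question and
  are out of scope.
* PERMANOVA's sequential partition depends on term order, which is
  therefore part of the report, and interaction R² from unreplicated
  designs should be read descriptively.
* The time-decay transform (log-log vs linear) changes slope units;
  reported slopes carry the transform tag and are only comparable within
  one choice.
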