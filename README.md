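# plastisphere

Community succession and assembly analysis for plastisphere microbiomes.

Biofilms that grow on plastic particles in lakes — the *plastisphere* — are
seeded from the surrounding water and reshaped over colonisation time by the
environment and by the polymer they grow on. Given an ASV count table, a
phylogeny and per-sample design factors (lake, day, polymer, water
fraction), this package quantifies that succession and infers the ecological
processes behind it. It is aimed at microbial ecologists analysing
time-resolved colonisation experiments; the same machinery applies to any
multi-site, multi-substrate, multi-timepoint community survey.

## What it computes

**Alpha diversity.** Species richness and rooted Faith's phylogenetic
diversity (total branch length of the minimal subtree spanning a sample's
taxa and the root), with group trajectories over colonisation time.

**Beta-diversity partition.** For each sample pair with `a` shared and
`b`, `c` unique taxa, the pairwise Baselga decomposition of Sørensen
dissimilarity into turnover and nestedness,

    beta_sor = (b + c) / (2a + b + c)
    beta_sim = min(b, c) / (a + min(b, c))
    beta_sne = beta_sor - beta_sim
    beta_ratio = beta_sim / beta_sor

with `beta_ratio > 0.5` meaning beta diversity is turnover-dominated.

**Assembly null models.** Abundance-weighted βMNTD between communities,

    bMNTD = 0.5 * ( Σ_i f_i min_j d_ij  +  Σ_j g_j min_i d_ij )

its standardised effect size βNTI against seeded tip-label shuffles, and
Raup–Crick with Bray–Curtis (RCbray) against richness- and
total-preserving random assembly from the regional pool. Each pair is
classified: βNTI > +2 heterogeneous selection, βNTI < −2 homogeneous
selection; within the stochastic band, RCbray > +0.95 dispersal
limitation, RCbray < −0.95 homogenizing dispersal, otherwise drift.
Group-level process fractions report the deterministic/stochastic and
homogenizing/differentiating shares.

**Succession statistics.** Time-decay of community similarity
(`log10(similarity) ~ log10(Δt)`; the slope magnitude is the temporal
turnover rate), sequential PERMANOVA over design factors and interactions,
Mantel tests against environmental distance, and a convergence trend: the
OLS slope of mean between-polymer dissimilarity against day, negative when
substrate identity matters less as biofilms mature.

**Synthetic studies.** `generate_study()` simulates the full design —
4 lakes × 8 polymers × 5 collection days of plastisphere samples plus
particle-associated (WP) and free-living (WF) water fractions, 160 + 40
samples by default — with controllable lake-pool divergence, temporal
convergence toward a shared attractor, polymer effects, and ground-truth
assembly regimes (homogeneous selection / dispersal limitation / neutral).
See the methods vignette (`vignettes/community-assembly-methods.Rmd`) for
the mechanism and for every numerical choice.

## Worked example

Simulate a two-lake study whose prokaryote-like communities are assembled
under homogeneous selection with temporal convergence, then recover both
signals:

```r
library(plastisphere)

design <- design_config(n_lakes = 2, polymers = c("PP", "PE", "PLA", "PHA"),
                        days = c(3L, 7L, 15L, 30L, 60L),
                        n_taxa = 120, sequencing_depth = 2000, seed = 42)
regime <- regime_config(assembly_regime = "homogeneous_selection",
                        convergence_rate = 0.05, sample_richness = 0.1,
                        selection_strength = 6)
study  <- generate_study(design, regime)
counts <- validate_abundance_table(study$counts)

res <- assembly_analysis(counts, study$tree, study$metadata,
                         null_config(n_null = 199, seed = 1))
pl <- study$metadata$sample_id[study$metadata$fraction == "plastisphere"]
res_pl <- res[res$sample_i %in% pl & res$sample_j %in% pl, ]
process_fractions(res_pl, study$metadata)[
  , c("lake", "n_pairs", "homogeneous_selection", "drift", "deterministic_share")]
#>   lake n_pairs homogeneous_selection     drift deterministic_share
#> 1   L1     190             0.4789474 0.4736842           0.4789474
#> 2   L2     190             0.3736842 0.5736842           0.3736842

cv <- convergence_trend(bray_curtis_matrix(counts[, pl]), study$metadata)
cv$trend
#>   group         slope intercept    r_squared convergence
#> 1    L1 -3.039835e-03 0.6636162 0.3056095117        TRUE
#> 2    L2 -5.441222e-05 0.6446348 0.0008661735        TRUE
```

Homogeneous selection is the leading deterministic process in both lakes
(47.9% / 37.4% of plastisphere pairs, against ~5% on neutral data), and the
between-polymer dissimilarity slope is negative in both lakes — the
convergence effect. Single simulations are noisy (L2's slope here is barely
below zero); the tested guarantees are over replicate seeds, see
`tests/testthat/test-acceptance.R`.

The same analyses are scriptable through a thin command-line wrapper:

```sh
Rscript inst/cli/assemblage.R simulate --out study/ --seed 3
Rscript inst/cli/assemblage.R alpha --abundance study/abundance.tsv \
    --tree study/tree.nwk --out alpha.tsv
```

with subcommands `simulate | alpha | beta | assembly | timedecay |
permanova | mantel | convergence | run` (exit codes: 0 ok, 2 validation
error, 3 stage failure), and `run_pipeline()` orchestrates all stages from
one seeded config, writing every stage TSV plus a machine-readable
`summary.json`.

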