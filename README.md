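# migseqr

Museomics phylogenomics for MIGseq loci.

MIGseq (multiplexed ISSR genotyping by sequencing) amplifies thousands of
short loci (~300–800 bp) between simple-sequence-repeat anchors by PCR. It
works on the fragmented DNA of century-old herbarium sheets as well as on
silica-dried field material — and because it sequences PCR amplicons
instead of the original fragments, it should sidestep the terminal
C→T / G→A deamination damage that affects direct sequencing of degraded
DNA. `migseqr` is the analysis side of such a study, for researchers who
want to turn mixed herbarium/silica reduced-representation data into
filtered loci, damage diagnostics, divergence statistics, trees and
divergence times — and to validate each step against simulated truth.

## What it computes

| Stage | Functions |
|---|---|
| Synthetic data with truth tables | `simulate_migseq()`, `simulate_species_tree()`, `evolve_loci()`, `apply_dropout()`, `simulate_reads()`, `assign_zones()`, `simulate_rate_phylogram()` |
| Locus assembly + filter cascade | `assemble_loci()`, `quality_filter_reads()`, `cluster_within_sample()`, `estimate_het_error()`, `call_consensus()`, `cluster_across_samples()`, `filter_loci()`, `compute_assembly_stats()`, `compare_groups()`, `correlogram_stats()` |
| Deamination damage profiling | `profile_damage()`, `misincorporation_profile()`, `terminal_damage_test()` |
| Genomic context of loci | `nearest_feature()`, `locus_density()`, `spacing_randomness_test()` |
| Zone divergence | `p_distance()`, `pool_pairwise_distances()`, `label_zone_pairs()`, `group_summaries()`, `two_way_anova()`, `tukey_hsd()` |
| Presence–absence phylogenetics | `build_presence_matrix()`, `binary_distance()`, `nj_tree()`, `bootstrap_support()`, `extract_snps()` |
| Penalized-likelihood dating | `fit_pl()`, `cross_validate_lambda()`, `pl_objective()`, `calibration()` |

The statistical core: per-sample heterozygosity/error are estimated by
joint ML under a diploid site model; loci pass an explicit, per-reason
filter cascade (depth ≥ 5, ≤ 2 alleles, ≤ 5 N, ≤ 8 heterozygous sites,
≤ 40 indels, ≥ 4 taxa); divergence is the pooled per-locus pairwise
p-distance labeled intra-/inter-zone and tested by type-II two-way ANOVA
with Tukey HSD; trees come from a Saitou–Nei neighbor-joining
implementation with loci-resampling bootstrap; and divergence times
minimize

```
-log L(ages, rates) + lambda * Phi,   x_b ~ Poisson(r_b * t_b * n_sites)
```

with a log-rate roughness penalty `Phi`, min/max fossil calibrations
(e.g. a 33.9–53 Ma root constraint), and `lambda` chosen by
leave-one-terminal-out cross-validation with a chi-square score.

## Worked example

Simulate a 10-species study (one third herbarium material, damage-free
amplicon reads), assemble loci, score continent-vs-island divergence and
date a clock phylogram:

```r
library(migseqr)

cfg <- pipeline_config(
  master_seed = 42,
  simulate = list(n_species = 10L, n_loci = 40L, depth = 10L,
                  length_range = c(150L, 250L)))
sim <- simulate_migseq(cfg)
asm <- assemble_loci(sim$reads)
print(asm$report)
#> Locus filter report
#>   candidate loci: 40
#>   removed (low_taxa): 0
#>   ...
#>   retained: 40
```

All 40 simulated loci survive the cascade (error-free amplicon reads at
depth 10). Divergence by biogeographic zone:

```r
recs <- pool_pairwise_distances(asm$loci)
lab  <- label_zone_pairs(recs, zone_config("zones2",
                                           as.list(sim$zones$zones2)))
group_summaries(lab)
#>        zone  type   n     median          q1         q3
#> 1 continent intra 769 0.01310044 0.005847953 0.03056769
#> 2 continent inter 764 0.04571429 0.037815126 0.05741627
#> 3    island intra 109 0.03902439 0.021008403 0.04910714
#> 4    island inter 764 0.04571429 0.037815126 0.05741627

two_way_anova(lab)
#>        term   df      sum_sq    f_value       p_value
#> 1      type    1 0.274959181 1113.64981 5.974317e-201
#> 2      zone    1 0.004884908   19.78503  9.060633e-06
#> 3 type:zone    1 0.019546157   79.16657  1.098407e-18
#> 4 Residuals 2402 0.593051735         NA            NA
```

Species sharing a zone are markedly closer (intra-zone median 0.013 on
the continent) than species from different zones (median 0.046), and the
distance-type term dominates the ANOVA — the clade-structured zone
assignment built into the simulation is recovered. Dating the tree from a
10,000-site clock phylogram under a 33.9–53 Ma root calibration:

```r
ph  <- simulate_rate_phylogram(sim$tree, base_rate = 0.002,
                               rate_model = "clock", n_sites = 10000,
                               seed = 7)$phylogram
fit <- fit_pl(ph, list(calibration(min = 33.9, max = 53)),
              lambda = 1e5, n_sites = 10000)
print(fit)
#> Penalized-likelihood chronogram fit
#>   10 tips, lambda = 100000, n_sites = 10000
#>   root age: 43.459 Ma
#>   rate range: [0.00211, 0.00212] subst/site/Ma
#>   objective: 64.9896
```

At `lambda = 1e5` the fitted rates collapse to a strict clock
(0.00211–0.00212 subst/site/Ma against a true rate of 0.002). Note the
root age: with clock-like data, ages inside the calibration interval are
equally likely and the fit reports the mid-box solution — see the methods
vignette (`vignettes/migseq-museomics.Rmd`) for this and every other
modeling decision.

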