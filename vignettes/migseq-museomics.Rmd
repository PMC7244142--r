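---
title: "Museomics phylogenomics with migseqr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Museomics phylogenomics with migseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migseqr)
```

## The analysis problem

MIGseq (multiplexed ISSR genotyping by sequencing) amplifies short loci
(~300–800 bp) between simple-sequence-repeat anchors by PCR, and works on
the fragmented DNA typical of herbarium sheets as well as on silica-dried
field collections. Because the sequenced molecules are PCR amplicons rather
than the original fragments, the terminal cytosine deamination that plagues
ancient-DNA data should be absent. `migseqr` implements the downstream
analysis chain for such data:

1. **Locus assembly** — quality filtering, greedy within-sample clustering,
   joint ML estimation of heterozygosity *h* and sequencing error *e*,
   statistical consensus calling, across-sample clustering, and an explicit
   filter cascade (depth, allele count, N and heterozygous-site caps,
   indels, taxon occupancy) with a per-reason report.
2. **Damage profiling** — reads are aligned back to their consensus locus
   and C→T (5′) / G→A (3′) misincorporation frequencies are profiled by
   distance from the read end, with a terminal-vs-interior two-proportion
   test.
3. **Genomic context** — nearest annotated feature (CDS / TE / UTR)
   per locus, per-chromosome locus density, and a spacing-randomness test.
4. **Zone divergence** — per-locus pairwise p-distances pooled over loci,
   labeled intra-/inter-zone under 2-, 4- and 6-zone biogeographic
   configurations, summarized and tested by two-way ANOVA plus Tukey HSD.
5. **Presence–absence phylogenetics** — binary distances over the
   samples × loci matrix, a Saitou–Nei neighbor-joining tree implemented in
   the package, bootstrap supports over resampled loci, and SNP-matrix
   export for external maximum-likelihood programs.
6. **Penalized-likelihood dating** — node ages and branch rates fitted to a
   phylogram under a Poisson substitution likelihood with a roughness
   penalty, min/max fossil calibrations, and cross-validated choice of the
   smoothing parameter.

A fully seeded synthetic-data module generates every input the pipeline
consumes, so each stage is testable end to end without any sequencing data.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions the test suite exercises.

* **Species tree**: pure-birth conditioned on the number of tips, rescaled
  to a root age in Ma (default 45, an Eocene-scale crown age appropriate
  for a tropical tree genus spanning continental Asia and Malesia). This is
  the simplest ultrametric generator with a controllable depth.
* **Loci**: Jukes–Cantor evolution along the dated tree. JC was chosen
  because it gives closed-form expectations — the expected p-distance over
  a path of length $2t$ at rate $\mu$ is $\tfrac34(1 - e^{-\frac43 2t\mu})$
  — which the tests verify directly. Locus lengths are uniform on
  300–800 bp; each locus carries a fixed pair of flanking SSR motifs
  recorded in the truth tables. The default rate (5×10⁻⁴
  substitutions/site/Ma) puts typical pairwise p-distances at the few-percent
  scale observed in congeneric tree species, and keeps orthologous copies
  above the 0.85 clustering identity.
* **Dropout**: each (sample, locus) cell survives with probability
  `plogis(intercept + age_coef * age + herb_coef * is_herbarium)`. The
  default is `age_coef = 0` (recovery unaffected by specimen age — the
  empirical finding for MIGseq herbarium data); non-null settings support
  power studies. One third of simulated specimens are herbarium material
  aged 17–109 years; silica samples are 2–7 years old.
* **Reads**: full-length copies of the locus (amplicons share anchored
  primers). `genomic` mode injects C→T at 5′ offset $i$ with probability
  $p_0 e^{-\lambda_d (i-1)}$ (and G→A mirrored at the 3′ end) before
  uniform sequencing error — the canonical exponential ancient-DNA damage
  profile; `amplicon` mode injects none, matching the damage-free
  expectation for PCR products. Every injected change is recorded in a
  truth table, so damage recovery can be scored event by event.
* **Zones**: the `clade` scheme cuts the dated tree where exactly *k*
  lineages exist and gives each subtree one zone, making intra-zone paths
  stochastically shorter — the structure the divergence analysis is meant
  to detect; the `random` scheme is the matching null.
* **Determinism**: every stage derives its own RNG stream from
  `(master_seed, stage_name)`, so stages can be re-run in any order or in
  isolation with identical results.

What the generator does *not* emulate: indel evolution, selection,
recombination, organellar/nuclear copy differences, PCR duplicates and
primer-site mutation dropout. Passing tests therefore demonstrate the
correctness of the algorithms under the stated models, not robustness to
every artifact of real museum data.

## Assembly model and numerical choices

The heterozygosity/error model treats each site of a depth-≥5 cluster as
heterozygous with probability *h* (two alleles at 50:50) or homozygous,
with per-read miscalls at rate *e* uniform over the three other bases. The
likelihood is a multinomial mixture summed over the 4 homozygous and 6
heterozygous states; because it is symmetric under base permutation, sites
are aggregated by their sorted count patterns before optimization
(Nelder–Mead on the logit scale). Consensus calling takes the
maximum-posterior state per site with priors $(1-h)/4$ and $h/6$; sites
under the depth threshold are called `N`. Allele phasing counts distinct
read haplotypes across the called heterozygous sites (support ≥ 2 reads);
more than `max_alleles` (default 2 — diploids) rejects the cluster as a
collapsed paralog.

Greedy clustering sorts sequences by abundance then lexicographically and
compares against centroids with an ungapped, 5′-anchored identity over the
overlap — appropriate because amplicon reads share primer-anchored ends;
ties are therefore impossible and the procedure is deterministic.
Across-sample members are aligned to their centroid by free-end-gap
alignment (match 1, mismatch −1, gap −2 per position) when lengths differ.

The filter cascade records *non-exclusive* per-reason counts: a locus
removed for several reasons counts under each (for example, a cluster
rejected for low depth can also push its locus below the taxon-occupancy
floor). The report flags this, the invariant `retained + |union removed| =
input` always holds, and re-running the cascade on retained loci removes
nothing. The taxon-occupancy boundary keeps loci found in **at least**
`min_taxa` samples (default 4), configurable for stricter readings.

Group comparisons of per-sample assembly statistics default to the
Mann–Whitney U test (robust for the small, skewed groups typical of
herbarium/silica contrasts; Welch's *t* is available) and report raw
p-values without multiplicity correction, as is conventional for these
descriptive contrasts.

## Damage statistics

The misincorporation profile counts, for offsets 1..25 from each read end,
opportunities (consensus C at a 5′ offset, consensus G at a 3′ offset) and
damage-consistent observations. The terminal test pools offsets 1–3
against offsets ≥ 11 and applies Fisher's exact two-proportion test; the
window boundaries are configurable. Visual inspection of damage plots is
thereby turned into an assertable hypothesis test: clean amplicon data
should reject at the nominal rate only, while genuine terminal deamination
(initial rate ≥ 0.2) rejects essentially always at realistic depths.

## Genomic context

Distances to features follow the `bedtools closest` convention: 0 for any
overlap, otherwise the gap between nearest interval ends, signed positive
downstream. Ties resolve deterministically (smaller feature start, then
class name order). BED input is kept 0-based half-open; GFF3 is converted
at the boundary. "Random locus placement" is operationalized as a
homogeneous Poisson process: inter-midpoint gaps scaled by per-chromosome
density are approximately unit-exponential, and a Kolmogorov–Smirnov test
against Exp(1) rejects both regular and clustered placements. Counts of
loci "near" features depend on an explicit `near_bp` threshold rather than
a hidden default.

## Zone divergence

p-distances exclude sites where either sequence has a gap, `N`, or any
IUPAC ambiguity code, so within-individual heterozygosity is not scored as
between-sample divergence. Records are pooled per (locus, pair) without
per-pair averaging. For the ANOVA, each record contributes one row per zone
involved (an inter-zone record appears under both its zones, mirroring
per-zone histogram panels); the model is `distance ~ type * zone` with
type-II sums of squares, appropriate for the unbalanced pooled records. A
degenerate zero-residual fit falls back to an explicit model-comparison
decomposition rather than failing. Multi-zone species are excluded under
the 2-zone configuration (the continent/island convention); under 4/6
zones a pair is intra-zone when the species share any zone. Note that
pooled records are pseudo-replicated across loci; the permutation null in
the test suite therefore permutes labels at the record level, which is the
exchangeability the F-test can be held to.

## Neighbor joining and bootstrap

The Saitou–Nei algorithm is implemented directly: the Q-criterion selects
each join (ties broken by lowest index pair), two-point formulas give
branch lengths, and negative lengths are clamped to zero with the deficit
moved to the sister branch so path lengths are preserved. NJ is consistent
on additive matrices, which the tests exploit as an exact oracle. The
default binary distance is the mismatch proportion (Jaccard optional); the
bootstrap resamples loci columns with replacement (1000 replicates by
default) and maps bipartition frequencies onto the reference tree.

## Penalized-likelihood dating

Per branch, the realized substitution count $x_b = \ell_b \cdot n_{sites}$
(not rounded; a floor of 10⁻⁹ keeps zero-length terminals finite) is
modeled as Poisson with mean $r_b t_b n_{sites}$, using the continuous
log-Gamma form. The objective is $-\log L + \lambda \Phi$ where $\Phi$
sums squared **log-rate** differences along parent–child branch pairs plus
the variance of the root children's log-rates. Penalizing log-rates makes
the smoothing scale-invariant: the meaning of $\lambda$ does not depend on
the magnitude of the rates, $\lambda \to \infty$ enforces a strict clock at
any realistic rate scale, and the conventional cross-validation grid
(10⁵ down to 10⁻³) spans "clock" to "unsmoothed" uniformly. A raw-rate
penalty at rates of order 10⁻³/site/Ma would need $\lambda$ beyond 10⁷ to
influence the fit at all, which would make the standard grid meaningless.

Ages are parameterized as fractions of the parent age (root boxed by its
calibration), which keeps parent > child feasible throughout bounded
L-BFGS-B optimization with the analytic gradient; internal MRCA
calibrations enter as steep quadratic penalties and are verified on the
returned fit. Fits use one deterministic start — root at the middle of its
calibration box, node fractions from the phylogram's relative depths, a
single clock rate — plus seeded random restarts, keeping a later restart
only when it improves the objective beyond a small tolerance. This start
policy matters: with strict-clock data and only an interval calibration the
likelihood is exactly invariant under rescaling ages against rates, so the
objective is flat along that direction; the deterministic interior start
then pins the reported solution mid-box instead of at an arbitrary
boundary, and users should read the root age as "any value in the
calibration interval fits equally well" in that regime.

Cross-validation is leave-one-terminal-out with the topology kept: the
tip's branch is masked out of the likelihood, the model is refitted, and
the branch's substitution count is predicted from the fitted parent-branch
rate times the fitted attachment-node age. The chi-square score
$\sum (x - \hat x)^2/\hat x$ is summed over tips (tips attached at the root
are skipped). Masking, rather than pruning, keeps the attachment age
estimable and makes the prediction unbiased under a clock; with pruning,
the attachment age is lost and any duration convention biases the score
enough to swamp the λ signal. The reported choice follows the
one-standard-error rule — the smoothest λ whose score lies within one SE
(estimated from the per-tip contributions) of the minimum — because with
the handful of terminals typical here the raw argmin of a nearly flat CV
curve is dominated by Monte-Carlo noise; the raw minimizer is returned as
`lambda_min` for users who prefer it.

## Problem sizes in the test suite

The suite exercises the statistical claims at deliberately modest sizes
chosen to give stable Monte-Carlo verdicts: 100-replicate power checks and
200–500-replicate size checks for the damage and divergence tests, 20
seeded dating simulations with 10 tips and 10⁴ sites, and 20 paired
clock/heterogeneous cross-validations on 8-tip trees. The
`scripts/acceptance.R` driver runs the default 20-species, 50-locus study
end to end.

## Known limitations

* Within- and across-sample clustering is greedy and identity-based; it
  will not reproduce any particular external assembler byte for byte.
* The damage module profiles only the two canonical deamination classes;
  full 12-class profiles and base-quality rescaling are out of scope.
* The ANOVA on pooled records inherits their pseudo-replication; treat the
  distance-type p-value as descriptive when loci per pair are many and
  pair-level signal dominates.
* Dating assumes a rooted binary phylogram with contemporaneous tips; and
  under clock-like data with interval calibrations the absolute timescale
  is identified only up to the calibration box (see above).
* Maximum-likelihood tree search on the SNP matrix is intentionally not
  reimplemented; `extract_snps()` exports PHYLIP/FASTA for external tools.
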