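# tasrdiv

Candidate-gene population genomics for panels of loci resequenced across
many individuals — the setting of taste/nutrient receptor surveys
(*Tas1r*, *Tas2r*, amino-acid and fatty-acid sensor genes) in livestock,
where a few dozen genomes are genotyped at ~20 gene windows and a fifth or
more of the genotypes are missing. The package is aimed at population
geneticists who start from a joint VCF plus a gene annotation and need
region-stratified diversity, selection summaries and differentiation that
remain unbiased under heavy missingness.

What it computes:

* **Windows and site classes** — gene span ± 10 kb flanks, gaps under
  20 kb split at the midpoint between neighbours; every position classed
  as intergenic / exon / intron / 5'UTR / 3'UTR.
* **Nucleotide diversity** robust to missing genotypes: per site
  `pi_i = n_i/(n_i-1) * (1 - sum p_a^2)` over the `n_i` *called* alleles,
  aggregated as ratios of sums per region class (π_t, π_int, π_g, π_e,
  π_i, π_utr, per kb), with SE/95% CI from neutral coalescent replicates
  at `theta = pi * L_eff`.
* **Selection summaries** — codon-level consequence classification,
  Nei–Gojobori synonymous/non-synonymous site counts, π_s, π_a and
  ω = π_a/π_s; McDonald–Kreitman tests against an outgroup.
* **Differentiation** — Hudson `F_ST = 1 - pi_within/pi_total` with
  label-permutation p-values.
* **Structure** — genotype PCA (dosage coding, mean imputation),
  allele-sharing distances, neighbor-joining trees (newick via `ape`).
* **Expression** — Pfaffl efficiency-corrected qPCR normalization with
  multiple reference genes and a calibrator assay.
* **Synthetic studies** — a neutral multi-deme coalescent simulator
  (infinite sites, island/split demographies, transition-biased mutation,
  Bernoulli missingness) that emulates the 77-sample / 21-gene regime and
  provides ground truth for every recovery test.

## Worked example

Simulate a small study (three bitter-receptor-like loci at 2.8 × 10⁻³
diversity per site, two amino-acid-sensor-like loci in the ~55%-missingness
exclusion regime, two fatty-acid-sensor-like loci at 1.2 × 10⁻³; four
populations under island-model structure) and run the full pipeline:

```r
library(tasrdiv)
sim <- study_config(n_genes_per_group = c(bitter = 3L, aminoacid = 2L,
                                          fattyacid = 2L))
sim$flank_bp <- 4000L
sim$populations <- data.frame(population = c("INT", "IB", "ASD", "EUWB"),
                              n = c(10L, 4L, 6L, 6L), is_outgroup = FALSE)
bundle <- run_pipeline(list(simulate = sim, n_perm = 200L,
                            ci_reps = 100L, seed = 42L))
bundle
#> <report_bundle>
#>   genes: 7 ( 2 excluded )
#>   SNPs: 683  ti/tv: 2.576
bundle$diversity_table[, c("gene_id", "group", "pi_t_kb", "pi_g_kb",
                           "omega", "fst", "fst_p")]
#>       gene_id     group pi_t_kb pi_g_kb  omega   fst   fst_p
#> 1    bitter01    bitter    2.77   0.557 0.0804 0.172 0.00498
#> 2    bitter02    bitter    3.34   1.976 2.4980 0.186 0.00498
#> 3    bitter03    bitter    3.84   6.764 1.3233 0.225 0.00498
#> 4 fattyacid01 fattyacid    1.68   2.285 1.0353 0.154 0.00498
#> 5 fattyacid02 fattyacid    1.31   1.068 0.1048 0.162 0.00498
bundle$exclusions
#>       gene_id              reason
#> 1 aminoacid01 missing rate >= 0.5
#> 2 aminoacid02 missing rate >= 0.5
```

Reading the output: the window-wide diversities `pi_t_kb` recover the
configured group contrast (bitter loci ≈ 3 per kb against ≈ 1.5 for the
fatty-acid group), while the genic values `pi_g_kb` scatter widely — a
single ~1 kb CDS under one genealogy is genuinely that noisy, which is why
the companion coalescent CIs matter; both ~55%-missing loci are excluded
from every statistic and listed with the reason; all F_ST values are
significant under 200 permutations (minimum attainable p = 1/201 ≈ 0.005),
as expected under island-model structure; and the transition-biased
mutation model yields ti/tv ≈ 2.6 against a configured expectation of
2.35 (683 SNPs of sampling noise). The full 21-gene regime
(`analysis/01`–`05`) recovers the contrast in genic diversity too:
3.04 / 1.33 / 1.14 per kb for the bitter / amino-acid / fatty-acid
groups, with F_ST between 0.20 and 0.36, every gene significant at 1000
permutations.

The same machinery runs from files:
`run_pipeline(list(vcf = ..., gff = ..., fasta = ..., panel = ...))`.

## Analysis scripts

`analysis/01_simulate_study.R` … `06_expression.R` narrate the default
study regime end to end: simulate and write plain-text fixtures
(VCF/GFF3/FASTA/panel) under `results/study/`, then QC + exclusions,
per-gene diversity, F_ST with 1000 permutations, PCA/NJ structure views
and Pfaffl-normalized expression for a synthetic plate, each writing TSVs
under `results/`. Run them in order from the repository root.

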