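---
title: "Candidate-gene diversity statistics under heavy genotype missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene diversity statistics under heavy genotype missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasrdiv)
```

`tasrdiv` implements the statistical core of a candidate-gene population
genomics workflow of the kind used to survey taste- and nutrient-receptor
loci (the *Tas1r*/*Tas2r* GPCR families and related amino-acid and
fatty-acid sensors) across dozens of resequenced genomes: region-stratified
nucleotide diversity that stays unbiased when a fifth or more of the
genotypes are missing, synonymous/non-synonymous diversity and
$\omega = \pi_a/\pi_s$, Hudson-style $F_{ST}$ with permutation
significance, coalescent-based uncertainty, exploratory structure (PCA,
neighbor-joining), and Pfaffl qPCR normalization for the companion
expression assay. A built-in neutral coalescent simulator generates study
regimes with known truth; it powers both the confidence intervals and the
package's own validation.

## Windows and site classes

Each gene's analysis window is its annotated span extended by a flank
(default 10 kb) on both sides, clamped at chromosome ends. When two genes on
a chromosome are separated by a gap smaller than twice the flank, the
intergenic gap is split at its midpoint and each half assigned to its
neighbour, so windows never overlap. For an odd gap the extra base goes to
the upstream (smaller-coordinate) gene; the annotation never dictates this
and the choice is covered by a unit test. Every window position carries
exactly one class — intergenic, exon (coding), intron, 5'UTR or 3'UTR —
with precedence CDS/exon > UTR > intron inside the gene span, and the class
lengths tile the window exactly (an invariant the tests verify by
exhaustive scans).

Coordinates are 1-based inclusive throughout the package, matching GFF3 and
VCF conventions directly; lengths are `end - start + 1`. Keeping a single
convention end to end removes the most common source of off-by-one errors
in this kind of pipeline. One canonical transcript is used per gene; if
several are annotated, the longest CDS is kept with a warning. Genes on
sequences absent from the assembly FASTA (isolated scaffolds, unplaced
contigs) are skipped with a logged reason rather than analysed.

## The diversity estimator

Shotgun resequencing at modest depth leaves many genotypes uncallable: the
motivating regime has ~20% missing genotypes on average and up to ~50% at
the worst loci. All diversity statistics therefore work with site-specific
sample sizes. At site $i$ with $n_i$ called alleles and sample allele
frequencies $\hat p_a$,

$$\pi_i = \frac{n_i}{n_i - 1}\Big(1 - \sum_a \hat p_a^2\Big),$$

the unbiased expected heterozygosity, identical to the fraction of
mismatching pairs among all $\binom{n_i}{2}$ called pairs. Sites with fewer
than two called alleles are skipped and tallied. Regional values are ratios
of sums — $\sum_i \pi_i$ over the class's variant sites divided by the
class's effective length — rather than means of per-site ratios, which is
the numerically stable choice at high missingness. Without a callability
mask, invariant window positions are assumed callable in all samples (a
logged caveat: a variants-only VCF cannot say otherwise); an optional
per-sample BED-style mask refines both the missingness accounting and the
effective lengths. Per-gene missing rates average over variant positions,
or over all window positions when a mask is supplied. Genes at or above the
exclusion threshold (default 50%) are dropped from all downstream
statistics, mirroring the design regime in which the two worst loci are
removed.

The genic class pools CDS, introns and UTRs; $\pi_{utr}$ pools 5' and 3'
UTRs; $\pi_t$ is computed directly over all window sites rather than as a
length-weighted average of classes.

## Synonymous and non-synonymous sites

Coding SNPs are classified by rebuilding the reference codon (honoring
strand and CDS phase), substituting each ALT allele singly — when a codon
carries two segregating SNPs each is classified with the other held at
reference — and comparing amino acids under the standard genetic code.
Site counts follow Nei–Gojobori: each codon position contributes
(synonymous single-base changes)/3 to $S$ and the remainder to $N$, changes
to a stop count as non-synonymous, and the terminal stop codon is excluded.
$\pi_s = \sum \pi_i / S$ over synonymous SNPs, $\pi_a$ likewise over
non-synonymous SNPs; stop-gain/stop-loss SNPs are tallied separately and
pooled with non-synonymous for $\pi_a$ by default (a switch controls this).
$\omega = \pi_a/\pi_s$ is undefined when a gene has no synonymous
diversity, and is reported as `NA` rather than 0. The classifier is
validated exhaustively against a translate-the-whole-CDS oracle for all 61
sense codons and on thousands of random SNPs on both strands.

## Differentiation

$F_{ST} = 1 - \pi_{iw}/\pi_{it}$, where $\pi_{iw}$ is the mean number of
differences between two sequences from the same population and $\pi_{it}$
the mean over all pairs in the pooled sample (within + between). Both are
ratios of sums over sites, so populations enter weighted by their number of
pairs — the stable choice when sample sizes range from 3 to 31 per
population. A between-pairs-only denominator is available behind a flag for
sensitivity checks. Significance comes from permuting sample-to-population
labels with population sizes preserved; whole columns move together so each
sample's missingness pattern travels with it. The p-value uses the add-one
estimator $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, so it is
never zero. Calibration: two demes fixed for different alleles give exactly
1; under panmixia the mean estimate over hundreds of simulated loci is
within 0.02 of zero and the permutation test holds its nominal 5% size;
under a clean split of depth $\tau$ (in 2N-generation units) the empirical
mean tracks the expectation derived from $E[\text{within}] = \theta$ and
$E[\text{between}] = \theta(1+\tau)$ combined with the pooled-pairs
definition.

## Coalescent machinery

Uncertainty on $\hat\pi$ comes from neutral coalescent replicates at
$\theta = \hat\pi \cdot L_{\mathrm{eff}}$ for the same number of alleles:
the replicate standard deviation is the SE and the 2.5/97.5 percentiles the
95% CI. Time is in units of 2N generations, mutations are Poisson on total
branch length at rate $\theta/2$, placed uniformly at distinct positions
(infinite sites; collisions redrawn) with the derived base drawn from the
three alternatives — optionally transition-biased, where bias $\kappa$
yields an expected ti/tv of $\kappa/2$, so $\kappa = 4.7$ emulates the
mammalian resequencing regime of ti/tv ≈ 2.35. Recombination is
approximated by splitting a locus into independent equal-length fragments
(default 11, standing in for an intermediate recombination rate of R = 10);
this narrows the replicate distribution exactly as averaging independent
loci should, but it is an approximation — no ancestral recombination graph
is simulated. Demographies: panmictic; a clean split (all demes merge at
$\tau$); a symmetric island model with per-lineage migration rate, plus an
optional non-migrating outgroup deme joining at a deeper time. Calibration
tests verify $E[S] = \theta\sum_{i<n} 1/i$ and $E[\pi] = \theta$ to within
2% at 5,000 replicates.

The study-regime generator (`study_config()` + `simulate_study()`) encodes
the conditions the package is designed for: 21 loci in three functional
groups — ten single-exon bitter-receptor-like genes at 2.8 per kb, six
multi-exon amino-acid-sensor-like genes at 1.5, five fatty-acid-sensor-like
genes at 1.2 (the groups' reported diversity contrasts) — 10 kb flanks,
island-model structure over panels of 31/4/14/3/8/6/9 samples plus two
singleton breeds and a two-sample outgroup at $\tau = 2$, 20% genotype
missingness with two amino-acid loci at 55% (the exclusion regime), and
$\kappa = 4.7$. Because the island model stretches coalescence times
(expected pairwise time $d$ within a deme and $d + (d-1)/(2\,mig)$ between
demes of $d$ migrating demes), the generator divides each locus's $\theta$
by the expected pooled pairwise time so that the *observed* pooled
diversity matches the stated per-kb targets. What it does *not* emulate: linkage disequilibrium within
fragments beyond the genealogy, sequencing error, depth-correlated
missingness (missingness is Bernoulli per genotype), selection, and
admixture pulses. Passing recovery tests on these simulations therefore
validates the estimators under neutral structured regimes with random
missingness, not every property of real resequencing data.

## Structure views

PCA uses ALT-dosage coding (0/1/2) of biallelic SNPs, per-SNP mean
imputation of missing genotypes, column centering and an eigendecomposition
of the sample covariance; an optional $\sqrt{p(1-p)}$ standardization is
off by default since the emulated workflow's preprocessing is unspecified.
The distance for trees is allele-sharing identity-by-state,
$d(i,j) = 1 - \overline{\text{shared allele proportion}}$ over mutually
called sites, a stand-in for the external tool the emulated workflow
delegates to. Neighbor-joining is the Saitou–Nei agglomeration with the
standard Q-criterion, deterministic smallest-index tie-breaking and
negative branch lengths clamped to zero with a note; on additive matrices
it reproduces the generating tree exactly (path lengths to 1e-9), and an
independent implementation (`ape::nj`) is used as a cross-check in the
tests, never as the implementation.

## qPCR normalization

Relative expression uses efficiency-corrected quantities
$Q(s,g) = E_g^{-Ct_{s,g}}$ (any per-gene anchoring constant cancels),
normalized per sample by the geometric mean of the reference-gene
quantities, then divided by the mean normalized quantity of the calibrator
gene over its replicates — so the calibrator's mean fold change is exactly
1 and all genes are expressed on the calibrator's scale, preserving
between-gene contrasts. Computation is in log space for numerical
stability. Efficiencies must lie in (1, 2.2]; samples missing a reference
Ct are excluded with a warning; SEMs are computed over normalized fold
changes (the alternative, raw-scale SEMs, is not what error bars on a
fold-change plot mean). Two properties pin the arithmetic down: adding a
constant to every Ct of a sample (equal efficiencies) leaves its fold
changes unchanged, and lowering a target Ct strictly raises its fold
change.

## Numerical and design choices

* Half-called diploid genotypes are treated as fully missing
  (conservative, and testable against the realized missingness rate).
* Multiallelic SNPs are kept; heterozygosity and $F_{ST}$ formulas operate
  on k-allele counts. Indels are dropped with a logged count. PCA and the
  biallelic fast paths drop multiallelic sites with a note.
* Frequencies are computed over called alleles only; a stratum with no
  calls yields `NA`, never 0.
* Permutation and CI replicate counts, seeds and thresholds are explicit
  arguments; every stochastic step derives its stream from the run seed,
  and identical configurations produce byte-identical outputs.
* Problem sizes in the validation suite (replicate counts of 2,000 for the
  missing-data bias check, 5,000 for simulator calibration, 1,000 loci for
  the permutation-size check, 200-400 loci per demography for the $F_{ST}$
  calibration) were chosen so Monte-Carlo error sits a factor of ~3 below
  the corresponding acceptance band.

## Known limitations

The pipeline starts from a joint VCF: it does not call variants, and
without a callability mask it cannot see missingness at invariant sites.
The independent-fragments recombination stand-in underestimates
within-fragment linkage. The MK test uses the outgroup consensus and drops
sites where the ingroup is monomorphic but the outgroup is missing.
STRUCTURE-style admixture inference, HKA tests, Watterson/Tajima statistics
and genome scans are out of scope.
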