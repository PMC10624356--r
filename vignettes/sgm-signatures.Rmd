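---
title: "Stop-gain mutations and SBS signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stop-gain mutations and SBS signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgmsig)
```

## The scientific model

Somatic single-base substitutions (SNVs) arise from mutational processes
with characteristic trinucleotide preferences, summarized as SBS signatures:
probability distributions over the 96 channels formed by a substitution type
(with the mutated base pyrimidine-normalized to C or T) and its immediate
5'/3' context. Because only a handful of sense codons sit one substitution
away from a stop codon, a process whose preferred channels coincide with
those codon contexts will produce an excess of stop-gain mutations (SGMs) —
the most disruptive SNV class, truncating the protein or triggering
nonsense-mediated decay.

Two mechanisms dominate. The serine codons TCA and TCG (the only serine
codons one substitution from a stop) are converted by the APOBEC-class
transversions T[C>G]A, T[C>A]A and T[C>A]G. Glutamic acid codons GAA/GAG are
converted by G>T transversions of their first base; on the pyrimidine
strand these read as T[C>A]N channels spanning **two adjacent codons**,
which is why channel context here is always taken from the genome, not from
codon boundaries. `signature_stop_distribution()` turns any 96-channel
profile plus a coding model into the expected amino-acid distribution of its
truncations; `stop_paths()`/`stop_reachable_codons()` expose the underlying
enumeration (18 of the 61 sense codons are stop-reachable, via 23 paths).

Statistically, the package asks three nested questions:

1. **Class level.** Do SNVs assigned to signature *s* fall in functional
   class *c* more often than expected? One-tailed Fisher's exact test on the
   2×2 co-occurrence table among exonic SNVs; expected counts by Monte
   Carlo: the mean and 2.5/97.5 percentiles of `binomial_iterations`
   draws from Binomial(n, p̂_s·p̂_c), with p̂ the empirical marginal
   fractions. Fold change is observed/expected-mean. BH FDR within one
   cohort × cancer-type family (a `fdr_across_types` switch pools the
   families; the per-type default matches how results are naturally
   reported).
2. **Gene level.** Among exonic SGMs, is a gene's signature fraction higher
   than the exome-wide fraction? One-tailed Fisher per gene and cohort,
   merged across cohorts with Brown's method, BH across genes.
3. **Sample level.** Do SGM burdens track the molecular or lifestyle drivers
   of the process (copy-number loss co-occurrence, YTCA/RTCA motifs,
   expression dichotomization, smoking history, knockout clones)?

## Assumptions

- Standard genetic code (translation table 1); one canonical transcript per
  gene; SNVs only (no indels/MNVs, no splice-site annotation).
- Signature assignment treats SNVs independently given per-sample
  exposures: the posterior for an SNV with channel *t* is proportional to
  `weight(s) * profile_s(t)`.
- Exposure refitting is a deliberately simple stand-in for heavier
  single-sample refitting tools: non-negative least squares of the
  normalized spectrum on the catalog, iteratively pruning signatures below
  1% weight and refitting until the active set is stable, then
  renormalizing. Downstream analyses consume only per-SNV labels, which is
  what this procedure is validated to deliver on synthetic data (exposure
  recovery to mean absolute error < 0.05 at 10,000 SNVs/sample in the test
  suite).

## Tunable parameters

`cohort_config()` surfaces every QC and testing threshold: hypermutator
cutoffs (90,000 SNVs for WGS, 1,800 for WES — about 30 SNVs/Mbp), the
20-SNV WES floor, the 20% artifact-signature fraction (default artifact set
SBS27, SBS43, SBS45–SBS60), 25 samples per consolidated cancer type, 100
SNVs per tested signature, at least one SNV of the tested class, FDR 0.01,
10,000 binomial iterations, 100 probabilistic iterations. QC rules apply in
a fixed order (hypermutators, WES low-count, artifact samples, per-patient
deduplication by highest purity, cancer-type consolidation) and every
removal is logged with its rule.

## The synthetic-data generator

`sim_config()` fixes a cohort completely: gene count and log-normal length
law (codons), codon usage (human-like table by default, uniform available),
intron and minus-strand fractions, sample count, Dirichlet exposure prior,
log-normal SNV burden, driver spikes, copy-number loss rate and WGD
fraction, expression and smoking links, and a mandatory seed. Identical
configurations produce byte-identical outputs; all randomness flows through
the seed (covariates use seed + 1 so they are independent of the mutation
draw but equally reproducible).

Mutations are *placed in sequence context*: each SNV draws its signature
from the sample's exposures, its channel from the signature profile, and
its position uniformly among genomic positions (CDS ± `flank`) whose
pyrimidine-normalized trinucleotide matches the channel. This means
annotation, motif analysis and the genetic-code analyses are exercised
against real sequence constraints — the SGM excess of an APOBEC-like
profile *emerges* from the genome rather than being stamped on.

What the generator does **not** emulate: regional mutation-rate covariates
(replication timing, chromatin), subclonal structure, selection on
passengers, indels, and the scale of a real exome (tens of genes vs ~20,000).
Passing tests therefore demonstrate correctness of the statistical machinery
and of the genetic-code mechanism under the stated generative model, not
robustness to every property of real tumor data.

Two generator regimes deserve comment:

- **Null calibration** uses a flat profile and SNV labels drawn
  independently of everything, the exact null of the class-level test; at
  the simulated table sizes the discrete Fisher p values are close enough to
  continuous for the nominal 5% level to be met within binomial error.
- **Driver recovery** spikes 20 signature-compatible SGMs into one gene of a
  300-sample cohort. Spiked SGMs are drawn into samples proportionally to
  their true signature exposure — a truncating driver generated by a
  mutational process can only appear in genomes where that process is
  active — and the cohort uses a sparse Dirichlet(0.25) exposure prior with
  ~1–2 background signature SGMs expected per gene, the regime in which
  published driver genes stand out (tens of signature SGMs against an
  expectation near one).

## Numerical choices and conventions

- Channel order is the catalog convention: substitution type (C>A, C>G,
  C>T, T>A, T>C, T>G), then the trinucleotide alphabetically. Purine
  references are reverse-complemented, flanks swapping and complementing.
- Profiles must sum to 1 (tolerance 1e-9 for analysis profiles; catalog
  columns are accepted within 1e-3 and renormalized).
- `stop_paths()` orders deterministically by position then alternate base;
  ties in `assign_top()` go to the alphabetically smallest signature name;
  zero posterior mass yields `"unassigned"`, and unassigned SNVs are
  excluded from signature-conditional tables but retained in totals.
- An SNV covered by several genes is annotated to the alphabetically first
  gene. Start-loss (any non-synonymous change in codon 1) takes precedence
  over missense, as does stop-loss in the terminal codon.
- Quadnucleotide motifs are read on the strand where the mutated base is C;
  mutations whose pyrimidine-normalized reference is T are classed `other`
  (the motif is an APOBEC construct and applies to cytosine targets);
  missing flanks give `not_applicable`.
- Probabilistic replication derives iteration seeds as `seed + i`, so runs
  are bit-reproducible and iterations are distinguishable.
- Brown's method uses the empirical covariance of −2 log p across genes
  tested in every cohort; negative covariance estimates are clamped at zero
  (correlation may only penalize significance), and with fewer than 20
  complete genes the method falls back to Fisher's with a warning. A single
  p value is returned unchanged.
- Median dichotomization sends ties to the low-expression group; positional
  skew with all positions exactly at the protein midpoint returns p = 1;
  copy number without any qualifying segment (≥ 1,000 bp overlap) is treated
  as "no CNA data", and the loss call defaults to `FALSE`.
- The knockout test fits negative-binomial models with per-fit dispersion;
  when the NB fit fails to converge (Poisson limit), the Poisson LRT is
  used and flagged in the result.
- On chromosome X with unknown sex, loss calls fall back to the autosome
  thresholds with a warning.

## Open design points, resolved

- The gene-level 2×2 can be read two ways from the observed/expected logic;
  the default conditions on SGMs ({gene vs exome} × {signature vs other}),
  which reproduces expected counts of the form gene-SGM-count ×
  exome-wide-signature-fraction. The all-mutations conditioning
  ({SGM vs non-SGM} among the signature's mutations) is available via
  `gene_test(conditioning = "all_mutations")`.
- The amino-acid propensity of `signature_stop_distribution()` conditions
  uniformly on CDS positions; it does not weight genes by their mutation
  rates. This is the cleanest statement of the genetic-code mechanism and is
  documented rather than configurable.
- Precomputed exposures can be supplied directly to `assign_top()` /
  `sample_assignments()` to bypass `fit_exposures()` when consensus
  exposures exist.

## Problem sizes used in validation

The test suite validates on desk-scale cohorts: 200 null cohorts of 20
samples (~3,000 SNVs each) for calibration; a 60-sample, ~18,000-SNV cohort
for mechanism recovery; 20 replicates of a 300-sample, ~9,000-SNV cohort
over 200 genes for driver recovery; 20 samples at 10,000 SNVs each for
exposure recovery. Fisher tests are checked against exhaustive
hypergeometric enumeration on all small tables and a random sweep of tables
up to total 60; BH against the textbook step-up computation.

## Known limitations

- No de novo signature extraction (NMF) and no indel/doublet signatures.
- The refitting stand-in can split weight between near-collinear profiles;
  with the well-separated synthetic catalog this is immaterial, but with a
  full COSMIC catalog users should expect the usual identifiability caveats
  of single-sample refitting.
- Pathway-level integration of gene results and protein-domain
  visualization are out of scope.
- TCGA-style relative copy-number calls are taken in the units of the input
  file (loss below 0); no unit conversion is attempted.
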