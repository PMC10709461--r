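---
title: "Methods: gene flow across recombination categories of a genome"
author: "periflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene flow across recombination categories of a genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periflow)
```

## The scientific question

Hybridising plant species such as the campions *Silene latifolia* and
*S. dioica* exchange genes where recombination permits introgressed
fragments to unlink from locally deleterious alleles. Chromosome-scale
pericentromeric recombination suppression — on the *S. latifolia* X, a
rarely-recombining block (`Xpr`) covering roughly 90% of the chromosome —
should therefore act as a barrier to interspecific gene flow, and could
by itself explain a "large X effect" in reproductive isolation. The
package implements the comparative machinery this hypothesis needs:
per-gene polymorphism and divergence statistics contrasted across four
gene categories (`freqA`, `rareA`, `freqX`, `rareX`: autosomal or
X-linked crossed with frequently or rarely recombining), demographic
inference of category-specific gene flow from joint site-frequency
spectra, and gene-expression divergence tabulation. A
structured-coalescent simulator generates complete synthetic datasets
with the same statistical structure, so every stage of the analysis runs
and is tested without access to the original RNA-seq data.

## Data model

A gene is a `hap_alignment`: a matrix of haplotype rows over
`{A,C,G,T,N,-}` in which each diploid sample owns two rows and every row
belongs to one of two species. Gaps are treated as missing data. The
real pipeline this mirrors derives such alignments from a multi-sample
VCF against reference CDS sequences; `vcf_to_pseudohaplotypes()`
performs that conversion, splitting heterozygous genotypes into
pseudo-haplotypes either at random (seed recorded) or REF-first. The
convention ProSeq-style tools use when emitting FASTA from VCF is not
standardised, so random splitting is the default and the rule is stored
with the output. Statistics that are functions of allele frequencies
(π, Tajima's D, Fst, Dxy, the SFS) are insensitive to the phasing rule;
only ZnS (a haplotype-LD statistic) depends on it, which is why the rule
is explicit and reproducible.

## Site classes

Within each CDS-aligned gene, `classify_codon_sites()` marks fourfold
degenerate third positions (the most nearly neutral sites available)
and the first two codon positions (the least neutral). A third position
counts as fourfold only when every row without missing data in the
codon carries a first-two-base context from a fourfold family of the
standard code; a polymorphism at positions 1–2 that changes the family
disqualifies the site. This unanimity rule is a design decision — the
alternative (classify per row and average) lets a site change class
between species, which would make the X/autosome contrasts
incommensurable. Columns of incomplete terminal codons belong to the
`all` class only. All statistics use complete deletion within a gene:
columns containing any `N` or `-` are dropped, and the retained count is
reported per record.

## Polymorphism and divergence statistics

Five statistics are computed per gene (`per_gene_stats()`), each on the
site classes the comparative analysis uses: π and Tajima's D per species
on fourfold and first-two classes, and Fst, Dxy, ZnS on all sites.

* π — mean per-site mismatch over all haplotype pairs, identical to the
  sample-size-corrected form `n/(n-1) (1 - Σ p²)`.
* Tajima's D — `(π_total - S/a1) / sqrt(e1 S + e2 S(S-1))` with the
  standard constants; undefined when no site segregates (flagged, and
  excluded listwise from group tests with counts logged).
* Dxy — mean per-site mismatch over between-species pairs.
* Fst — `1 - mean(π_within) / Dxy`. The Hudson/Nei family was chosen
  because the source framework cites the classic molecular-evolution
  formulation without naming an estimator; the ratio form is the one a
  per-gene analysis can compute stably, and it is recorded as
  configurable. Undefined when Dxy = 0.
* ZnS — mean squared allelic correlation r² over all pairs of biallelic
  segregating sites, computed on haplotypes; all biallelic sites enter
  (no frequency cutoff, another unstated upstream choice made explicit
  here).

For X-versus-autosome comparisons of π the autosomal values can be
scaled to 75% (`adjust_autosomal_pi()`), reflecting the X's
three-quarter effective population size; both raw and adjusted tables
are produced.

## Joint SFS and demographic models

`build_joint_sfs()` counts biallelic segregating sites into an
(n₁+1)×(n₂+1) matrix; sites with missing rows are projected to the
target sample sizes by hypergeometric expectation and sites below the
target are skipped and logged. Without an outgroup the spectra are
folded (minor-allele orientation); the synthetic data carry their
ancestral sequences, so unfolded spectra are available for method
checks. Per-gene spectra are summed within a gene category — a
composite likelihood over sites that is exact for free recombination
between genes and no recombination within, which is precisely what the
generator simulates.

Five isolation-with-migration models are fitted (`optimize_model()`):
`split_mig` (constant sizes, symmetric migration, k = 4), `IM`
(exponential size change since the split, symmetric migration, k = 5),
`IM2` (direction-specific migration, k = 6), and the heterogeneous
mixtures `IM_2M` (k = 7) and `IM2_2M` (k = 9) in which a proportion P of
sites migrates at class-A rates and the rest at class-B rates, with a
single mutation scale θ shared by the two classes (the mixture is over
expected spectra, matching the Poisson-random-field framework; whether θ
was shared upstream is unstated, and sharing is the choice consistent
with a latent class assignment of sites). Units: sizes in multiples of
the ancestral size N_A, time in 2·N_A generations, migration in 2·N_A·m.
Deme sizes interpolate exponentially from (s, 1−s) at the split to
(N1, N2) at present.

### Expected spectra by Monte-Carlo structured coalescent

The expected branch-length spectrum is computed by simulating the
structured coalescent backward in time (compiled code): coalescence at
rate C(k,2)/ν_deme(t), backward migration at rate M/2 per lineage, a
panmictic ancestral deme of size 1 beyond T. Event times are sampled by
thinning, with the majorant refreshed on a short horizon so that
exponentially shrinking demes do not make the bound hopeless. Each
branch adds its length to the spectrum cell indexed by its species-wise
descendant counts. A diffusion solver is the classical alternative; the
Monte-Carlo engine was adopted because it is exact for these models
(no grid, no extrapolation), shares code with the data generator, and
its accuracy is a single knob (`n_reps`). The engine is validated
against closed-form neutral theory: at T = 0 and constant size the
pooled marginal spectrum obeys E[ξ_k] ∝ 1/k, and mean Tajima's D over
thousands of simulated neutral genes is near zero (both are asserted in
the test suite).

Two consequences of a Monte-Carlo likelihood surface shape the
optimisation design. First, likelihood evaluations within one
optimisation share an engine seed (common random numbers), making each
run's surface deterministic. Second, parameters maximising a
low-replicate surface carry an O(1/n_reps) noise-induced bias, so
reported log-likelihoods are re-evaluated at a high replicate count
(`final_reps`), and the recommended protocol polishes the incumbent on a
high-replicate surface before interpreting estimates.

### Optimisation protocol

Fitting follows a two-stage multi-start protocol: wide log-uniform
ranges (sizes up to 100, times up to 5, migration up to 10), a
first stage of runs from the best points of a cheap likelihood screen of
those ranges, then a second stage with ranges tightened by a factor of 3
around the best first-stage optima (the upstream protocol "adjusted"
ranges by hand; a factor of 3 around the top three candidates is the
automated counterpart). Each run is Nelder–Mead on log-transformed
(logit for s, P) parameters; after both stages the incumbent is
restarted until it stops improving, because a capped Nelder–Mead run
ends with a shrunken simplex that a fresh restart escapes. θ never
enters the search: its Poisson optimum Σobs/ΣE is profiled out
analytically.

Model support is compared with AIC (`2k − 2lnL`), ΔAIC and relative
likelihoods `exp(−ΔAIC/2)`; nested pairs are compared with
likelihood-ratio tests. For the focal IM2 vs IM2_2M comparison,
`lrt_heterogeneity()` fits both models on the same surface and
alternates refinement — the richer model starts from embeddings of the
null optimum (class rates equal, then split by factors 3 and 10), the
null is refitted from the P-weighted projection of the heterogeneous
optimum — until neither improves. Without this alternation the
statistic reflects whichever model's optimiser happened to fail, not
heterogeneity; with it, the test is well calibrated against χ²(3) in the
regime the tests exercise (a few thousand sites), and detection of a
10-fold migration contrast is essentially certain.

Bootstrap confidence intervals are M ± 1.96·SD over replicate refits
(genes resampled with replacement for data spectra, or parametric
Poisson redraws for spectrum-level experiments). Replicate refits use
dispersed starts around the point estimate and a fresh engine seed per
replicate, so the SD honestly includes the Monte-Carlo component of the
estimator's variance; anchored refits would understate it.

## Group comparisons and expression divergence

Category comparisons use the Kruskal–Wallis test and pairwise Wilcoxon
rank-sum tests (normal approximation with tie correction) summarised by
a compact letter display computed by insert-and-absorb, so two
categories share a letter exactly when their pairwise test is not
significant at α = 0.05. No multiplicity correction is applied by
default — the letter-grouping convention being mirrored reports plain
pairwise tests — but Holm adjustment is available.

Expression divergence takes FPKM matrices as given (no count modelling):
a Welch two-sample t-test per gene ("t-test" upstream is otherwise
unspecified; unequal variances are the safe default), significance at
P < 10⁻⁴, tabulated as counts and percentages per category with squared
Pearson correlations of species-mean FPKM per {freq, rare, all} ×
{X, A, all} cell, and pairwise chi-square tests (no continuity
correction, df = 1) between category proportions. Note one known
discrepancy documented rather than forced: the published chi-square for
the freqA-vs-rareA proportion comparison (3.595) is not recovered from
the published counts by either the plain (4.23) or the Yates-corrected
(3.99) statistic; the package reports what the counts imply.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 12 diploids per
species; four gene categories with counts 2009/1909/209/398; per-category
IM2_2M demographies anchored to the study's best-fit estimates, with the
low-migration class fraction P = 0.55 in rarely recombining categories
and 0.30 in frequently recombining ones; genes of 300 codons (a typical
plant CDS); codon-structured mutation in which positions 1–2 mutate at
0.15 times the third-position rate, emulating purifying selection; and
log-normal FPKM with a species shift of 1.2 natural-log units planted in
7.2–10% of genes per category (the study's observed proportions). The
planted fraction is the generator's ground truth; at 12 samples per
species and this shift size the strict per-gene test detects roughly
half to two-thirds of the planted genes with essentially no false
positives, so the *detected* percentages in a synthetic run sit below
the planted ones — the truth record exists precisely so tests can
separate the two.

The mutation scales θ (per third-position site) are calibrated once,
analytically, to the emulated diversity levels: the target median
fourfold π is 0.033 (freqA) and 0.011 (rareA), with X categories at 75%
of the corresponding autosomal target to reflect their three-quarter
effective size, and θ = target / E[within-species pairwise coalescence
time] under each category's demography (the expectation computed from
the engine at high replicates). The frozen defaults are
`r paste(names(default_thetas()), signif(default_thetas(), 3), sep = " = ", collapse = ", ")`.
Applying the 75% factor to θ directly instead would invert the
X/autosome diversity ordering, because the fitted X demographies have
longer internal coalescence times in their own N_A units.

What the generator deliberately does not emulate: linked selection
(diversity differences between categories enter through θ, not through
sweeps or background selection), intragenic recombination, sequencing
error and missing data, expression count noise, or any correlation
between a gene's sequence diversity and its expression divergence.
Passing tests therefore demonstrate that the estimators, the inference
machinery and the comparative logic are correct under the assumed
statistical structure — not that the biological conclusions would
survive features of real data the generator omits.

## Problem sizes used by the tests and the acceptance script

Scales were chosen so the whole suite exercises every claim at useful
power: estimator oracles run on 100 random alignments; engine
calibration uses 20,000 genealogies and 2,000 neutral genes; parameter
recovery fits a 12×12 spectrum of ≈20,000 sites with the 10+30-run
protocol and 12 parametric-bootstrap refits; heterogeneity detection
uses 8 replicate pairs of 8×8 spectra of ≈3,000 sites (the dataset size
at which the composite likelihood's Monte-Carlo approximation error sits
below the Poisson noise floor, where the χ² reference is honest); the
end-to-end ordering check simulates 1,600 genes per seed for three
seeds. The acceptance script runs the full pipeline at half the study's
gene counts. The deliberately reduced replicate counts (8 rather than
20; 12 bootstrap refits rather than 100) trade statistical resolution of
the *test assertions* for runtime; the package defaults keep the full
protocol (10+30 runs, 100 bootstrap replicates).

## Known limitations

* The Monte-Carlo likelihood surface limits how small a log-likelihood
  difference can be interpreted; ΔlnL below a few units is within engine
  noise at the default `n_reps`.
* `split_mig` is not strictly nested in `IM` (the exponential family
  only contains constant trajectories when N1 + N2 = 1), so the
  monotonicity of likelihoods along that edge of the model chain is
  empirical, not guaranteed.
* The composite likelihood ignores linkage within genes; with strong
  intragenic LD the LRT is anticonservative on real data, the classical
  caveat for Poisson-random-field inference. Gene bootstrap CIs are the
  mitigation.
* Compact-letter displays depend on the unadjusted pairwise α; with
  many categories the display can be non-unique, though the
  insert-and-absorb construction is deterministic here.
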