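# periflow

Population-genetic analysis of whether pericentromeric recombination
suppression restricts interspecific gene flow — the mechanism proposed to
explain the "large X effect" in hybridising campions (*Silene latifolia*
× *S. dioica*), where a rarely-recombining pericentromeric block spans
~90% of the X chromosome.

The package implements the three analysis layers such a study needs, and
a coalescent simulator that generates complete synthetic datasets with
the assumed statistical structure, so everything runs and is tested
without the original sequencing data:

* **Per-gene polymorphism and divergence** over codon-aware site classes
  (all sites, fourfold-degenerate third positions, first two codon
  positions): nucleotide diversity π, Tajima's D, Hudson-type
  F<sub>ST</sub> = 1 − π<sub>w</sub>/D<sub>xy</sub>, D<sub>xy</sub>, and
  Kelly's Z<sub>nS</sub> (mean r² over pairs of biallelic sites),
  compared across the four gene categories freqA / rareA / freqX / rareX
  (autosome or X × frequently or rarely recombining) with
  Kruskal–Wallis and pairwise Wilcoxon tests summarised as compact
  letter displays, including the 0.75 ploidy adjustment of autosomal π.
* **Demographic inference** from joint site-frequency spectra under five
  isolation-with-migration models — `split_mig`, `IM`, `IM2`
  (direction-specific migration M₁, M₂) and the heterogeneous-migration
  mixtures `IM_2M`, `IM2_2M` (a proportion P of sites migrating at
  class-A rates, the rest at class-B rates) — by Poisson composite
  likelihood over a Monte-Carlo structured-coalescent expected spectrum,
  with the 10+30-run two-stage search protocol, AIC / relative
  likelihood model selection, nested likelihood-ratio tests
  (`lrt_heterogeneity()` for the focal IM2 vs IM2_2M comparison) and
  bootstrap confidence intervals M ± 1.96·SD.
* **Expression divergence**: per-gene Welch t-tests on FPKM at
  P < 10⁻⁴, per-category counts, percentages and r² of species-mean
  expression, with pairwise chi-square comparisons of proportions.

## Worked example

Simulate a small dataset under the study conditions (12 diploids per
species; per-category IM2_2M demographies with post-split growth and a
low-migration site class covering P ≈ 0.55 of rarely-recombining genes),
then compare diversity across categories:

```r
library(periflow)

cfg <- sim_config(genes_per_category = c(freqA = 150, rareA = 150,
                                         freqX = 80, rareX = 80),
                  n_codons = 150, seed = 42)
d <- simulate_dataset(cfg)
stats <- stats_table(d$alignments, d$categories)
compare_categories(stats, "pi_1", "fourfold")
```

```
<group_comparison> pi_1 - Kruskal-Wallis H = 210.5 , p = 2.29e-45 
  group   n   median letters
1 freqA 150 0.026030       a
2 rareA 150 0.009897       b
3 freqX  80 0.021720       c
4 rareX  80 0.006664       d
```

Rarely-recombining genes hold a fraction of the diversity of
frequently-recombining ones (medians 0.0099 vs 0.0260 on autosomes), and
the rarely-recombining X is lowest of all — the letters mark groups that
all differ in pairwise rank-sum tests at α = 0.05. Fitting the nested
migration models to the rareA joint spectrum then asks whether gene flow
is heterogeneous across sites:

```r
sfs <- build_joint_sfs(d$alignments[d$categories$category == "rareA"],
                       12, 12, fold = TRUE)
het <- lrt_heterogeneity(sfs, seed = 1)
het$p                       # ~0: two migration classes strongly supported
het$fit_alt$params          # includes the class-A fraction P
```

On a half-scale dataset the heterogeneous model wins with
2ΔlnL ≈ 2294 (p ≈ 0) and recovers the class-A fraction P̂ ≈ 0.54
against a configured 0.55.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (simulate → per-gene statistics and category
comparisons → spectra and demographic fits → expression divergence),
writing their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1 --scale 0.25 --out results/data
Rscript analysis/02_popgen_stats.R --data results/data --out results
Rscript analysis/03_demography.R --data results/data --out results
Rscript analysis/04_expression.R --data results/data --out results
```

`vignettes/periflow-methods.Rmd` documents the models, estimator
conventions, optimisation protocol, generator calibration and known
limitations.

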