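---
title: "Composite selection-signature scanning with dcmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection-signature scanning with dcmscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmscan)
```

## The problem

Artificial selection in a closed livestock herd — for milk yield, coat
colour, disease resistance — leaves localized footprints in the genome:
reduced nucleotide diversity, skewed allele-frequency spectra, long
stretches of haplotype homozygosity, and allele-frequency differentiation
between herd strata. No single statistic captures all of these, and the
statistics are correlated with one another, so naive combination
double-counts shared information. `dcmscan` implements a composite scan for
medium-density SNP-array data from a single population: five univariate
statistics are computed per SNP, converted to rank-based p-values, and
combined into the De-correlated Composite of Multiple Selection Signals
(DCMS), which weights each statistic by the inverse of its summed absolute
correlation with all five.

## The model and its assumptions

For locus $l$ and statistic $t$ with rank p-value $p_{lt}$,

$$\mathrm{DCMS}_l = \sum_{t=1}^{5} w_t\,
  \log\!\frac{1 - p_{lt}}{p_{lt}},\qquad
  w_t = \frac{1}{\sum_{i=1}^{5} |r_{it}|},$$

where $r_{it}$ is the genome-wide correlation between statistics $i$ and
$t$. A statistic strongly correlated with the others receives a small
weight, so five copies of the same signal count once ($|r_{it}| \equiv 1$
collapses the sum to the mean logit), while an uncorrelated statistic
contributes its full logit. The five statistics and their tails:

| statistic | captures | tail under selection |
|---|---|---|
| Weir–Cockerham FST (founder vs farm-born) | stratum differentiation | right |
| Garud H1 (14-SNP windows, step 1) | hard-sweep haplotype homozygosity | right |
| Garud H12 | hard + soft sweep homozygosity | right |
| Tajima's D (non-overlapping bins) | frequency-spectrum skew | left |
| per-site nucleotide diversity $\pi$ | diversity trough | left |

Assumptions worth stating: genotypes are phased and biallelic; the two
strata used for FST partition one homogeneous population (FST here measures
drift between herd generations, not divergent breeds); and the genome-wide
empirical distribution of each statistic is dominated by neutral loci, so
fractional ranks behave like null p-values away from true sweeps.

## Pipeline and parameters

`run_scan()` executes, in fixed order: variant QC → per-chromosome
statistics → running-median smoothing → fractional-rank p-values → robust
correlation → DCMS → robust normal fit → upper-tail p → Benjamini–Hochberg
q. The defaults are the package's study conditions:

* **QC** (`qc_config()`): call rate ≥ 0.95, MAF ≥ 0.05, Hardy–Weinberg
  exact-test p ≥ 0.001, duplicate positions removed, in that order, so
  per-filter counts are reproducible. The HWE test is the exact conditional
  test (two-sided by probability mass), computed on all samples. Pairwise
  relatedness pruning (`pihat_matrix()` + `exclude_related()`, PI_HAT >
  0.1, greedy hub-first removal with id tie-break) is provided as an
  explicit step rather than wired into `run_scan()`: in a small-Ne herd
  background relatedness is pervasive — on the default simulations the 0.1
  rule discards most of the sample — so sample pruning is a decision the
  analyst applies to real pedigreed data, not an unconditional stage.
* **Windows** (`window_config()`): H1/H12 use 14-SNP windows with step 1,
  the window value assigned to the SNP at 0-based offset 7 (centred
  assignment; the convention choice only shifts tracks by half a window).
  Haplotypes with any missing allele in a window are excluded from the
  frequency counts rather than imputed. Tajima's D uses non-overlapping
  300 kb bins; the bin width is configurable because array densities vary
  (at the simulated 25 kb spacing a 300 kb bin holds ~12 SNPs, enough for a
  stable segregating-site count without erasing locality). Bins with no
  segregating site are set to 0, the pipeline-wide convention that missing
  statistic values become 0 before ranking.
* **Smoothing**: `stats::runmed(k = 31, endrule = "constant")` per
  chromosome, applied uniformly to all five raw tracks for coherence
  (configurable per statistic). The constant end rule copies the nearest
  fully-windowed median into the first/last 15 positions.
* **DCMS** (`pipeline_config()$dcms`): the correlation matrix is estimated
  on the smoothed statistic values (the inputs actually combined) by the
  Minimum Covariance Determinant with subset fraction `alpha = 0.75` and
  `nsamp = 50000` candidate subsets, seeded; a singular best subset falls
  back to the classical correlation with a warning. The composite is fitted
  with an intercept-only Huber M-estimate (c = 1.345, tolerance 1e-8) and
  MAD scale — resistant to the right tail the scan is looking for — and
  upper-tail normal p-values are BH-adjusted into q-values. Storey-type
  q-values are deliberately not the default; BH is the named correction.
* **Regions** (`region_config()`): a region is a maximal run of SNPs with
  q ≤ 0.1 containing at least `core_min = 2` consecutive SNPs with
  q < 0.05. The boundary SNP (first with q > 0.1) is exclusive. `core_min`
  can be lowered to 1 to admit single-SNP peaks. Region length is the
  member-SNP span; a single region reports SD 0.
* **Enrichment**: per (trait, chromosome), the observed annotated-QTL count
  is compared with `n_iter = 1000` draws (with replacement) of equally many
  records from the database restricted to the same chromosome; the
  empirical p is add-one smoothed and BH-adjusted across pairs.

One global seed drives everything: each stochastic stage derives its seed
as `(seed + 999983 k) mod (2^31 - 1)` (`derive_seed()`), so a stage rerun
in isolation reproduces the full-run result, and repeated runs are
byte-identical.

## The synthetic-data generator

No genotype archive accompanies this pipeline, so `simulate_population()`
generates study data with the structure the scan assumes: 200 breeding
diploids, 3 chromosomes × 2,000 SNPs at 25 kb spacing, founder allele
frequencies drawn from Beta(0.5, 0.5) truncated to [0.05, 0.95] (the
U-shape of array ascertainment, kept clear of the MAF filter), 200
generations of neutral Wright–Fisher burn-in building drift and LD
(crossover probability 1e-3 per adjacent-SNP interval, free recombination
between chromosomes), then a beneficial allele planted at 5% standing
frequency and selected with additive viabilities 1, 1+s, 1+2s (default
s = 0.05) for 150 generations; 150 diploids are sampled at the end. A
replicate that loses the beneficial allele restarts with an incremented
seed. `split_subpopulations()` freezes 25% of samples as founders and
replaces the rest with descendants after 10 further neutral generations —
ten herd generations is a plausible gap between foundation animals and
current farm-born stock, and produces mean FST of a few percent. The
per-generation reproduction step is compiled (Rcpp) with crossovers drawn
by geometric skipping, so a full replicate simulates in about a second.

What the generator does *not* emulate: new mutations (standing variation
only, keeping sites biallelic), genotyping error, realistic cattle
demography or recombination maps, and soft sweeps from recurrent origins.
Passing tests on these simulations therefore show the pipeline's internal
correctness and calibration under drift + one hard sweep; they do not show
power on any particular real dataset.

## Detectability at the default study conditions

Two empirical findings from the package's own calibration runs deserve
emphasis, because they are properties of the method at these conditions,
not defects:

1. **Drift mimics sweeps.** With Ne = 200 and a founder bottleneck, the
   neutral genome contains diversity troughs and haplotype-homozygosity
   plateaus that the composite legitimately flags: across neutral
   replicates roughly a third produce at least one called region (the mean
   fraction of SNPs at q < 0.05 stays well below 5%). The rank-based
   p-values are relative measures within the genome scanned; BH on them
   does not control a frequentist region-level error rate.
2. **A weak hard sweep is usually invisible after MAF filtering.** At
   s = 0.05 (2Ns = 20) the sweep fixes in most conditioned replicates; the
   hitchhiked core then fails the MAF ≥ 0.05 filter and drops out of the
   scan, while the surviving nearby SNPs are exactly the recombination-
   rescued ones carrying little homozygosity signal. The footprint that
   remains (~±300 kb at r = 1e-3 per interval) is narrower than a 14-SNP
   window at post-QC density, and is diluted further by k = 31 smoothing.
   The sweep's H12/π footprint is plain in the *pre-QC* haplotypes (the
   simulator invariants verify it), but the called regions of the post-QC
   composite rank drift peaks above it in most replicates. Detecting weak
   sweeps in small populations needs denser markers, larger Ne, or
   statistics robust to the MAF ascertainment — a real limitation of this
   class of scan worth knowing before interpreting region lists.

## Numerical choices and degenerate inputs

* FST estimates below 0 are clamped to 0; SNPs monomorphic across both
  strata are missing (then 0 after imputation). Both subpopulations need
  ≥ 2 genotyped samples at a SNP.
* Fractional ranks are bounded in $[1/(n+1), n/(n+1)]$, so every logit is
  finite by construction; `dcms_combine()` refuses p-values outside (0, 1).
* `robust_normal_fit()` errors on zero spread (MAD 0) rather than
  returning a degenerate fit; `tajimas_d()` requires ≥ 4 haplotypes.
* Chromosomes shorter than a window (H) or a smoother width (runmed) fall
  back to missing values or the largest odd width that fits, respectively.
* Chromosome order is natural-numeric where parseable, lexicographic
  otherwise; ties in greedy relatedness pruning break by sample id; region
  ranking ties break by peak DCMS.

## Known limitations

Single-population, biallelic, autosomal scans only; no iHS/XP-EHH-style
haplotype-length statistics; no genetic-map-aware windows; the enrichment
null samples database records (not genomic positions), which conditions on
the database's interval-length distribution; and the generator's additive
single-locus selection cannot produce polygenic or soft-sweep architectures.
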