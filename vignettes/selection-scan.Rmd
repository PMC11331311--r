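---
title: "Composite selection scans in two-population genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection scans in two-population genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmscan)
```

## The problem

Artificial selection leaves several distinct footprints in a livestock
genome: long runs of homozygosity (ROH) shared by many animals, unusually
long haplotypes around a high-frequency allele (detected by EHH-based
statistics within a breed, iHS, or between breeds, XP-EHH), and strong
allele-frequency differentiation between breeds (per-SNP FST). No single
statistic is sensitive to all sweep configurations, so `dcmscan` combines
them into a *decorrelated composite of multiple signals* (DCMS), assigns
empirical p-values and Benjamini–Hochberg q-values, and merges significant
SNPs into candidate regions annotated with overlapping genes.

The package provides the whole chain for two phased populations, plus a
synthetic-data generator with truth tables, so every stage can be exercised
and benchmarked without access to restricted livestock datasets.

## The statistics

**Autozygosity.** ROH are called per individual with a sliding-window
screen: a window of `window_snp` consecutive SNPs (default 100, suited to
sequence-density data) counts as homozygous when it contains at most 1
heterozygote and 5 missing calls; a SNP is eligible when at least 5% of the
full windows overlapping it are homozygous; maximal eligible runs are split
at gaps above 1000 kb and kept when they have ≥ 100 SNPs, ≥ 1000 kb, and at
most 50 kb per SNP. The autozygosity track is the proportion of individuals
whose ROH cover each SNP.

**EHH, iHS, XP-EHH.** EHH at distance *d* from a core SNP is the
probability that two random carrier haplotypes of a core allele are
identical over the interval from the core to *d*. iHH integrates EHH over
genetic distance outward from the core (trapezoid rule), truncated where
EHH falls below 0.05 (linearly interpolated crossing); SNPs whose EHH fails
to decay before a chromosome end are flagged invalid and excluded from
standardization, because they would otherwise bias the bin dispersions.
iHS is `ln(iHH_ancestral / iHH_derived)`, standardized to mean 0 / SD 1
within equal-width derived-allele-frequency bins. XP-EHH integrates the
all-haplotype EHH of each population to a *common* boundary — the point
where the EHH of the pooled haplotypes of both populations drops below the
cutoff — and standardizes `ln(iHH_A / iHH_B)` genome-wide. The pooled-EHH
stopping rule is what gives XP-EHH its power: a population carrying a long
swept haplotype keeps accumulating homozygosity while the other decays.
Genetic distance defaults to a linear 1 cM/Mb map; a per-SNP map can be
supplied on the panel.

**FST.** Per SNP, with baseline `p̄ = (p1 + p2)/2`, the statistic is
`(p1 − p̄)² / (p̄ (1 − p̄))`. With two equally weighted populations the
numerator is the same computed from either breed. Sites with a monomorphic
baseline are masked rather than zero-filled so that rank-based p-values
downstream are not flooded with ties at an arbitrary value.

**DCMS.** Each track is converted to right-tailed p-values by fractional
ranks, `p = 1 − (rank − 0.5)/n`, which keeps p strictly inside (0, 1) — the
composite's `log((1 − p)/p)` terms diverge at 0 and 1. The composite is

DCMS_l = Σ_t w_t · log((1 − p_lt)/p_lt),  w_t = 1 / Σ_i |r_it|,

with `r` the Pearson correlation matrix of the tracks. The absolute value
in the weight denominator guards against signed correlations cancelling to
non-positive sums; since a duplicated (perfectly correlated) signal halves
its weights, adding redundant statistics does not inflate the composite.
Composite p-values come from the upper tail of a normal fitted with the
empirical mean and SD of the DCMS vector itself, q-values from
Benjamini–Hochberg, and SNPs with q < 0.05 are chained into regions when
consecutive significant SNPs lie strictly less than 1 Mb apart. Gene
annotation requires at least one shared base pair with a region (1-based
inclusive coordinates everywhere inside the package; BED input is shifted
at the boundary).

The tracks entering the composite for a focal breed are its autozygosity,
its smoothed |iHS|, the smoothed two-population FST, and |XP-EHH|
(absolute values, as the ranks are right-tailed). XP-EHH smoothing is off
by default and available as a switch. A track that is constant across the
shared sites — typically the autozygosity track of a simulation without
planted ROH — carries no ranking information and is dropped from the
composite with a log note.

## The synthetic-data generator

`sim_two_pop_fixture()` emulates the data layout of a two-breed imputed
whole-genome study: one shared site index, two populations with
Balding–Nichols-differentiated allele frequencies (Beta-distributed around
a shared ancestral frequency with variance `F·p(1−p)`), background LD from
founder-mosaic haplotypes, optional hard sweeps, and optional planted
homozygous segments, each recorded in a truth table.

Default conditions, chosen once for realism at desk scale:

* `fst_param = 0.1` — genome-wide differentiation of the order seen
  between distinct beef breeds.
* `n_founders = 50` — a founder-haplotype pool matching the small
  effective population size (tens of animals) of intensively selected
  breeds.
* `switch_rate = 2e-5`/bp — founder blocks of ~50 kb, matching the
  distance over which livestock LD decays.
* Sweeps copy one carrier haplotype onto random non-carriers until the
  core-allele frequency reaches its target (default flank 100 kb with a
  30 kb-mean exponential taper per recipient side). The taper mimics
  recombination during the sweep: the shared haplotype is longest at the
  core and frays outward, so haplotype statistics peak at the core instead
  of plateauing over a rectangular block. `inject_sweep()` without
  `taper_bp` performs the plain rectangular copy.

The generator reproduces the *structure* real scans rely on — LD decay,
frequency differentiation, long shared haplotypes, homozygous segments —
but not demographic history, recombination-rate variation, mutation, or
imputation error. Passing tests therefore validate the statistical
machinery, not the biological calibration of any particular breed pair.

## Problem sizes and scaled parameters

The sweep benchmark uses a 5 Mb chromosome with 2,000 SNPs and 100
individuals per population (200 haplotypes), one sweep to carrier
frequency 0.8; the null benchmark uses 800 SNPs over 4 Mb with 50
individuals per population, `fst_param = 0`, and no sweep, repeated over
20 seeds; the ROH benchmark plants 2 Mb segments in 40% of 50 individuals
on a 10 Mb / 2,000-SNP chromosome. At genome scale the package defaults to
the field-standard choices (running median over 1,001 SNPs, 50 iHS
frequency bins). At the benchmark's 2.5 kb SNP spacing those counts
correspond to far more physical distance than at sequence density, so the
benchmark scans use a 21-SNP median window (~50 kb, of the order of the
sweep's shared-haplotype scale) and 10 frequency bins (~85 valid SNPs per
bin); these were fixed after a seed-replicated power study and are stated
here as the package's desk-scale configuration.

## Numerical and degenerate-case choices

* `running_median()` shrinks its window symmetrically near the ends
  (`k' = 2·min(i−1, n−i)+1`), so output length equals input length and the
  first and last values pass through; missing values are excluded
  per window.
* Rank p-values average ties; a single value gets p = 0.5.
* Bins with zero SD standardize to 0; loci missing any component p are
  dropped from DCMS (complete-case) unless `impute_missing = TRUE`
  imputes 0.5.
* `fst_param = 0` uses the degenerate point mass at the ancestral
  frequency (no division by zero in the Beta parameterization).
* Site intersection harmonizes swapped REF/ALT codings and drops (or, in
  strict mode, errors on) irreconcilable allele pairs; strand flips are
  not supported.
* ROH windows truncated at chromosome ends are not formed; chromosomes
  with fewer SNPs than the window yield no calls.
* Ancestral alleles default to allele 0 (REF); since the composite uses
  |iHS|, polarization errors only flip signs and do not change the scan.

## Null behavior of the composite

The DCMS → empirical-normal → BH chain is anticonservative at the extreme
upper tail: the composite is a weighted sum of logit-transformed uniform
ranks, whose logistic tails are heavier than the normal used to calibrate
p-values. In repeated full-null simulations (and equally with fully
independent synthetic rank p-values), roughly one run in five to ten
produces at least one isolated BH-significant SNP at α = 0.05. Interpreting
single-SNP regions from a DCMS scan therefore warrants caution; regions
supported by many SNPs are the reliable output. The acceptance suite
reports the measured null rate.

## Known limitations

* Hard sweeps only; soft sweeps and polygenic adaptation are out of scope.
* The per-SNP FST estimator is the two-population baseline-variance form;
  Weir–Cockerham or Hudson estimators are deliberately not provided.
* No gap penalty is applied between distant markers during EHH
  integration.
* The mean of the per-SNP FST statistic on Balding–Nichols data sits below
  the ratio-of-expectations limit `F/(2−F)` (Jensen's inequality); the
  package's calibration tests compare against a direct Monte-Carlo of the
  generating model (~0.091 at F = 0.2) rather than the analytic limit.
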