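---
title: "Methods: admixture, hybrid classification and diversity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture, hybrid classification and diversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgressr)
```

## The problem

When a colonising species (here *Ischnura elegans*) expands into the range
of a closely related resident (*I. graellsii*), fertile F1 hybrids and
repeated backcrossing move alleles from one gene pool into the other.
This package implements the statistical pipeline used to quantify that
process from a handful of codominant microsatellite loci and a set of
aligned mitochondrial fragments: per-population diversity and
differentiation, an ordination of population allele frequencies, a
Bayesian admixture model that estimates each individual's ancestry
proportion `q`, a simulator of known hybrid categories that calibrates
how `q` maps onto F1/F2/backcross classes, and Nei's haplotype and
nucleotide diversity for the mitochondrial data.

Because the original field genotypes are not available, the package ships
a synthetic-data generator that emulates the survey design (sample sizes,
locus count, two differentiated parental pools, admixed individuals with
known ancestry), so every stage of the pipeline is exercised end to end
with a known ground truth.

## Genotype data model

A `genotype_table` stores an `n × L × 2` integer array of allele codes
(microsatellite fragment sizes) with `NA` for missing data, plus sample
metadata (`population`, `species`, `region`, `is_reference`).  Two design
rules keep the contracts simple:

* a locus in a sample is either fully typed or fully missing —
  half-missing genotypes are a parse error, never silently coerced;
* allele codes are opaque integers; no repeat-motif or size-range
  semantics are attached.

Readers and writers cover the STRUCTURE dialects (one or two rows per
individual, popflag column for learning samples, missing code −9) and
GENEPOP (2- or 3-digit encoding, `00`/`000` as missing); both round-trip
exactly.  Region and species labels come from a separate metadata CSV
rather than being inferred from population names.

## Diversity and differentiation

* **Observed heterozygosity** is the fraction of non-missing genotypes
  that are heterozygous; group values are unweighted means over loci (the
  survey table reports a single value per group without stating a
  weighting, so the simplest convention is used).
* **Expected heterozygosity** is Nei's unbiased gene diversity
  `He = 2n/(2n−1) · (1 − Σ p²)` with `n` the diploid count.
* **Allelic richness** is rarefied to `g` gene copies:
  `Σ_alleles [1 − C(N−N_i, g)/C(N, g)]`, evaluated with `lchoose` for
  stability.  `g` defaults to the smallest non-missing gene count across
  the compared groups; at `g = N` richness equals the observed allele
  count, and richness is monotone in `g`.
* **FST** is Weir & Cockerham's θ from the 1984 closed-form variance
  components `a`, `b`, `c`, combined as a *ratio of sums* over alleles
  and loci (standard practice; mean-of-ratios would weight loci
  erratically).  Loci monomorphic over all groups contribute nothing.
  Significance comes from permuting **whole multilocus genotypes** among
  groups, which preserves within-individual disequilibrium;
  `p = (1 + #{θ* ≥ θ}) / (n_perm + 1)` so p-values sit on the achievable
  grid and are never zero.

## Population-frequency PCA

The ordination operates on the population × allele frequency matrix (one
column per distinct allele across all loci), weighted by per-population
gene counts, i.e. populations are the units as in frequency-based PCA
software for codominant markers — the corresponding figure in this kind
of survey plots populations, so individual-level PCA is out of scope.
Axis significance is assessed by permuting individuals among populations
and recomputing the leading eigenvalues; the exact randomization scheme
of the original software is undocumented, so this reconstruction is our
stated convention.  Two further conventions:

* each axis is reported with an "axis FST" equal to the global multilocus
  θ times the axis's inertia fraction — an apportionment for reporting,
  not an estimator;
* axis signs are fixed by making the largest-magnitude loading positive,
  so plots are bit-for-bit reproducible.

## The admixture model

`run_admixture()` fits the standard Bayesian admixture model by Gibbs
sampling.  Latent variables and updates, per sweep:

* each gene copy's cluster of origin `z` is categorical with probability
  ∝ `q_ik · p_kla`;
* cluster allele frequencies `P` get a conjugate Dirichlet update.  Under
  the **correlated-frequencies model** (the default) the prior for
  cluster `k` at locus `l` is `Dirichlet(p_A · (1−F_k)/F_k)` where `p_A`
  are ancestral frequencies and `F_k` a per-cluster drift parameter;
  `F_k` (gamma prior, mean 0.01, sd 0.05) and `p_A` (Dirichlet(λ) prior)
  are updated by Metropolis steps.  λ is fixed at 1;
* individual ancestries `Q` get `Dirichlet(α + copy counts)`; a single α
  shared across clusters is updated by Gaussian Metropolis (sd 0.025) with
  a uniform prior on (0, 10];
* learning samples (`is_reference`) have `Q` **clamped** to the unit
  vector of the cluster implied by their species label.  Prior population
  information serves here purely to anchor the clusters on known-pure
  individuals; hard clamping implements exactly that and fixes the
  cluster labels across runs, so no post-hoc label alignment is needed
  for supervised runs.  The full migration-prior machinery of the
  reference software is deliberately not reconstructed.

Posterior summaries (mean `q`, central 90% credible intervals from the
thinned post-burn-in draws, thinning 10) are bit-reproducible given the
seed.  `ln P(D)` is estimated as `mean(lnL) − var(lnL)/2`, and
`evanno_delta_k()` computes `ΔK = mean_r |L_r(K−1) − 2L_r(K) + L_r(K+1)| /
sd(L(K))`, pairing replicate runs by index; ΔK is undefined at the end
points and where the replicate sd is zero.  Where several replicate
supervised runs must be reduced to one per-individual `q` table, we use
the run with the highest `ln P(D)` — the original report does not state
how its five replicates were combined, so this choice is ours.

Numerical safeguards: frequency draws are floored at 1e−9 and
renormalised so no observed allele ever has exactly zero probability;
`q` rows are renormalised to sum to 1 within 1e−9; a flat α trace
triggers a mixing warning rather than an error.

One stated symmetry deserves a caveat: the posterior is exactly
exchangeable under cluster relabeling, but a *bit-exact* column
permutation under a relabeled rerun is unattainable with a serial RNG
(gamma rejection sampling consumes a data-dependent number of uniforms),
so the symmetry is verified statistically (the symmetric F1 case must
give `q = 0.5 ± 0.02`), not bitwise.

**Run lengths.**  The package default is 5000 burn-in / 20000 sampling
sweeps, which on the 6-locus scenarios used throughout the tests gives
posterior means within Monte-Carlo error of the exact enumeration
posterior (checked against a brute-force oracle on fixed-difference
loci).  The full-length setting of the original analysis (20000 /
100000) is available via `admixture_config()`.

## Hybrid simulation and classification

`generate_cross_panel()` rebuilds the artificial-cross design: 50
offspring each of F1 (*graellsii* × *elegans*), F2, the first
*graellsii* backcross GB1, and the first to fourth *elegans* backcrosses
EB1–EB4, each generated panel serving as parental pool for its
dependants.  Two generators are provided:

* `frequency_draw` (default) matches the published tool's semantics: one
  allele per parent-side drawn from the pool's allele frequencies,
  independently across loci (HWE/LE within pools).  Frequencies for
  derived pools are re-tallied from the simulated panels.
* `pedigree` draws an actual parent individual per offspring and
  transmits one allele per locus, preserving parental multilocus
  associations.  It exists because the HWE assumption of frequency
  sampling inflates F2 variance; both modes are tested against the
  ancestry recursion `a(child) = (a(A)+a(B))/2`.

Expected *elegans* ancestries are 0.5 (F1, F2), 0.25 (GB1), 0.75, 0.875,
0.9375, 0.96875 (EB1–EB4).  Missing data are never generated.

Classification uses the posterior-mean `q` (credible intervals are
carried for reporting only).  The published assignment groups are
integer-percent ranges (≥90 / 89–68 / 67–21 / 20–11 / ≤10) that leave
gaps between bins; to make classification a total function the cut
points are placed at the midpoints 0.105, 0.205, 0.675 and at 0.90, with
right-open intervals (the source tables disagree between "(90–68)" and
"89–68", resolved in favour of a right-open interval at 0.90).  All cut
points are configurable, since the original binning of exact boundary
values is unstated.

## Mitochondrial diversity

`collapse_haplotypes()` groups identical sequences after a site policy:
`complete_sites_only` (default, DnaSP-like) drops columns containing gaps
or N before grouping; `pairwise` keeps all columns and skips ambiguous
sites pair by pair.  From the haplotype spectrum:

* `h = n(1 − Σ p²)/(n − 1)` with Nei's sampling variance
  `V(h) = 2/(n(n−1)) {2(n−2)(Σp³ − (Σp²)²) + Σp² − (Σp²)²}`; the
  reported sd is `√V(h)` and reproduces the published ± values (0.133,
  0.099, 0.047, 0.180);
* `π = Σ_{i<j} n_i n_j d_ij / (C(n,2) L)`, reported to 5 decimals as
  conventionally printed, and verified to equal a direct
  all-pairs computation.

Two published values are *documented discrepancies rather than targets*:
the COII π (0.00122) is not recoverable from its stated configuration
(one site, counts {9,3}, 673 bp gives 0.00061; the printed value is
consistent with ~335 analysed sites), and the CYTB π depends on an
unstated haplotype distance (neither resolution reaches 0.00053).  The
tests assert the computed values and the discrepancy, not the printed
numbers.

## The synthetic scenario

`survey_shape_scenario()` emits the full bundle the workflow consumes.
Choices, made once:

* **Balding–Nichols** frequencies
  (`Dirichlet(p_anc (1−θ)/θ)`) model the species split — the source
  analysis has no generative model for it, and BN is the standard
  parameter-sparse choice with θ directly interpretable as the target
  FST.  Parental differentiation defaults to θ = 0.2 at 6 loci × 10
  alleles, strong multilocus differentiation of the kind the real
  species pair shows.
* **Group sizes** follow the printed group totals 220 / 166 / 56
  (26 populations, 442 individuals).  The source's per-population rows
  are internally inconsistent with those totals, so the Spanish
  population sizes follow the one table whose rows do sum correctly and
  the other two groups use even splits.
* **Spanish ancestry mixture**: 27% pure-like (q 0.93–1), 59%
  backcross-like (0.70–0.90), 14% mixed (0.35–0.65) — cosmetic, so that
  report shapes resemble an introgressed survey; not an acceptance
  surface.
* mtDNA panels reproduce the five published haplotype configurations
  exactly (counts, segregating sites, fragment lengths).

What the generator does **not** emulate: within-region population
substructure (populations inside a region are i.i.d. draws from one
pool, so within-region FST is ≈ 0 where the real survey reported
0.029–0.049), null alleles and genotyping error, mutation, linkage, and
ascertainment-biased allele counts.  Passing tests therefore demonstrate
correctness of the estimators and the pipeline's behaviour under a known
model — not that the real data would yield the published field values,
which are explicitly not desk-reproducible without the original
genotypes.

## Verification strategy and problem sizes

Every estimator is checked against an independent oracle: exhaustive
subsample enumeration for rarefaction (N = 6, g = 4 and similar),
an independent ANOVA (sums-of-squares) transcription for θ, direct
pairwise scans for h and π, closed-form hand examples for ΔK and
`ln P(D)`, and exact-enumeration posteriors for the admixture sampler's
symmetric cases.  Ancestry recovery is measured as RMSE between
posterior-mean and true `q`, pooled over three replicate datasets of the
calibration design (50 + 50 references, 50 admixed individuals with
uniform true ancestry) — a single 50-individual RMSE has wide
Monte-Carlo spread, so pooling is the stated measurement protocol; the
pooled value must be below 0.15.  The hybrid-panel check uses the full
seven-cross design at 50 offspring per cross and requires strictly
increasing mean `q` along GB1 < F1 ≈ F2 < EB1 < EB2 < EB3 < EB4 with at
least 90% of F1 in the mixed bin.  These sizes — and the desk-scale run
lengths above — are the package's chosen test conditions.

## Known limitations

* The sampler implements the admixture model with correlated frequencies
  and hard-clamped learning samples only; LOCPRIOR, linkage and
  recessive-allele models, and multi-run cluster matching (CLUMPP-style)
  are out of scope.
* Unsupervised runs at K > 2 are subject to label switching; only
  `ln P(D)` is consumed from them (for ΔK), which is label-invariant.
* Rarefaction requires `g` no larger than the smallest group's gene
  count; groups with an entirely missing locus are rejected in the PCA
  matrix rather than imputed.
* Haplotype-network inference, Hardy–Weinberg and linkage tests, and
  null-allele detection are deliberately absent.
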