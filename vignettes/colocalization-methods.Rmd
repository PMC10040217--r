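---
title: "Methods: permutation co-localization, IP-MS enrichment, and coverage profiling"
author: "colocshuffle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation co-localization, IP-MS enrichment, and coverage profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocshuffle)
library(dplyr)
```

# Overview

`colocshuffle` answers three related questions that come up when studying
chromatin-bound factors such as the origin recognition complex (ORC) and
chromatin-binding nucleoporins (Elys, Nup98, members of the Nup107-160
subcomplex):

1. **Do two factors bind the same genomic regions more than chance would
   allow?** A permutation test on base-pair overlap between peak sets.
2. **Which proteins are specifically enriched in an immunoprecipitation?**
   Per-protein Fisher exact tests and fold enrichment on IP-MS spectral
   counts against a negative control.
3. **Does a perturbation reduce a factor's ChIP signal at its binding
   sites?** Background-scaled coverage tracks and mean-signal metaprofiles
   around peak centers, with shuffled-peak controls.

Everything operates on plain tibbles in BED conventions (0-based starts,
half-open ends), so results compose with dplyr/tidyr, and a synthetic-data
module generates genomes, peak sets, count tables and coverage tracks with
*planted* structure so each claim the package makes about real data can be
rehearsed on data where the truth is known.

# The permutation co-localization test

## Model and procedure

Given an **anchor** peak set $A$ (held fixed) and a **comparison** set $B$,
the statistic is the observed base-pair overlap
$O = |\mathrm{cover}(A) \cap \mathrm{cover}(B)|$. The null model relocates
$B$: each interval keeps its length and is placed uniformly at random over
every position, genome-wide, at which it fits entirely inside the allowed
space (the genome minus an exclusion mask of assembly gaps and blacklisted
regions). Chromosomes are therefore chosen with probability proportional to
their number of valid start positions for that interval length — a direct
inverse-CDF draw over the allowed runs, not rejection sampling, so short
chromosomes and snug gaps introduce no placement bias and an interval that
fits nowhere is an immediate, named error.

With $n$ permutations yielding null overlaps $O_1^*, \dots, O_n^*$:

$$p_\text{enrich} = \frac{\#\{O_i^* \ge O\} + 1}{n + 1}, \qquad
  p_\text{deplete} = \frac{\#\{O_i^* \le O\} + 1}{n + 1},$$

the add-one empirical estimator. Both tails include the tie term, so
$p_\text{enrich} + p_\text{deplete} \ge 1 + 1/(n+1)$ and the smallest
attainable p-value is $1/(n+1)$ — with the default $n = 1000$ the floor is
$\approx 0.000999$. Smaller printed values sometimes seen in the literature
for permutation analyses of this design are not attainable under this
estimator, and the package makes no attempt to produce them.

Effect size is the log2 fold enrichment of observed over expected overlap,

$$\mathrm{LFC} = \log_2\frac{O + c}{\bar O^* + c},$$

with pseudocount $c = 1$ bp applied only when either term is zero (keeping
the value finite without biasing typical cases). Direction is *enriched*
when $O > \bar O^*$, *depleted* when $O < \bar O^*$, *neutral* only on exact
equality.

## Screens, multiplicity, and differential enrichment

`enrichment_screen()` runs the test for many comparison sets against one
anchor and applies a Bonferroni correction across the screen. Since the
procedure yields two one-sided empirical p-values, the adjusted value
reported in `p_adj` is the Bonferroni-corrected *directional* p — the
smaller of `p_enrich` and `p_deplete` times the number of comparisons,
capped at 1. Each comparison receives a child seed derived by hashing its
name together with the master seed, so the null distribution of one
comparison is invariant to adding or removing others — screens can be
extended incrementally without silently changing earlier rows.

`differential_enrichment()` repeats the screen against two anchors (for
example, sites bound by both Elys and ORC2 versus Elys-only sites) with
independently derived seeds and reports $\Delta\mathrm{LFC} =
\mathrm{LFC}_{A_1} - \mathrm{LFC}_{A_2}$ per comparison set.

## Numerical choices

* **Merging.** Overlap is computed on merged sets by default so nested or
  duplicated peaks within one file are not double-counted; `merge = FALSE`
  switches to the raw pairwise intersection sum for peak files whose
  internal duplication is meaningful. Published peak files rarely document
  which convention their overlap statistics used, so both are exposed.
* **Coordinates.** All interval arithmetic runs in linearised genome-wide
  coordinates with cumulative-coverage lookups (`findInterval` on merged
  interval boundaries), which makes a single permutation of a few hundred
  peaks a sub-millisecond operation and keeps $10^5$-permutation screens
  interactive. The unit tests pin this arithmetic, base for base, to a
  brute-force boolean-array count on toy genomes, and cross-check it
  against `GenomicRanges::intersect()`.
* **Self-overlap.** Shuffled intervals may overlap one another (the common
  shuffle semantics); overlap of the shuffled set is still computed on its
  merged form, so the null statistic is a genuine union overlap.
* **Determinism.** Every stochastic function takes a `seed` and restores
  the caller's RNG state; identical seeds give bit-identical results, on
  disk included.

# IP-MS spectral-count enrichment

Replicate spectral counts are pooled per protein and condition (the test
compares conditions using all replicates jointly; per-replicate testing
followed by combination is deliberately not offered). For each protein with
pooled counts $a$ (IP) and $b$ (control) against condition totals $N_a,
N_b$, the two-sided Fisher exact test is applied to

$$\begin{pmatrix} a & N_a - a \\ b & N_b - b \end{pmatrix},$$

via `stats::fisher.test()`; the suite verifies the p-values against an
independent hypergeometric enumeration to $10^{-10}$. Fold enrichment is
the raw pooled ratio $a / b$, with $b = 0$ replaced by 1 so the value stays
finite (such proteins carry a `zero_control` flag); a per-replicate mean
ratio is available as an auxiliary column. A protein is called significant
when **both** $p < 0.05$ and fold enrichment $\ge 2$ — the joint cutoff
keeps deep-count proteins with trivially small fold changes out of the hit
list. For display, p-values at or below 0.0010 are floored to 0.0010 in
`p_display`; the raw `p_value` column is never altered. The 2×2 margins use
per-condition totals summed over all proteins and replicates; other margin
constructions (per-sample totals) exist in vendor software but are not
documented well enough to reproduce, so the explicit construction above is
the contract.

# Coverage quantification

* **Background scaling** (`background_scale()`): sample `n_regions`
  regions of `region_len` bp uniformly (defaults 25,000 × 250 bp),
  integrate each track's signal over them, and scale every track down to
  the minimum total. "Signal within regions" is integrated coverage (value
  × covered bp) rather than a read count, since the package consumes
  coverage tracks, not alignments; for tracks derived from constant-width
  binned counts the two differ only by a constant factor, which the ratio
  normalization cancels. Background regions may overlap each other and may
  overlap peaks; with 25,000 × 250 bp over a multi-megabase genome the
  peak contribution to the sampled total is a small, condition-shared term.
* **CPM scaling** (`cpm_scale()`): total integrated signal rescaled to
  $10^6$.
* **Joint rescaling** (`joint_rescale()`): within each replicate group all
  tracks share one factor chosen so the reference (negative-control)
  track's maximum hits a target, absorbing depth differences between
  replicate experiments while preserving within-replicate ratios.
* **Metaprofiles** (`profile_matrix()`): windows of ±`halfwidth` bp around
  each peak center (`floor((start+end)/2)`; the midpoint convention is the
  package's choice, as plotting tools leave it unstated) are cut into
  `bin_width` bp bins and averaged. Windows running off a chromosome end
  are truncated: partially covered bins average only their covered bases,
  empty bins are `NA` and drop out of the column means. With an even bin
  count the reported "center" bin is the bin whose left edge is the peak
  center.

# The synthetic-data generator

The generator emulates the statistical structure the analyses rely on, with
defaults chosen to resemble a compact metazoan chromatin experiment:

* **Genome**: 2 chromosomes × 5 Mb — large enough that chance overlap is
  small, small enough that full screens run in seconds.
* **Exclusion mask**: random 2-kb regions merged; the draw count is set to
  $-\ln(1-f)\,G/L$ so the merged coverage hits the target fraction $f$
  (default 0.1, a typical gap+blacklist burden) in expectation.
* **Peak sets**: 500 anchors of 200–1000 bp (uniform lengths), matching the
  size range of typical ChIP-seq peak calls. Comparison sets plant a
  per-peak overlap fraction $\theta$: $\lceil\theta n\rfloor$ peaks are
  centered on randomly chosen anchors with Gaussian jitter (SD 100 bp),
  clipped to retain at least 1 bp of overlap; the rest are placed
  uniformly. The realized `fraction_peaks_overlapping()` is $\theta$ plus
  chance overlap, and at $\theta = 0.98$ on the default sparse genome the
  measured fraction reproduces the 98%-regime within ±0.02.
* **Spectral counts**: per-protein baselines $\lambda_p \sim$
  Gamma(shape 1.5, mean 10) — a right-skewed abundance distribution with a
  realistic dynamic range; control counts Poisson($\lambda_p$), IP counts
  Poisson($f_p \lambda_p$) with planted folds $f_p$ and $f_p = 1$
  elsewhere; 3 replicates per condition. Poisson rather than
  negative-binomial is intentional: the Fisher test itself assumes no
  overdispersion beyond sampling, so the null calibration of the test is
  measured under its own model. Real IP-MS replicates are typically
  overdispersed, so passing null calibration here bounds behaviour under
  the test's assumptions, not under all real data.
* **Coverage**: per condition, background (0.1) + amplitude × triangular
  kernel over each peak, evaluated at 50-bp bin midpoints, plus Gaussian
  bin noise (SD 0.05) floored at zero. The triangular kernel is chosen for
  closed-form bin means, which makes the per-base oracles in the test
  suite exact. Amplitudes (1, 0.6) emulate a depletion that reduces signal
  at binding sites by 40% without touching the background; the center-bin
  ratio recovered by `profile_matrix()` then sits near 0.6 — slightly
  above it, since the shared background enters both numerator and
  denominator (≈ $(0.1 + 0.6\bar k)/(0.1 + \bar k)$ with $\bar k \approx
  0.95$ the mean kernel value in the center bin).

What the generator does **not** model: GC or mappability structure,
fragment-length effects, nucleosome positioning, read-level noise,
overdispersed spectral counts (the generator is Poisson only), or
correlated placement of decoy peak sets. Tests passing on
synthetic data therefore validate the *statistical machinery* — calibration,
power against planted effects, exactness of the deterministic primitives —
not robustness to every artifact of real sequencing data.

# Problem sizes and validation scope

The test suite validates at deliberately compact scales: toy genomes of a
few kb for the exact oracles (per-base overlap equality on 1,000 random
pairs; exhaustive-placement uniformity of the shuffler; hypergeometric
Fisher enumeration), 0.5–5 Mb genomes for the statistical properties
(type-I error of the permutation test in [0.02, 0.09] over 200 independent
runs at 200 permutations; a $\theta = 0.95$ planted set ranking first at
the p floor in ≥95% of 50 ten-comparison screens; recovery of a 0.6
depletion ratio within ±0.06). `scripts/acceptance.R` recomputes the same
quantities from scratch at these sizes for any seed.

# A worked example

```{r example, eval = FALSE}
g      <- simulate_genome(2, 5e6)
mask   <- simulate_exclusion_mask(g, 0.1, seed = 1)
anchor <- simulate_anchor_peaks(g, 300, c(200, 800), mask = mask, seed = 2)

cmps <- list(
  elys_like = simulate_colocalized_peaks(anchor, g, 0.95, 300, mask = mask, seed = 3),
  decoy     = simulate_anchor_peaks(g, 300, c(200, 800), mask = mask, seed = 4))

scr <- enrichment_screen(anchor, cmps, g, mask, n_perm = 1000, seed = 5)
tidy(scr)
autoplot(scr)
```

# Known limitations

* No GC-, mappability- or chromatin-state-matched nulls; the shuffle null
  asks "anywhere in the allowed genome", which is the right question for
  gross co-localization but inflates enrichment for factors confined to,
  say, euchromatin. Comparisons between factors sharing such confinement
  remain interpretable through the differential screen.
* The empirical p floor $1/(n+1)$ means a 1000-permutation screen cannot
  distinguish candidates beyond $p \approx 0.001$; rank by log2 fold
  enrichment within the floor group.
* Fisher margins use per-condition totals; if the upstream search reports
  per-sample assigned-spectra totals, recompute margins before calling.
* `profile_matrix()` assumes stepwise tracks with non-overlapping runs;
  overlapping-run bedGraphs are rejected rather than resolved.
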