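---
title: "Genomic diversity metrics for conservation assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic diversity metrics for conservation assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdassess)
```

This vignette is the package's account of its science: the estimators and
models it implements, the assumptions behind them, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the design choices made where more than one convention was
defensible.

## Scope and data model

`gdassess` works from *called diploid genotypes* for a single population
of 2–25 individuals: a `variant_table` holds biallelic SNP sites coded as
alternate-allele counts (0/1/2, `NA` for missing). All coordinates are
0-based half-open (BED convention); VCF positions are converted on read.
Chromosome count is `n = 2 × individuals` — autosomes only; sex
chromosomes, phased haplotypes, and genotype likelihoods are out of
scope. Operating on called genotypes rather than genotype likelihoods is
a deliberate design choice: it keeps every estimator deterministic and
desk-scale, and the estimators' definitions are agnostic to how genotypes
were obtained. With low-coverage data the caller's uncertainty propagates
into the metrics, so upstream genotype quality matters more here than in
likelihood-based pipelines.

Callability is explicit throughout. The callable mask is the intersection
of non-repeat regions, uniquely mappable regions, and scaffolds of at
least 100 kb (`callable_mask()`); per-site quantities are normalized by
*effective sites*, the callable bp per window. The scaffold-length
boundary is inclusive (a scaffold of exactly 100 kb is retained). An
alternative definition of the denominator — sites with data rather than
callable mask length — can be emulated by supplying a mask built from
covered positions; the mask-length definition is the default because it
matches how repeat/mappability filtering is usually reported.

## Diversity estimators

For each non-overlapping window (default 50 kb; the trailing partial
window is kept and flagged, and can be excluded from summaries):

* **Segregating sites and Watterson's theta.**
  `theta_W = (S / a1(n)) / L_eff`, with `a1(n) = sum_{i=1}^{n-1} 1/i` and
  `L_eff` the window's effective sites. Because `a1` depends on `n`,
  sites with per-site call rate below a threshold (default 0.8) are
  dropped and the *modal* called-chromosome number among retained sites
  is used, keeping the `S / a1` form exact rather than mixing `n` values.
* **Nucleotide diversity.** Per site, the expected pairwise difference is
  `2 x (n - x) / (n (n - 1))` with the *per-site* called `n`; summed and
  divided by `L_eff`. This equals the brute-force average Hamming
  distance over all sequence pairs, which the test suite verifies by
  enumeration on small haplotype matrices.
* **Tajima's D.** `D = (pi_abs - S/a1) / sqrt(e1 S + e2 S (S - 1))` with
  the standard constants derived from `n` (`tajima_constants()`). `D` is
  undefined at `S = 0` and such windows are excluded from window means
  (the window-mean convention is also our default for reporting a
  genome-wide `D`, rather than one genome-wide evaluation). A numerical
  note established by this package's own simulations (see below): the
  *mean* of `D` over neutral replicates is slightly negative rather than
  exactly zero — a finite-sample property of the variance normalization,
  not an implementation artifact; an independent coalescent simulator
  reproduces the same mean.
* **Heterozygosity.** Per individual, `H = het sites / callable sites`;
  the population value is the arithmetic mean over individuals. Species
  with a single sampled individual are summarized with a warning.

## Runs of homozygosity

ROH are called per individual with a two-state HMM over site-level
observations (hom / het / missing):

* Inside an autozygous tract, heterozygotes appear only through genotype
  error or recent mutation: emission `p_het_in_roh` (default 0.005).
* Outside, the het emission is the Hardy–Weinberg expectation
  `2 p (1 - p)` from the population allele frequency at the site
  (clamped to [1e-4, 0.5]), or a fixed constant (default 0.35) when
  frequencies are not used.
* Missing genotypes emit probability 1 in both states.
* Transition probability over an inter-site gap of `g` bp is
  `1 - (1 - t)^g` with `t = 5e-7` per bp, computed in log space, so the
  cost of switching scales with physical distance rather than site count.

Decoding is exact Viterbi; the tests verify it against exhaustive path
enumeration (comparing path probabilities, since symmetric instances can
have genuinely tied optima). Maximal AZ runs become segments spanning
first-to-last AZ site (+1). `F_ROH>L` is the summed length of segments at
least `L` long divided by the assessed length — by default the callable
length of scaffolds ≥ 100 kb; the full scaffold span can be used instead.
`F_ROH>1Mb` is reported as undefined when no scaffold reaches 1 Mb, since
such an assembly cannot contain a qualifying segment, mirroring how
low-contiguity assemblies are treated in practice.

The HMM is genotype-based by design rather than a re-implementation of a
genotype-likelihood/allele-frequency caller: the defaults above give the
same segment semantics while remaining self-contained and exactly
testable against enumeration.

## Heterozygosity-loss projection and genetic categories

The projection is the classical drift expectation
`H_T = H_O (1 - 1/(2 Ne))^T`, evaluated in log space (`exp(T * log1p(...))`)
so that ratios at very large `Ne` do not lose precision; the tests check
agreement with naive evaluation to 12 significant digits across
`Ne ∈ [10, 1e9]`. `T` is the real-valued number of generations in the
horizon (100 years by default, chosen to align with Green Status
assessment time frames): `T = 100 / t`.

`Ne` can be supplied directly, derived from census size via an `Ne/Nc`
ratio (0.10 and 1.00 bracket the strict and lenient conventions), or from
`theta_W / (4 mu)`.

The decision tree, in order, with exactly one rule recorded as
provenance:

1. **Ratio rule** (when `Ne` is derivable and the generation time is not
   long): `H_T:H_O ≤ 0.90` → CR; `≤ 0.95` → EN; `≤ 0.975` → VU.
2. **Ne floors**, a safeguard that may only *worsen* the category:
   `Ne < 1000` → at least VU, `< 500` → at least EN, `< 100` → at least
   CR.
3. **Relative-H_O rule**: applied when `Ne` cannot be derived, when the
   generation time exceeds the configured bound (default 15 years —
   long-generation species register drift too slowly for a 100-year
   ratio), or when the tree returns LC and a reference is available. If
   `H_O` is below the *maximum* `H_O` of relatives (same taxonomic
   Order, Family as fallback) already categorized VU/EN/CR, the species
   is determined Threatened (conventionally reported as VU). The maximum
   is used rather than a mean or median because it only increases as new
   references accrue, so the threshold is stable.
4. Otherwise LC.

Open parameters settled here and exposed in `category_thresholds()`: only
the 0.95 (CR-or-EN) and 0.975/Ne<1000 (VU) boundaries are fixed by the
published tree; the CR/EN split at 0.90 and the EN:500 / CR:100 floors
are package defaults (the 500 echoes the CBD's Ne > 500 indicator).
Binary collapse counts VU with the Threatened group. NT is accepted on
input but never produced by the tree. `genetic_categories()` applies the
tree in two passes over a species table: tree categories first, then the
relative-H_O rule against the resulting within-Order threatened maxima —
so a reference table never has to be supplied by hand.

## Green Score

`G = sum_S W_S / (W_F × N) × 100` over `N` spatial units, and the
GD-corrected variant multiplies each unit's weight by
`min(GD_S / GD_LC, 1)`, where `GD_LC` is the average diversity of related
Least-Concern species. The cap at 1 means correction can never raise a
score, and equals the uncorrected score only when every unit is at or
above the reference.

Two weight presets are shipped because the published definition and the
published worked example disagree: the stated weighting is
absent/present/viable/functional = 0/3/6/9 with `W_F = 9` (`"iucn"`), but
the towhee worked-example arithmetic only reproduces with functional = 12,
viable = 9, `W_F = 12` (`"box1"`). Both are preserved; `box1` is the
default so the worked examples reproduce exactly (100 / 58.936 / 75 /
38.028 to the 3 decimals at which scores are reported). The `present`
weight in `box1` is kept at 3 — it is not exercised by the worked
examples, and no published arithmetic pins it down.

## The coalescent simulator

`simulate_coalescent()` draws a Kingman genealogy (exponential waiting
times at rate `k(k-1)/2` while `k` lineages remain), places mutations as
a Poisson process at rate `theta/2` per unit branch length, assigns each
mutation to a branch proportionally to its length, and gives it a unique
uniform integer position — the infinite-sites model, with duplicate
positions resampled. There is **no recombination within a window**;
windows are independent replicates (`simulate_population()` lays them end
to end on one scaffold). Haplotypes `2i-1, 2i` pair into individual `i`.

Closed forms under this model anchor the validation: `E[S] = theta × a1(n)`
(14.1448 at `n = 10`, `theta = 5`) and expected pairwise differences
`= theta`. The acceptance tests simulate 2000 replicate windows and check
recovery within three Monte-Carlo standard errors, plus per-site
`theta_W` recovery at `theta/L = 0.002` through the full windowed
pipeline (200 windows of 50 kb, 10 individuals). On the same fixtures the
mean of Tajima's D is measured: it sits near −0.07 rather than 0 (the
finite-sample bias noted above), which an independent simulator
reproduces; the strict within-3-SE-of-zero check is therefore expected to
fail even for a correct implementation, and we keep it as a documented
known limitation of that expectation rather than re-centering the test.

`inject_roh()` converts a chosen sample's heterozygous genotypes to
hom-ref within specified tracts (any homozygote would do for a
genotype-based HMM), creating ground truth for ROH recovery: with tracts
≥ 1 Mb and outside het density ≥ 10× the inside, `F_ROH>1Mb` is recovered
within ±0.02 of the injected fraction. What the generator does *not*
emulate: demographic change (bottlenecks, growth), selection,
recombination within windows, sequencing error, or missingness patterns —
so passing tests demonstrate estimator correctness under neutrality, not
robustness to real-data artifacts.

Fixtures round-trip through plain-text VCF (`write_fixture()` /
`read_genotype_table()`) byte-identically under a fixed seed, with a JSON
truth file recording `theta`, the seed, and any injected tracts.

## Problem sizes and numerical choices

Test and validation runs use sizes chosen to make Monte-Carlo error small
relative to the quantities checked while staying desk-scale: 2000
coalescent replicates for the closed-form recoveries, 200 windows for the
windowed `theta_W` recovery, 200 random instances (≤ 12 sites) for
Viterbi-vs-enumeration, and a 4 Mb two-sample genome with 10,000 sites
for ROH-tract recovery. All stochastic tests run under fixed seeds.

Degenerate inputs are mapped to explicit undefined markers (`NA`) rather
than errors where a downstream mean can simply skip them: windows with no
callable bp, `D` at `S = 0`, `F_ROH>1Mb` without a 1 Mb scaffold, `H`
with zero callable sites. Genuine contract violations (unknown sample,
interval beyond scaffold end, overlapping injected tracts, `Ne ≤ 0.5`)
are errors that name the offending input.
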