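---
title: "Inferring generation intervals from two genomic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring generation intervals from two genomic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genclock)
```

## The problem

The mean age of parents at reproduction — the generation interval — is a
basic demographic parameter of human populations, yet it is invisible in
most population-genetic summaries. Two molecular clocks carry information
about it:

* **The recombination clock.** All non-Africans carry tracts of
  Neanderthal ancestry from an admixture pulse roughly two thousand
  generations ago. Each generation, recombination breaks these tracts, so
  their length distribution shortens at a rate set by the *number of
  generations* elapsed, not by calendar time. Populations with shorter
  generation intervals pack more generations — and more recombination —
  into the same number of years, and end up with shorter archaic
  fragments.
* **The mutation clock.** Trio sequencing shows that the number of de novo
  mutations a child receives grows roughly linearly with each parent's
  age, with a large paternal and a small maternal slope. Because the
  regression has a positive intercept, the *yearly* mutation rate falls
  as the generation interval grows. Populations with shorter generation
  intervals therefore accumulate derived alleles faster per year, and the
  relative frequencies of mutation types (the mutation spectrum) shift
  with parental age as well.

`genclock` implements both clocks and the statistics connecting them,
together with a synthetic-cohort generator rich enough that the entire
pipeline can be exercised, calibrated and tested without any external
data.

## The tract-decay model

Under the Markovian approximation of ancestry along a chromosome, `g`
generations after a pulse contributing a fraction `alpha` of archaic
ancestry, archaic tract lengths are approximately exponential with mean

$$ \mathbb{E}[s] = \frac{1}{g\,(1-\alpha)} \text{ Morgans}, $$

and the generation count is recovered from a mean tract length in cM as
`estimate_generations()`: \(\hat g = 100 / (\bar s_{cM} (1-\alpha))\).
Generations along a lineage are accumulated piecewise: years in the shared
epoch divide by the ancestral mean parental age, years after the
group split divide by the group's own mean parental age
(`lineage_generations()`).

The generator (`simulate_fragment_decay()`) does not run a coalescent.
Each sampled haplotype copies material from a finite pool of `n_pool`
ancestral haplotypes simulated at the split (a stationary two-state Markov
chain with archaic segment mean `1/(g_shared (1-alpha))`), in ancestry
blocks whose breakpoints arrive at the private-epoch recombination rate.
Two calibration details matter:

* A block cut re-picks the same pool haplotype with probability
  `1/n_pool`, silently rejoining the tract it just cut. The cut rate is
  therefore inflated by `n_pool/(n_pool - 1)` so that the composite
  archaic tract-end hazard equals `(g_shared + g_private)(1 - alpha)` per
  Morgan exactly in expectation. With the default `n_pool = 32` the
  uncorrected bias would be about 3% — of the same order as the Monte
  Carlo error of the calibration tests — which is why the correction is
  applied rather than documented away.
* The finite pool is what creates *shared* archaic sequence between
  individuals and groups (all pulse-one material lives inside the union of
  the same 32 ancestral haplotypes). This mirrors drift in a finite
  ancestral population: `n_pool` plays the role of the effective number of
  admixed founder haplotypes. A second pulse uses its own pool private to
  its target group, which is exactly why the two-pulse scenario produces
  an excess of group-private archaic sequence at matched total archaic
  proportion; dilution removes whole tracts with the stated probability,
  thinning coverage without touching the length distribution.

Consequences worth knowing: carriers are correlated through the pool, so
tract counts fluctuate more than independent sampling would suggest
(binomial in `n_pool`, not in the number of sampled haplotypes), and
when a group is sampled during the shared epoch each haplotype is a
verbatim pool copy. X chromosomes scale the recombination generation
count by 2/3 (X recombines in females only). Tract boundaries snap to the
1 kb HMM window grid, so truth and calls are comparable without
off-by-one ambiguity; snapping drops tracts shorter than half a window,
a negligible (<1%) effect at the simulated means.

## The window HMM

Archaic fragments are called from per-window private-SNP counts by a
two-state hidden Markov model with Poisson emissions scaled per window by
`callability * mutrate_scale` (`fit_hmm()`, `decode_fragments()`). The
model is deliberately minimal — the pipeline's contribution is downstream
of calling — but honest: Baum–Welch with a monotone log-likelihood,
windows below 5% callability treated as missing (no emission term,
transitions still apply), emission rates initialised from the 50th and
99th percentiles of exposure-corrected counts, tolerance `1e-6` on the
log-likelihood and at most 500 iterations. Decoding reports maximal runs
of archaic posterior above 0.5, each annotated with its mean posterior;
"high-confidence" fragments are those with mean posterior at or above a
configurable 0.8 (no published value exists for this cutoff; it is a
default, not a reproduction).

At the default emission contrast (0.02 vs 0.4 expected SNPs per
fully-callable kb, i.e. 20x) posterior decoding overshoots each planted
tract boundary by roughly two to three windows — the per-window
log-likelihood ratio at zero counts is only ~0.35 — which is what limits
false-called sequence to a few percent of called bp on 100 kb tracts, and
why recall and false-call rates are benchmarked on tracts of that size
rather than on the shortest tracts the generator can produce.

## Resampling statistics

Group comparisons are exclusively resampling-based. `bootstrap_ci()`
follows the normal-approximation construction (bootstrap mean ± z ×
bootstrap sd; the percentile form is available as an option).
`permutation_diff_means()` permutes group labels, counts permuted
statistics *as or more extreme* than the observed difference in the
observed direction (ties count as extreme, compared with `>=` on exact
values), doubles the one-tailed fraction, and floors the fraction at
`1/n_perm` when no permutation qualifies — the floor is applied before
doubling, so an empty tail reports `p < 2/n_perm` with a `floored` flag.
`permutation_F()` uses the one-way F statistic for multi-group tests
(one-tailed; all-identical data define F = 0). Tests in this package run
at `n_perm = 999` and `n_boot = 2000` — enough for the calibration bands
asserted in the test suite — while `100000` remains the default for
analysis use. Permutations shuffle *individuals* (their per-individual
summary values), not fragments, since every group statistic here is a
mean over individuals.

## Interval semantics

All fragment-set arithmetic is 0-based half-open BED. `merge_intervals()`
joins overlapping *and* book-ended intervals (the merge convention of the
standard genome-arithmetic toolkit); `intersect_total()` reports overlap
segments and the shared/private bp decomposition; fragment-level sharing
(`classify_individual_fragments()`) uses any-overlap semantics — one
base pair qualifies, book-ended contact does not, fragments are kept
whole. `window_frequency()` tiles the merged fragments into 1 kb windows
and counts *distinct individuals* overlapping each window. Counting
overlap events instead would coincide for fragments longer than a window
but not in general; distinct individuals is the quantity interpreted as
an archaic allele frequency, and the event-counting alternative remains
available via `count = "overlaps"`. The implementation rides on
IRanges/GenomicRanges; the test suite verifies every semantics decision
against a per-base brute-force oracle on hundreds of random instances.

## Recombination maps and genetic lengths

Population-specific maps give the same chromosome different genetic
lengths, which would bias between-population fragment comparisons.
`rescale_maps()` multiplies each population's rates by `l_qc / l_pc` so
every population matches the shortest population's chromosome length.
The printed form of that factor in the source description (`l_pc / l_qc`)
inflates rather than equalises lengths and contradicts the stated goal of
a common total length; the implementation follows the stated contract,
and the printed variant is available behind `mode = "printed"` for
replication experiments. Fragment genetic lengths use the
overlap-weighted mean block rate (`fragment_mean_rate()`) and the unit
conversion `s(cM) = s(bp) * 1e-6 * r(cM/Mb)`.

## Mutation spectrum

Derived-allele records are filtered (`filter_variants()`: outgroup-shared
sites, multi-allelic positions, masked regions including everything with
archaic evidence — which also makes the mutation analyses independent of
the fragment analyses), then classified (`classify_mutations()`) under
the standard pyrimidine-ancestral strand collapse into 96 trinucleotide
types and 9 reported types: the six base types plus C>T subdivided into
CpG>TpG (3' G after collapse, taking precedence), TCC>TTC, and the
remainder C>T'. Homozygous derived genotypes count two mutations,
heterozygous one. All nine reported fractions share one denominator —
the total over the six base types — so the six base fractions sum to 1
and the three C>T subtypes sum to the C>T fraction.

## From counts to generation intervals

With pedigree coefficients (defaults 6.05 + 1.51 a_f paternal,
3.61 + 0.37 a_m maternal, overridable via `pedigree_params()`):

* `mu_per_generation()` and `mu_per_year()` give `9.66 + 1.88 a` and
  `9.66/a + 1.88` at equal parental ages;
* an excess measured since the out-of-Africa epoch is rescaled to the
  post-split epoch by `excess_scaling()` (`x t_ooa / t_split`);
* `estimate_parental_age()` inverts the yearly-rate ratio to the unknown
  mean parental age, and `expected_accumulation_ratio()` is its exact
  inverse (epoch-weighted variants included). Internally everything is
  full precision; rounding to two decimals happens only at presentation.

One reproducibility note: at ratio 1.0164 and a reference age of 32 the
inversion yields 28.6089, while the matching published table prints
28.59 alongside a difference of 3.39 years (consistent with 28.61); the
unrounded ratio behind the published number is unstated. The package
reports the formula value.

Sex-specific signatures: `x_to_a_ratio()` (females only by default, X
spends 2/3 of its history in females), `cg_cdnm_ratio()` (per-window
C>G vs non-C>G ratio averaged separately over clustered-DNM and other
1 Mb windows — unweighted mean over windows, with a count-weighted
option; windows with zero non-C>G counts are skipped and reported), and
`y_rate_sensitivity()`, the relative derivative of the paternal yearly
rate (about 0.4–0.5% per year near 28–29 years; the source states the
band but not the formula, so the derivative is a reconstruction and
labelled as such).

## Regression comparison

`fit_type_vs_fraglen()` fits per-type OLS of mutation fraction on mean
fragment length across individuals; `aggregate_dnm()` reproduces the trio
aggregation rules (group probands by mean parental age rounded to one
decimal — the published grouping is ambiguous for non-integer ages, so
the precision is a parameter — sum counts, take fractions of sums, drop
keys with fewer than two probands) and `fit_type_vs_age()` fits weighted
least squares with proband counts as weights. `compare_slopes()`
regresses one slope set on the other across the nine types.

## Synthetic mutation generation

`simulate_mutations()` draws per-individual dosage-weighted counts as
Poisson with the closed-form epoch-summed mean (`expected_variant_count()`),
scaled to the synthetic genome size. Nine-type probabilities are linear
in the lineage mean parental age (defaults: TCC>TTC decreasing by 1e-3
per year, CpG>TpG flat, C>G increasing, slopes summing to zero — the
directions seen in trio data; the magnitudes are this package's choice,
as no published parameterisation exists at this granularity). X counts
mix maternal and paternal exposures 2/3 : 1/3; Y counts are paternal
only; records inside flagged cDNM windows have their C>G probability
inflated by `1 + cdnm_gamma (a_m - 20)`. Variants are placed uniformly
on the callable mask at window, not site, granularity for the cDNM
enrichment, and each record is emitted on a random strand so that
classification must actually strand-collapse.

What the generator does *not* emulate: selection, gene conversion,
reference bias, sequencing error, linkage between variants, and realistic
site-frequency structure. Passing tests therefore demonstrate the
correctness and calibration of the *statistics*, not robustness to every
real-data pathology.

## Problem sizes and reproducibility

The test suite runs the calibration checks at deliberately modest sizes
chosen once: 2000 null replicates at 999 permutations for type-I error,
1000 replicates at 2000 bootstrap resamples for CI coverage, ≥5000 tracts
for tract-decay recovery, a 200,000-window track for HMM parameter
recovery and 40 planted 100 kb tracts for the recall benchmark, and two
30-individual groups (autosomal genome 100 Mb, mutation counts scaled
3x) for the end-to-end generation-interval recovery. All randomness
flows from one master seed through named substreams (one per individual
per chromosome, hashed from labels), so adding individuals or groups to
a configuration never perturbs existing draws, and every result is
bit-reproducible given the seed.

## Known limitations

* The tract model is Markovian; real tract-length distributions have
  heavier tails and inter-tract correlations that a coalescent would
  produce.
* Called fragment lengths are biased upward relative to truth tracts
  (short tracts are missed; boundaries smear; the two haplotypes of an
  individual merge), so generation counts estimated from *called*
  fragments underestimate the truth — exactly as with real callers. The
  decay calibration therefore tests the generator's truth tracts, and
  the end-to-end mutation-clock recovery uses counts, which carry no
  such bias.
* The pipeline's slope-concordance stage needs real per-individual
  spectrum variation to be informative; at small synthetic cohort sizes
  the per-type slopes are noise-dominated and the concordance fit is
  reported without a significance claim.
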