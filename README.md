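# genclock

Inference of historical human generation intervals from two independent
genomic clocks:

* **the recombination clock** — introgressed Neanderthal fragments are
  broken by recombination every generation, so populations that packed
  more generations into the ~40,000 years since the Eurasian split carry
  shorter archaic fragments;
* **the mutation clock** — the de novo mutation count per child grows
  linearly with parental age (paternal `6.05 + 1.51 a_f`, maternal
  `3.61 + 0.37 a_m` per generation), so the *yearly* rate
  `μ̂_y = 9.66/a + 1.88` falls with the generation interval `a`, and both
  the rate of derived-allele accumulation and the mutation spectrum
  (96 trinucleotide types; 9 reported types with C>T split into CpG>TpG,
  TCC>TTC and C>T′) shift with it.

Given a derived-allele accumulation ratio `d_x/d_z` between two
populations and the reference generation interval `a_z`, the unknown
interval is

```
a_x = 9.66 / ( (d_x/d_z) * (9.66/a_z + 1.88) - 1.88 )
```

The package implements the full analysis as composable stages — a
synthetic-cohort generator (exponential tract-length decay under
one-pulse, two-pulse and dilution demographies; Poisson mutation counts
with age-dependent spectra; window tracks; recombination maps), a
two-state Poisson window HMM for archaic-fragment calling, BED-style
interval arithmetic with merged/shared/private/frequency semantics,
bootstrap and permutation statistics, physical-to-genetic length
conversion, spectrum classification, the generation-time estimators, and
sex-specific signatures (X-to-A ratio, clustered C>G enrichment,
Y-linked rate sensitivity) — plus `run_pipeline()` to execute them end to
end. It is aimed at population geneticists who want to study, teach or
stress-test generation-interval inference on fully controlled synthetic
data.

## Worked example

Two groups that differ only in generation interval (25.3 vs 28 years)
over the 40,000 years since their split:

```r
library(genclock)

cfg <- cohort_config(
  groups = list(group_spec("WE", 8, a_f = 25.3, a_m = 25.3),
                group_spec("EA", 8, a_f = 28,   a_m = 28)),
  chromosomes = data.frame(name = c("chr1", "chr2", "chrX", "chrY"),
                           length = c(20e6, 20e6, 10e6, 5e6),
                           is_x = c(FALSE, FALSE, TRUE, FALSE),
                           is_y = c(FALSE, FALSE, FALSE, TRUE)),
  ancestral_a = 28, mutation_scale = 2, seed = 5)

report <- run_pipeline(cfg)
print(report)
#> pipeline report (seed 5, 16 individuals)
#>   mean fragment length (bp): WE = 58754, EA = 63522
#>   generations since admixture: WE = 1454, EA = 1364
#>   derived-allele excess: 1.014% total, 1.521% post-split
#>   estimated a_x = 25.50 y vs a_z = 28.00 y (diff 2.50 y)
```

Both clocks point the same way: the short-generation group WE has
*shorter* HMM-called archaic fragments (58.8 vs 63.5 kb, hence more
generations since admixture) and has accumulated *more* derived alleles
(1.01% excess over the whole history). Rescaling the excess to the
post-split epoch (× 60,000/40,000) and inverting the pedigree model
recovers an estimated generation interval of 25.5 years against the
28-year reference — close to the simulated truth of 25.3, with the
remaining gap dominated by Poisson counting noise at this deliberately
small cohort size.

The equation-level estimator can also be used directly:

```r
estimate_parental_age(1.0164, 28)
#> generation estimate: d_ratio = 1.0164, a_z = 28.00 y -> a_x = 25.32 y (difference 2.68 y)
```

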