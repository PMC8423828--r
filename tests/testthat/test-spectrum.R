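all_raw_contexts <- function() {
  base <- c("A", "C", "G", "T")
  g <- expand.grid(ancestral = base, derived = base, ctx5 = base,
                   ctx3 = base, stringsAsFactors = FALSE)
  g[g$ancestral != g$derived, ]
}

revcomp_records <- function(r) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(ancestral = unname(comp[r$ancestral]),
             derived = unname(comp[r$derived]),
             ctx5 = unname(comp[r$ctx3]), ctx3 = unname(comp[r$ctx5]),
             stringsAsFactors = FALSE)
}

test_that("all 192 raw contexts collapse onto exactly 96 classes", {
  raw <- all_raw_contexts()
  expect_equal(nrow(raw), 192)
  cls <- classify_mutations(raw)
  expect_equal(sort(unique(cls$type96)), sort(mutation_types_96()))
  expect_equal(length(unique(cls$type96)), 96)
  # each class is hit by exactly two raw contexts (the two strands)
  expect_true(all(table(cls$type96) == 2))
})

test_that("classification is invariant under reverse complement", {
  raw <- all_raw_contexts()
  cls <- classify_mutations(raw)
  rc <- classify_mutations(revcomp_records(raw))
  expect_equal(cls$type96, rc$type96)
  expect_equal(cls$type9, rc$type9)
})

test_that("named signatures classify correctly on both strands", {
  tcc <- classify_mutations(data.frame(ancestral = "C", derived = "T",
                                       ctx5 = "T", ctx3 = "C"))
  expect_equal(tcc$type9, "TCC>TTC")
  expect_equal(tcc$type96, "T[C>T]C")
  # GGA>GAA is the reverse strand of TCC>TTC
  gga <- classify_mutations(data.frame(ancestral = "G", derived = "A",
                                       ctx5 = "G", ctx3 = "A"))
  expect_equal(gga$type9, "TCC>TTC")
  cpg <- classify_mutations(data.frame(ancestral = "C", derived = "T",
                                       ctx5 = "A", ctx3 = "G"))
  expect_equal(cpg$type9, "CpG>TpG")
  other_ct <- classify_mutations(data.frame(ancestral = "C", derived = "T",
                                            ctx5 = "A", ctx3 = "A"))
  expect_equal(other_ct$type9, "C>T'")
  n_rec <- classify_mutations(data.frame(ancestral = c("C", "N"),
                                         derived = c("T", "A"),
                                         ctx5 = c("A", "C"),
                                         ctx3 = c("A", "C")))
  expect_equal(nrow(n_rec), 1)
  expect_equal(attr(n_rec, "skipped"), 1)
})

worked_example_records <- function(dosage = 1L) {
  # 100 mutations: C>T 40 of which CpG 10, TCC 5, C>T' 25; C>A 60
  rec <- rbind(
    data.frame(ancestral = "C", derived = "T", ctx5 = "A",
               ctx3 = "G")[rep(1, 10), ],
    data.frame(ancestral = "C", derived = "T", ctx5 = "T",
               ctx3 = "C")[rep(1, 5), ],
    data.frame(ancestral = "C", derived = "T", ctx5 = "A",
               ctx3 = "A")[rep(1, 25), ],
    data.frame(ancestral = "C", derived = "A", ctx5 = "C",
               ctx3 = "C")[rep(1, 60), ])
  rec$chrom <- "chr1"
  rec$pos <- seq_len(nrow(rec))
  rec$dosage <- dosage
  rec$individual <- "ind1"
  rec
}

test_that("fractions share one denominator and C>T subtypes sum to C>T", {
  counts <- spectrum_counts(worked_example_records())
  expect_equal(unname(counts$denominator), 100)
  fr <- spectrum_fractions(counts)
  expect_equal(unname(fr[1, "C>T"]), 0.40)
  expect_equal(unname(fr[1, "CpG>TpG"]), 0.10)
  expect_equal(unname(fr[1, "TCC>TTC"]), 0.05)
  expect_equal(unname(fr[1, "C>T'"]), 0.25)
  expect_equal(unname(fr[1, "C>A"]), 0.60)
  expect_equal(sum(fr[1, mutation_types_6()]), 1)
  expect_equal(sum(fr[1, c("CpG>TpG", "TCC>TTC", "C>T'")]),
               unname(fr[1, "C>T"]))
  # doubling all counts (dosage 2) leaves every fraction unchanged
  fr2 <- spectrum_fractions(spectrum_counts(worked_example_records(2L)))
  expect_equal(fr2, fr)
  expect_equal(
    unname(spectrum_counts(worked_example_records(2L))$denominator), 200)
})

test_that("a single-type spectrum has fraction one and the rest zero", {
  rec <- data.frame(ancestral = "C", derived = "A", ctx5 = "A", ctx3 = "A",
                    chrom = "chr1", pos = 1:7, dosage = 1L,
                    individual = "x")
  fr <- spectrum_fractions(spectrum_counts(rec))
  expect_equal(unname(fr[1, "C>A"]), 1)
  expect_equal(sum(fr[1, ]), 1)  # all other eight types are zero
  empty <- rec[0, ]
  expect_error(spectrum_counts(empty)$denominator, NA)
})

test_that("per-chromosome counts sum to the genome-wide counts", {
  rec <- worked_example_records()
  rec$chrom <- rep(c("chr1", "chr2"), length.out = nrow(rec))
  by_chrom <- spectrum_counts(rec, by = "individual_chrom")
  genome <- spectrum_counts(rec)
  expect_equal(colSums(by_chrom$counts96), genome$counts96["ind1", ])
  expect_equal(sum(by_chrom$denominator), unname(genome$denominator))
})

test_that("variant filters drop outgroup, multi-allelic and masked records", {
  rec <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 30, 40, 50),
                    ancestral = c("C", "C", "C", "C", "T", "T"),
                    derived = c("T", "A", "T", "G", "C", "G"),
                    stringsAsFactors = FALSE)
  out <- filter_variants(rec,
                         outgroup_sites = data.frame(chrom = "chr1", pos = 10),
                         masks = data.frame(chrom = "chr1", start = 45,
                                            end = 60))
  expect_equal(unname(out$dropped), c(1, 2, 1))
  expect_equal(out$records$pos, c(20, 40))
  # no filters: everything retained
  clean <- filter_variants(rec[1:2, ])
  expect_equal(nrow(clean$records), 2)
  expect_equal(clean$retained_fraction, 1)
})
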