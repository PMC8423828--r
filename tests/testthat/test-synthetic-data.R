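test_that("cohort configuration enforces its invariants", {
  expect_error(cohort_config(list(group_spec("A", 2)),
                             admixture_fraction = 1.2), "admixture_fraction")
  expect_error(cohort_config(list(group_spec("A", 2)),
                             admixture_time_years = 30000,
                             split_time_years = 40000), "admixture_time")
  expect_error(cohort_config(list(group_spec("A", 2,
                                             sampling_time_years = 60000))),
               "sampled at or before")
  expect_error(group_spec("A", 2, a_f = 9), "a_f")
  expect_error(cohort_config(list(group_spec("A", 1), group_spec("A", 1))),
               "unique")
  expect_error(cohort_config(list(group_spec("A", 1)),
                             second_pulse = list(group = "Z",
                                                 time_years = 1000,
                                                 fraction = 0.1)),
               "unknown group")
})

test_that("identical seeds reproduce identical outputs, and substreams
           isolate individuals from config growth", {
  cfg <- test_config(seed = 5)
  f1 <- simulate_fragment_decay(cfg, "A")
  f2 <- simulate_fragment_decay(cfg, "A")
  expect_identical(f1, f2)
  v1 <- simulate_mutations(cfg, "A")
  expect_identical(v1, simulate_mutations(cfg, "A"))
  # adding a group leaves existing groups' draws untouched
  cfg3 <- cohort_config(
    groups = c(cfg$groups, list(group_spec("C", 2))),
    chromosomes = cfg$chromosomes, ancestral_a = 28, seed = 5)
  expect_identical(simulate_fragment_decay(cfg3, "A"), f1)
  expect_identical(simulate_mutations(cfg3, "A"), v1)
})

test_that("tracts are snapped, sorted and non-overlapping per haplotype", {
  cfg <- test_config(seed = 8)
  fr <- simulate_fragment_decay(cfg, "A")
  for (ind in fr) {
    expect_true(all(ind$start %% cfg$window_bp == 0))
    expect_true(all(ind$end %% cfg$window_bp == 0))
    expect_true(all(ind$end > ind$start))
    for (h in split(ind, list(ind$chrom, ind$haplotype))) {
      if (nrow(h) < 2) next
      expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    }
  }
  # males carry a single X haplotype
  males <- fr[paste0("A_", 3:4)]
  for (m in males)
    expect_true(all(m$haplotype[m$chrom == "chrX"] == 1))
})

test_that("sampling just after the pulse yields full-length carrier tracts", {
  cfg <- cohort_config(
    groups = list(group_spec("A", 30, sampling_time_years = 54999)),
    chromosomes = data.frame(name = "chr1", length = 20e6,
                             is_x = FALSE, is_y = FALSE),
    admixture_time_years = 55000, split_time_years = 0,
    admixture_fraction = 0.3, seed = 12)
  fr <- simulate_fragment_decay(cfg, "A")
  lens <- unlist(lapply(fr, function(f) f$end - f$start))
  expect_true(all(lens == 20e6))  # every tract is the whole chromosome
  # carrier haplotype fraction near the admixture fraction; the variance is
  # dominated by the finite ancestral pool (n_pool haplotypes), not by the
  # number of sampled haplotypes
  expect_lt(abs(length(lens) / 60 - 0.3), 3 * sqrt(0.3 * 0.7 / cfg$n_pool))
})

test_that("mean tract length follows the exponential decay closed form", {
  cfg <- cohort_config(
    groups = list(group_spec("A", 15)),
    chromosomes = data.frame(name = c("chr1", "chr2"), length = 50e6,
                             is_x = FALSE, is_y = FALSE),
    admixture_time_years = 43500, split_time_years = 40000,
    ancestral_a = 29, admixture_fraction = 0.02,
    recomb_rate_cM_Mb = 1.2, seed = 7)
  g <- lineage_generations(cfg, "A")
  expect_equal(g$g_total, 1500, tolerance = 1e-9)
  fr <- simulate_fragment_decay(cfg, "A")
  lens <- unlist(lapply(fr, function(f) f$end - f$start))
  expect_gt(length(lens), 1000)
  expected <- 1 / (1500 * 0.98) / 1.2e-8
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se)
})

test_that("dilution removes archaic sequence without shortening tracts", {
  chroms <- data.frame(name = c("chr1", "chr2"), length = 50e6,
                       is_x = FALSE, is_y = FALSE)
  grp <- list(group_spec("A", 15))
  cfg0 <- cohort_config(grp, chroms, admixture_fraction = 0.04, seed = 3)
  cfg1 <- cohort_config(grp, chroms, admixture_fraction = 0.04,
                        dilution = list(group = "A", proportion = 0.3),
                        seed = 3)
  l0 <- unlist(lapply(simulate_fragment_decay(cfg0, "A"),
                      function(f) f$end - f$start))
  l1 <- unlist(lapply(simulate_fragment_decay(cfg1, "A"),
                      function(f) f$end - f$start))
  expect_lt(abs(sum(l1) / sum(l0) - 0.7), 0.05)
  z <- (mean(l1) - mean(l0)) /
    sqrt(stats::sd(l1)^2 / length(l1) + stats::sd(l0)^2 / length(l0))
  expect_lt(abs(z), 3)
})

test_that("expected mutation counts respect symmetry and the epoch ratio", {
  cfg <- cohort_config(
    groups = list(group_spec("A", 2, a_f = 29, a_m = 29),
                  group_spec("B", 2, a_f = 29, a_m = 29)),
    ancestral_a = 29, seed = 1)
  expect_equal(expected_variant_count(cfg, "A"),
               expected_variant_count(cfg, "B"))
  # a = 28 vs 32 over a 40,000-year private epoch after 20,000 shared years
  cfg2 <- cohort_config(
    groups = list(group_spec("X", 40, a_f = 28, a_m = 28),
                  group_spec("Z", 40, a_f = 32, a_m = 32)),
    chromosomes = data.frame(name = "chr1", length = 40e6,
                             is_x = FALSE, is_y = FALSE),
    ooa_time_years = 60000, split_time_years = 40000,
    ancestral_a = 30, mutation_scale = 4, seed = 44)
  mu_y <- function(a) 9.66 / a + 1.88
  closed <- (20000 * mu_y(30) + 40000 * mu_y(28)) /
    (20000 * mu_y(30) + 40000 * mu_y(32))
  expect_equal(expected_variant_count(cfg2, "X") /
                 expected_variant_count(cfg2, "Z"), closed,
               tolerance = 1e-12)
  dx <- sum(simulate_mutations(cfg2, "X")$dosage)
  dz <- sum(simulate_mutations(cfg2, "Z")$dosage)
  se_ratio <- closed * sqrt(1 / dx + 1 / dz)
  expect_lt(abs(dx / dz - closed), 3 * se_ratio)
})

test_that("variants land in the callable mask with consistent contexts", {
  cfg <- test_config(n = 3, seed = 23)
  v <- simulate_mutations(cfg, "A")
  masks <- callable_masks(cfg)
  gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::countOverlaps(
    gr, GenomicRanges::GRanges(masks$callable$chrom,
                               IRanges::IRanges(masks$callable$start + 1,
                                                masks$callable$end)))
  expect_true(all(hits > 0))
  expect_true(all(v$dosage %in% c(1L, 2L)))
  cls <- classify_mutations(v)
  expect_equal(attr(cls, "skipped"), 0)
  expect_true(all(cls$type9 %in% mutation_types_9()))
})

test_that("window counts vanish with zero callability and match the
           Poisson mean inside long tracts", {
  truth <- list(A_1 = data.frame(chrom = "chr1",
                                 start = seq(1e6, 17e6, by = 2e6),
                                 end = seq(1e6, 17e6, by = 2e6) + 2e5,
                                 haplotype = 1))
  dead <- cohort_config(list(group_spec("A", 1)),
                        chromosomes = data.frame(name = "chr1", length = 20e6,
                                                 is_x = FALSE, is_y = FALSE),
                        callability_beta = c(0, 1), seed = 2)
  tr0 <- simulate_window_counts(truth, dead)$A_1
  expect_true(all(tr0$count == 0))
  cfg <- cohort_config(list(group_spec("A", 1)),
                       chromosomes = data.frame(name = "chr1", length = 20e6,
                                                is_x = FALSE, is_y = FALSE),
                       lambda_background = 0.02, lambda_archaic = 0.4,
                       seed = 2)
  tr <- simulate_window_counts(truth, cfg)$A_1
  gr <- bed_idx <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(truth$A_1)))
    bed_idx <- bed_idx | (tr$start >= truth$A_1$start[i] &
                            tr$end <= truth$A_1$end[i])
  inside <- tr[bed_idx, ]
  expected <- 0.4 * mean(inside$callability * inside$mutrate_scale)
  se <- stats::sd(inside$count) / sqrt(nrow(inside))
  expect_lt(abs(mean(inside$count) - expected), 3 * se)
  expect_lt(mean(tr$count[!bed_idx]), 0.05)
})

test_that("cohort bundles, writers and the config YAML round-trip", {
  cfg <- test_config(n = 2, seed = 66)
  co <- simulate_cohort(cfg, window_tracks = FALSE)
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(nrow(co$metadata), 4)
  expect_setequal(co$metadata$group, c("A", "B"))
  expect_equal(names(co$recomb_maps), c("A", "B"))
  tmp <- tempfile(fileext = ".tsv")
  write_variants_tsv(co$variants, tmp)
  back <- read_variants_tsv(tmp)
  expect_equal(nrow(back), nrow(co$variants))
  expect_equal(back$pos, co$variants$pos)
  cy <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, cy)
  cfg2 <- read_cohort_config(cy)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$spectrum, cfg$spectrum)
  expect_identical(simulate_fragment_decay(cfg2, "A"),
                   simulate_fragment_decay(cfg, "A"))
})
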