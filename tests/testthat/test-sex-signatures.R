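test_that("X-to-A ratio is the density ratio with the female convention", {
  expect_equal(x_to_a_ratio(100, 1000, 300, 3000), 1)
  expect_equal(x_to_a_ratio(50, 1000, 300, 3000), 0.5)
  expect_error(x_to_a_ratio(50, 1000, 300, 3000, sex = "M"), "females only")
  expect_equal(x_to_a_ratio(50, 1000, 300, 3000, sex = "M",
                            require_female = FALSE), 0.5)
  expect_error(x_to_a_ratio(50, 1000, 0, 3000), "positive")
  expect_error(x_to_a_ratio(50, 0, 300, 3000), "positive")
})

test_that("a wider paternal-maternal age gap raises the expected X-to-A ratio", {
  abar <- 29
  gaps <- c(0, 2, 4, 8, 12)
  ratios <- vapply(gaps, function(d)
    expected_x_to_a(abar + d / 2, abar - d / 2), numeric(1))
  expect_true(all(diff(ratios) > 0))
  # equal ages: X rate uses 2/3 maternal exposure, below the autosomal mix
  expect_lt(expected_x_to_a(29, 29), 1)
})

test_that("simulated X and autosome counts match the exposure expectations", {
  cfg <- test_config(n = 12, mutation_scale = 3, seed = 31)
  v <- simulate_mutations(cfg, "A")
  sexes <- individual_sexes <- rep(c("F", "M"), each = 6)
  d_by <- tapply(v$dosage, list(v$individual, v$chrom), sum)
  d_by[is.na(d_by)] <- 0
  females <- paste0("A_", 1:6)
  obs_x <- sum(d_by[females, "chrX"])
  exp_x <- 6 * expected_variant_count(cfg, "A", "X", "F")
  expect_lt(abs(obs_x - exp_x) / sqrt(exp_x), 3)
  obs_a <- sum(d_by[, "chr1"])
  exp_a <- 12 * expected_variant_count(cfg, "A", "autosome")
  expect_lt(abs(obs_a - exp_a) / sqrt(exp_a), 3)
  # Y carries counts for males only, from the paternal lineage
  males <- paste0("A_", 7:12)
  expect_equal(sum(d_by[females, "chrY"]), 0)
  obs_y <- sum(d_by[males, "chrY"])
  exp_y <- 6 * expected_variant_count(cfg, "A", "Y", "M")
  expect_lt(abs(obs_y - exp_y) / sqrt(exp_y), 3)
})

test_that("clustered C>G ratio follows the stated window formulas", {
  w <- data.frame(d_cg = c(2, 4, 1, 2), d_non_cg = c(10, 10, 10, 10),
                  cdnm = c(TRUE, TRUE, FALSE, FALSE))
  out <- cg_cdnm_ratio(w)
  expect_equal(out$r, 2)
  expect_equal(out$p_bar_cdnm, 0.3)
  expect_equal(out$p_bar_non_cdnm, 0.15)
  # identical composition everywhere: r = 1
  same <- data.frame(d_cg = 3, d_non_cg = 30,
                     cdnm = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cg_cdnm_ratio(same)$r, 1)
  # invariant to uniform scaling of all counts
  w3 <- w; w3$d_cg <- w3$d_cg * 3; w3$d_non_cg <- w3$d_non_cg * 3
  expect_equal(cg_cdnm_ratio(w3)$r, 2)
  # zero non-C>G windows are skipped and reported
  wz <- rbind(w, data.frame(d_cg = 1, d_non_cg = 0, cdnm = TRUE))
  out_z <- cg_cdnm_ratio(wz)
  expect_equal(out_z$n_skipped, 1)
  expect_equal(out_z$r, 2)
  expect_error(cg_cdnm_ratio(w[w$cdnm, ]), "each")
  wt <- cg_cdnm_ratio(w, weighted = TRUE)
  expect_equal(wt$r, (6 / 20) / (3 / 20))
})

test_that("generator cDNM inflation raises the C>G ratio with maternal age", {
  r_at <- function(a_m, gamma) {
    cfg <- cohort_config(
      groups = list(group_spec("A", 6, a_f = 29, a_m = a_m)),
      chromosomes = data.frame(name = "chr1", length = 30e6,
                               is_x = FALSE, is_y = FALSE),
      cdnm_gamma = gamma, cdnm_fraction = 0.3, mutation_scale = 8,
      seed = 77)
    v <- simulate_mutations(cfg, "A")
    cls <- classify_mutations(v)
    win <- cdnm_windows(cfg)
    wi <- (cls$pos - 1) %/% 1e6 + 1
    cg <- tapply(cls$dosage * (cls$type6 == "C>G"), wi, sum)
    non <- tapply(cls$dosage * (cls$type6 != "C>G"), wi, sum)
    w <- data.frame(d_cg = as.numeric(cg), d_non_cg = as.numeric(non),
                    cdnm = win$cdnm[as.integer(names(cg))])
    cg_cdnm_ratio(w)$r
  }
  # no inflation: composition identical inside and outside cDNM windows
  expect_lt(abs(r_at(30, 0) - 1), 0.1)
  # inflation grows with maternal age under a positive slope
  r_young <- r_at(22, 0.05)
  r_old <- r_at(42, 0.05)
  expect_gt(r_old, r_young)
  expect_gt(r_old, 1.5)
})

test_that("paternal yearly-rate sensitivity sits in the expected band", {
  expect_equal(y_rate_sensitivity(28), 100 * (6.05 / 28^2) / (6.05 / 28 + 1.51))
  expect_equal(round(y_rate_sensitivity(28), 3), 0.447)
  expect_equal(round(y_rate_sensitivity(29), 3), 0.419)
  a <- seq(20, 40, by = 1)
  expect_true(all(diff(y_rate_sensitivity(a)) < 0))
  expect_true(all(y_rate_sensitivity(c(28, 29, 30)) > 0.38 &
                    y_rate_sensitivity(c(28, 29, 30)) < 0.5))
  expect_error(y_rate_sensitivity(0), "positive")
})

test_that("null cohorts show no significant sex-signature group differences", {
  cfg <- cohort_config(
    groups = list(group_spec("A", 8, a_f = 28, a_m = 28),
                  group_spec("B", 8, a_f = 28, a_m = 28)),
    chromosomes = data.frame(name = c("chr1", "chrX"),
                             length = c(20e6, 10e6),
                             is_x = c(FALSE, TRUE), is_y = FALSE),
    cdnm_gamma = 0, mutation_scale = 2, seed = 19)
  xa <- lapply(c("A", "B"), function(g) {
    v <- simulate_mutations(cfg, g)
    vapply(paste0(g, "_", 1:4), function(i) {   # females
      vi <- v[v$individual == i, ]
      x_to_a_ratio(sum(vi$dosage[vi$chrom == "chrX"]), 10e6,
                   sum(vi$dosage[vi$chrom == "chr1"]), 20e6)
    }, numeric(1))
  })
  p <- permutation_F(xa, n_perm = 999, seed = 4)$p
  expect_gt(p, 0.05)
})
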