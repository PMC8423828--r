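toy_dnm <- function() {
  as_dnm_table(data.frame(
    proband = c("p1", "p2", "p3"),
    father_age = c(30, 30, 40), mother_age = c(30, 30, 40),
    "C>A" = c(10, 20, 10), "C>G" = c(5, 5, 5), "T>A" = c(5, 5, 5),
    "T>C" = c(20, 20, 20), "T>G" = c(5, 5, 5), "CpG>TpG" = c(10, 10, 10),
    "TCC>TTC" = c(5, 5, 2), "C>T'" = c(20, 15, 18),
    check.names = FALSE))
}

test_that("DNM aggregation groups by rounded mean parental age", {
  agg <- aggregate_dnm(toy_dnm())
  # the lone proband at age 40 is discarded; the two at 30 form one point
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mean_parental_age, 30)
  expect_equal(agg$n_probands, 2)
  # fraction of summed counts, not mean of per-proband fractions
  # (summed denominator: 30 + 10 + 65 + 10 + 40 + 10 = 165)
  expect_equal(agg[["C>A"]], 30 / 165)
  mean_of_fracs <- mean(c(10 / 80, 20 / 95))
  expect_false(isTRUE(all.equal(agg[["C>A"]], mean_of_fracs)))
  expect_equal(agg[["C>T"]], (10 + 10 + 5 + 5 + 20 + 15) / 165)
  # keeping singletons retains both age keys
  agg1 <- aggregate_dnm(toy_dnm(), min_probands = 1)
  expect_equal(nrow(agg1), 2)
})

test_that("DNM table validation enforces schema and plausible ages", {
  bad <- data.frame(proband = "p", father_age = 30, mother_age = 30)
  expect_error(as_dnm_table(bad), "missing columns")
  young <- toy_dnm()
  class(young) <- "data.frame"
  young$mother_age[1] <- 9
  expect_error(as_dnm_table(young), "exceed 10")
})

test_that("weighted age fits reduce to OLS under equal weights", {
  set.seed(2)
  n <- 12
  agg <- data.frame(mean_parental_age = seq(20, 42, length.out = n),
                    n_probands = 5, check.names = FALSE)
  for (tp in mutation_types_9()) agg[[tp]] <- 0.1 + rnorm(n, 0, 0.01)
  fits_w <- fit_type_vs_age(agg)
  ols <- stats::lm(agg[["TCC>TTC"]] ~ agg$mean_parental_age)
  expect_equal(fits_w$slope[fits_w$type == "TCC>TTC"],
               unname(coef(ols)[2]), tolerance = 1e-12)
  # doubling all weights changes nothing
  agg2 <- agg; agg2$n_probands <- 10
  expect_equal(fit_type_vs_age(agg2)$slope, fits_w$slope, tolerance = 1e-12)
  # unequal weights do matter
  agg3 <- agg; agg3$n_probands <- c(rep(1, 6), rep(40, 6))
  expect_false(isTRUE(all.equal(fit_type_vs_age(agg3)$slope, fits_w$slope)))
})

test_that("per-type age slopes are recovered from simulated trio data", {
  truth <- default_spectrum_law()
  hits <- 0
  for (rep in 1:6) {
    tab <- simulate_dnm_table(600, seed = 100 + rep)
    fits <- fit_type_vs_age(aggregate_dnm(tab))
    f <- fits[fits$type == "TCC>TTC", ]
    if (abs(f$slope - truth["TCC>TTC", "slope"]) < 2 * f$slope_se)
      hits <- hits + 1
  }
  expect_gte(hits, 4)  # ~95% coverage expected from a 2 SE band
  # the decreasing TCC>TTC and increasing C>G directions are recovered
  fits <- fit_type_vs_age(aggregate_dnm(simulate_dnm_table(2000, seed = 1)))
  expect_lt(fits$slope[fits$type == "TCC>TTC"], 0)
  expect_gt(fits$slope[fits$type == "C>G"], 0)
})

test_that("fraction-vs-fragment-length fits flag constant and degenerate input", {
  frac <- matrix(0.1, nrow = 5, ncol = 9,
                 dimnames = list(paste0("i", 1:5), mutation_types_9()))
  lens <- stats::setNames(c(5, 6, 7, 8, 9) * 1e4, rownames(frac))
  fits <- fit_type_vs_fraglen(frac, lens)
  expect_equal(fits$slope, rep(0, 9))
  expect_error(fit_type_vs_fraglen(frac[1:2, ], lens[1:2]), "three")
  expect_error(fit_type_vs_fraglen(frac, stats::setNames(rep(1, 5),
                                                         rownames(frac))),
               "constant")
})

test_that("fragment-length slopes mirror the latent age law", {
  # fractions generated from the age law; fragment length linear in age,
  # length_kb = 200 - 5 * abar, so beta_len = beta_age / (-5 kb/yr)
  set.seed(33)
  law <- default_spectrum_law()
  abar <- runif(40, 22, 36)
  len <- 200 - 5 * abar
  frac <- vapply(rownames(law), function(tp)
    law[tp, "intercept"] + law[tp, "slope"] * (abar - 29) +
      rnorm(40, 0, 5e-4), numeric(40))
  frac9 <- cbind(frac[, c("C>A", "C>G")],
                 "C>T" = rowSums(frac[, c("CpG>TpG", "TCC>TTC", "C>T'")]),
                 frac[, c("T>A", "T>C", "T>G", "CpG>TpG", "TCC>TTC", "C>T'")])
  rownames(frac9) <- paste0("i", 1:40)
  fits <- fit_type_vs_fraglen(frac9[, mutation_types_9()],
                              stats::setNames(len, rownames(frac9)))
  f <- fits[fits$type == "TCC>TTC", ]
  expect_lt(abs(f$slope - law["TCC>TTC", "slope"] / -5), 2 * f$slope_se)
  expect_gt(f$slope, 0)  # decreasing in age means increasing in length here
})

test_that("slope concordance recovers identity, scaling and mismatches", {
  set.seed(4)
  fits_b <- data.frame(type = mutation_types_9(),
                       slope = rnorm(9, 0, 1e-3))
  fits_a <- fits_b
  cc <- compare_slopes(fits_a, fits_b)
  expect_equal(cc$slope, 1, tolerance = 1e-9)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  fits_a2 <- fits_b; fits_a2$slope <- 2 * fits_b$slope
  expect_equal(compare_slopes(fits_a2, fits_b)$slope, 2, tolerance = 1e-9)
  bad <- fits_b; bad$type[1] <- "X>Y"
  expect_error(compare_slopes(fits_a, bad), "mismatched")
})

test_that("restricting the parental age gap leaves age slopes stable", {
  tab <- simulate_dnm_table(1500, seed = 9)
  fits_all <- fit_type_vs_age(aggregate_dnm(tab))
  near <- tab[abs(tab$father_age - tab$mother_age) <= 3, ]
  class(near) <- class(tab)
  fits_near <- fit_type_vs_age(aggregate_dnm(near))
  for (tp in c("TCC>TTC", "C>G", "T>C")) {
    a <- fits_all[fits_all$type == tp, ]
    b <- fits_near[fits_near$type == tp, ]
    expect_lt(abs(a$slope - b$slope), 2 * (a$slope_se + b$slope_se))
  }
})
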