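stationary_track <- function(n, lambda_bg = 0.02, lambda_arc = 0.4,
                             p_flip = 0.005, seed = 1, chrom = "chr1") {
  set.seed(seed)
  st <- integer(n)
  st[1] <- stats::rbinom(1, 1, 0.5)
  flips <- stats::runif(n) < p_flip
  for (w in 2:n) st[w] <- if (flips[w]) 1L - st[w - 1] else st[w - 1]
  call <- stats::rbeta(n, 20, 2)
  sc <- stats::rgamma(n, 50, 50)
  lam <- ifelse(st == 1, lambda_arc, lambda_bg)
  list(track = data.frame(chrom = chrom, start = (0:(n - 1)) * 1000,
                          end = (1:n) * 1000,
                          count = stats::rpois(n, lam * call * sc),
                          callability = call, mutrate_scale = sc,
                          stringsAsFactors = FALSE),
       states = st)
}

test_that("EM increases the likelihood monotonically and converges", {
  d <- stationary_track(20000, seed = 2)
  fit <- fit_hmm(d$track)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_gt(fit$params$lambda_archaic, fit$params$lambda_background)
})

test_that("emission rates are recovered on self-generated data", {
  d <- stationary_track(60000, seed = 4, p_flip = 0.001)
  fit <- fit_hmm(d$track)
  expect_lt(abs(fit$params$lambda_background - 0.02) / 0.02, 0.1)
  expect_lt(abs(fit$params$lambda_archaic - 0.4) / 0.4, 0.1)
  expect_gt(fit$params$p_stay_archaic, 0.99)
})

test_that("equal emission rates still terminate without error", {
  d <- stationary_track(5000, lambda_bg = 0.2, lambda_arc = 0.2, seed = 5)
  fit <- fit_hmm(d$track, max_iter = 50)
  expect_s3_class(fit, "hmm_fit")
  expect_true(is.finite(fit$loglik))
})

test_that("an all-zero track is flagged as a degenerate fit", {
  tr <- data.frame(chrom = "chr1", start = (0:499) * 1000,
                   end = (1:500) * 1000, count = 0L,
                   callability = 0.9, mutrate_scale = 1)
  expect_warning(fit <- fit_hmm(tr), "degenerate")
  expect_true(fit$degenerate)
})

test_that("decoding returns nothing on empty tracks and respects the
           posterior threshold monotonically", {
  tr <- data.frame(chrom = "chr1", start = (0:999) * 1000,
                   end = (1:1000) * 1000, count = 0L,
                   callability = 0.9, mutrate_scale = 1)
  dec <- decode_fragments(tr, hmm_params())
  expect_equal(nrow(dec), 0)
  d <- stationary_track(20000, seed = 7, p_flip = 0.002)
  fit <- fit_hmm(d$track)
  counts <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.99), function(th)
    sum(decode_fragments(d$track, fit, th)$high_confidence), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(decode_fragments(d$track, fit, 0.4), "posterior_threshold")
  expect_error(decode_fragments(d$track, fit, 1.2), "posterior_threshold")
})

test_that("posteriors are proper probabilities and decoding is invariant
           to chromosome relabelling", {
  d <- stationary_track(5000, seed = 9)
  fit <- fit_hmm(d$track)
  post <- hmm_posteriors(d$track, fit)
  expect_true(all(post$posterior_archaic >= 0 & post$posterior_archaic <= 1))
  dec1 <- decode_fragments(d$track, fit)
  tr2 <- d$track
  tr2$chrom <- "chrOther"
  dec2 <- decode_fragments(tr2, fit)
  expect_equal(dec1$start, dec2$start)
  expect_equal(dec1$mean_posterior, dec2$mean_posterior)
})

test_that("called fragments bridge callability dips inside a tract", {
  n <- 3000
  count <- rep(0L, n)
  call <- rep(0.9, n)
  arc <- 1500:1600                  # one planted 100-window tract
  count[arc] <- stats::rpois(length(arc), 0.5)
  count[seq(1502, 1598, by = 3)] <- 1L   # guarantee interior evidence
  dip <- 1545:1555
  call[dip] <- 0.01                 # missing windows inside the tract
  count[dip] <- 0L
  tr <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1000,
                   end = (1:n) * 1000, count = count, callability = call,
                   mutrate_scale = 1)
  dec <- decode_fragments(tr, hmm_params(lambda_background = 0.02,
                                         lambda_archaic = 0.5))
  # the dip does not split the fragment
  cover <- dec[dec$start <= 1545 * 1000 & dec$end >= 1556 * 1000, ]
  expect_equal(nrow(cover), 1)
})

test_that("window tracks must tile chromosomes contiguously", {
  bad <- data.frame(chrom = "chr1", start = c(0, 2000), end = c(1000, 3000),
                    count = 0L, callability = 1, mutrate_scale = 1)
  expect_error(fit_hmm(bad), "tile")
  short <- data.frame(chrom = "chr1", start = (0:9) * 1000,
                      end = (1:10) * 1000, count = 1L,
                      callability = 1, mutrate_scale = 1)
  expect_error(fit_hmm(short), "at least 100")
})
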