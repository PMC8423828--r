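#' Summary statistics of a fragment-length sample
#'
#' @param lengths Numeric vector of fragment lengths (bp), n >= 1.
#' @return A `fragment_summary`: list with `n`, `mean`, `median`, `sd`
#'   (unbiased; 0 by convention for n = 1), and `se = sd/sqrt(n)`.
#' @examples
#' summarize_fragments(c(50, 150))  # mean 100, sd ~70.71, se 50
#' @export
summarize_fragments <- function(lengths) {
  if (length(lengths) < 1) stop("need at least one fragment length")
  n <- length(lengths)
  s <- if (n > 1) stats::sd(lengths) else 0
  structure(list(n = n, mean = mean(lengths), median = stats::median(lengths),
                 sd = s, se = s / sqrt(n)),
            class = "fragment_summary")
}

#' @export
print.fragment_summary <- function(x, ...) {
  cat(sprintf("n = %d fragments: mean = %.2f, median = %.2f, sd = %.2f, se = %.2f\n",
              x$n, x$mean, x$median, x$sd, x$se))
  invisible(x)
}

#' Bootstrap confidence interval for an arbitrary statistic
#'
#' Resamples the data with replacement `n_boot` times and forms the CI from
#' the bootstrap sampling distribution.  The default `"normal"` method uses
#' bootstrap-mean +/- z * bootstrap-sd; `"percentile"` uses the empirical
#' quantiles of the bootstrap distribution.
#'
#' @param values Numeric vector, n >= 2.
#' @param statistic Function of a numeric vector returning a scalar
#'   (default `mean`).
#' @param n_boot Number of bootstrap resamples (default 100000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed; results are bit-reproducible given
#'   (data, seed, n_boot).
#' @param method `"normal"` (default) or `"percentile"`.
#' @return A `bootstrap_ci`: list with `point` (observed statistic), `lo`,
#'   `hi`, `boot_mean`, `boot_sd`, `n_boot`, `level`, `method`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 100000,
                         level = 0.95, seed = 1L,
                         method = c("normal", "percentile")) {
  method <- match.arg(method)
  if (length(values) < 2) stop("need at least two values to bootstrap")
  n <- length(values)
  boot <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    if (identical(statistic, mean)) {
      colMeans(matrix(values[idx], nrow = n))
    } else {
      apply(idx, 2, function(i) statistic(values[i]))
    }
  })
  bm <- mean(boot); bs <- stats::sd(boot)
  if (method == "normal") {
    z <- stats::qnorm((1 + level) / 2)
    lo <- bm - z * bs; hi <- bm + z * bs
  } else {
    q <- stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  structure(list(point = statistic(values), lo = lo, hi = hi,
                 boot_mean = bm, boot_sd = bs,
                 n_boot = n_boot, level = level, method = method),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.4g [%0.4g, %0.4g] (%d%% %s bootstrap CI, %d resamples)\n",
              x$point, x$lo, x$hi, round(100 * x$level), x$method, x$n_boot))
  invisible(x)
}

perm_result <- function(observed, p_one, n_perm, tails, floored) {
  p <- if (tails == 2) min(1, 2 * p_one) else p_one
  structure(list(observed = observed, p = p, n_perm = n_perm,
                 tails = tails, floored = floored),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed = %.6g, %s p %s %.3g (%d permutations%s)\n",
              x$observed, if (x$tails == 2) "two-tailed" else "one-tailed",
              if (x$floored) "<" else "=", x$p, x$n_perm,
              if (x$floored) ", floored" else ""))
  invisible(x)
}

#' Two-group permutation test on the difference of means
#'
#' The observed statistic is mean(a) - mean(b).  Group labels are permuted
#' `n_perm` times; the one-tailed fraction of permuted statistics as or
#' more extreme than the observed value in the observed direction (ties
#' count as extreme) is doubled for the two-tailed result.  If no permuted
#' value qualifies, the fraction is floored at 1/n_perm and the result is
#' flagged, so the reported p is "< 2/n_perm".
#'
#' @param a,b Numeric vectors (typically per-individual statistics), both
#'   non-empty.
#' @param n_perm Number of label permutations (default 100000).
#' @param seed Integer seed.
#' @return A `permutation_result`: `observed`, `p` (two-tailed), `n_perm`,
#'   `tails = 2`, `floored`.
#' @export
permutation_diff_means <- function(a, b, n_perm = 100000, seed = 1L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  tot <- sum(pooled)
  obs <- mean(a) - mean(b)
  perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    sa <- sum(pooled[sample.int(n, na)])
    sa / na - (tot - sa) / nb
  }, numeric(1)))
  k <- if (obs >= 0) sum(perm >= obs) else sum(perm <= obs)
  floored <- k == 0
  p_one <- max(k, 1) / n_perm
  perm_result(obs, p_one, n_perm, tails = 2, floored = floored)
}

# One-way F statistic from group values; pooled within-group df; returns 0
# when the data are all identical (0/0 guard).
f_statistic <- function(values, sizes) {
  k <- length(sizes); n <- sum(sizes)
  ends <- cumsum(sizes); starts <- c(1, utils::head(ends, -1) + 1)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (j in seq_len(k)) {
    v <- values[starts[j]:ends[j]]
    m <- mean(v)
    ssb <- ssb + sizes[j] * (m - gm)^2
    ssw <- ssw + sum((v - m)^2)
  }
  if (ssw == 0) {
    if (ssb == 0) return(0)
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Multi-group permutation test on the one-way F statistic
#'
#' Observed statistic is the one-way ANOVA F (between/within mean squares);
#' the null distribution is generated by shuffling group labels.  One-tailed
#' (large F extreme), with the same 1/n_perm floor rule as
#' [permutation_diff_means()].  All-identical data give F = 0 by
#' convention.
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed.
#' @return A `permutation_result` with `tails = 1`.
#' @export
permutation_F <- function(groups, n_perm = 100000, seed = 1L) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  obs <- f_statistic(pooled, sizes)
  perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    f_statistic(pooled[sample.int(n)], sizes)
  }, numeric(1)))
  k <- sum(perm >= obs)
  floored <- k == 0
  perm_result(obs, max(k, 1) / n_perm, n_perm, tails = 1, floored = floored)
}

#' Invert mean genetic tract length to generations since admixture
#'
#' Under the Markovian ancestry model, archaic tract lengths are
#' approximately exponential with mean \eqn{1/(g(1-\alpha))} Morgans after
#' g generations with admixture fraction \eqn{\alpha}.  Inverting with the
#' mean in centiMorgans:
#' \deqn{\hat g = \frac{100}{\bar s_{cM} (1-\alpha)}.}
#'
#' @param mean_length_cM Mean tract length in cM (> 0).
#' @param admix_fraction Admixture fraction \eqn{\alpha \in [0, 1)}.
#' @return Estimated number of generations since admixture.
#' @examples
#' estimate_generations(0.0667, 0)  # ~1499
#' @export
estimate_generations <- function(mean_length_cM, admix_fraction = 0) {
  if (mean_length_cM <= 0) stop("mean_length_cM must be positive")
  if (admix_fraction < 0 || admix_fraction >= 1)
    stop("admix_fraction must be in [0, 1)")
  100 / (mean_length_cM * (1 - admix_fraction))
}
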