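# Per-base brute-force oracle for the interval semantics, used to verify
# the IRanges-backed implementation on small random instances
# (coordinates < 1000, so position-indexed logical vectors are exact).

bf_coverage <- function(x, chroms, maxpos = 1000) {
  cov <- lapply(stats::setNames(chroms, chroms),
                function(ch) logical(maxpos))
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    cov[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  cov
}

bf_cov_to_bed <- function(cov) {
  out <- list()
  for (ch in names(cov)) {
    r <- rle(cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  x <- do.call(rbind, out)
  x <- x[order(x$chrom, x$start), ]
  rownames(x) <- NULL
  x
}

bf_merge <- function(sets, chroms, maxpos = 1000) {
  cov <- lapply(stats::setNames(chroms, chroms), function(ch) logical(maxpos))
  for (s in sets) {
    c2 <- bf_coverage(s, chroms, maxpos)
    for (ch in chroms) cov[[ch]] <- cov[[ch]] | c2[[ch]]
  }
  bf_cov_to_bed(cov)
}

bf_shared_bp <- function(a, b, chroms, maxpos = 1000) {
  ca <- bf_coverage(a, chroms, maxpos)
  cb <- bf_coverage(b, chroms, maxpos)
  sum(vapply(chroms, function(ch) sum(ca[[ch]] & cb[[ch]]), numeric(1)))
}

bf_classify <- function(ind, other, chroms, maxpos = 1000) {
  co <- bf_coverage(other, chroms, maxpos)
  shared <- vapply(seq_len(nrow(ind)), function(i)
    any(co[[ind$chrom[i]]][(ind$start[i] + 1):ind$end[i]]), logical(1))
  shared
}

bf_window_freq <- function(joined, individuals, window_bp, chroms,
                           maxpos = 1000) {
  covs <- lapply(individuals, bf_coverage, chroms = chroms, maxpos = maxpos)
  out <- list()
  for (i in seq_len(nrow(joined))) {
    s <- seq(joined$start[i], joined$end[i] - 1, by = window_bp)
    e <- pmin(s + window_bp, joined$end[i])
    ch <- joined$chrom[i]
    cnt <- vapply(seq_along(s), function(j)
      sum(vapply(covs, function(cv) any(cv[[ch]][(s[j] + 1):e[j]]),
                 logical(1))), numeric(1))
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                         count = as.integer(cnt),
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rand_interval_set <- function(n_chrom = 3, max_intervals = 20, maxpos = 1000) {
  chroms <- paste0("c", seq_len(n_chrom))
  n <- sample.int(max_intervals, 1)
  start <- sample.int(maxpos - 2, n, replace = TRUE) - 1
  len <- sample.int(80, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = pmin(start + len, maxpos),
             stringsAsFactors = FALSE)
}

# Small fast cohort config shared by generator tests.
test_config <- function(..., n = 4, seed = 1) {
  cohort_config(
    groups = list(group_spec("A", n, a_f = 28, a_m = 28),
                  group_spec("B", n, a_f = 25, a_m = 25)),
    chromosomes = data.frame(name = c("chr1", "chrX", "chrY"),
                             length = c(20e6, 10e6, 5e6),
                             is_x = c(FALSE, TRUE, FALSE),
                             is_y = c(FALSE, FALSE, TRUE)),
    ancestral_a = 28, seed = seed, ...)
}
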