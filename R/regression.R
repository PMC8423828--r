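fit_one_type <- function(y, x, w = NULL, type = "") {
  if (length(unique(x)) < 2)
    stop("predictor is constant; cannot fit slope for type ", type)
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  # summary.lm warns on an exactly collinear fit (e.g. constant fractions);
  # that degenerate case is legitimate here and reported as slope 0
  sm <- suppressWarnings(summary(fit))$coefficients
  data.frame(type = type,
             intercept = sm[1, 1], slope = sm[2, 1],
             slope_se = sm[2, 2], slope_p = sm[2, 4],
             n = length(y), weighted = !is.null(w),
             stringsAsFactors = FALSE)
}

#' Per-type linear fits of mutation fraction on mean fragment length
#'
#' For each of the nine mutation types, ordinary least squares of the
#' per-individual mutation fraction on the individual's mean archaic
#' fragment length (the generation-time proxy):
#' `lm(mutation_fraction ~ mean_fragment_length)`.
#'
#' @param fractions An individuals x 9 matrix of fractions (from
#'   [spectrum_fractions()]), rownames = individuals.
#' @param mean_fragment_length Named (or positionally matched) numeric
#'   vector of per-individual mean fragment lengths.
#' @return A data.frame with one row per type: `type`, `intercept`,
#'   `slope`, `slope_se`, `slope_p`, `n`, `weighted`.
#' @export
fit_type_vs_fraglen <- function(fractions, mean_fragment_length) {
  stopifnot(is.matrix(fractions))
  if (nrow(fractions) < 3) stop("need at least three individuals")
  if (!is.null(names(mean_fragment_length)))
    mean_fragment_length <- mean_fragment_length[rownames(fractions)]
  stopifnot(length(mean_fragment_length) == nrow(fractions))
  out <- do.call(rbind, lapply(colnames(fractions), function(tp)
    fit_one_type(fractions[, tp], mean_fragment_length, type = tp)))
  rownames(out) <- NULL
  out
}

#' Read a trio de novo mutation table
#'
#' Tab-separated, one row per proband, with columns `proband`,
#' `father_age`, `mother_age` and one count column per disjoint mutation
#' class (`C>A`, `C>G`, `T>A`, `T>C`, `T>G`, `CpG>TpG`, `TCC>TTC`,
#' `C>T'`); C>T totals are derived as the sum of the three subtypes.
#' Only single-nucleotide classes appear: indels are excluded at this
#' reader (rows with a non-missing `is_indel` truthy flag are dropped).
#'
#' @param path File path.
#' @return A `dnm_table` data.frame.
#' @export
read_dnm_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if ("is_indel" %in% names(x)) {
    x <- x[!as.logical(x$is_indel), , drop = FALSE]
    x$is_indel <- NULL
  }
  as_dnm_table(x)
}

#' Validate a per-proband DNM count table
#'
#' @param x A data.frame with columns `proband`, `father_age`,
#'   `mother_age`, and the eight disjoint count classes.
#' @return The validated data.frame with class `dnm_table`.
#' @export
as_dnm_table <- function(x) {
  need <- c("proband", "father_age", "mother_age", dnm_count_cols())
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("DNM table missing columns: ", paste(miss, collapse = ", "))
  if (any(x$father_age <= 10 | x$mother_age <= 10))
    stop("parental ages must exceed 10 years")
  if (any(as.matrix(x[dnm_count_cols()]) < 0)) stop("counts must be non-negative")
  class(x) <- c("dnm_table", class(x))
  x
}

dnm_count_cols <- function() {
  c("C>A", "C>G", "T>A", "T>C", "T>G", "CpG>TpG", "TCC>TTC", "C>T'")
}

#' Aggregate proband DNM counts by mean parental age
#'
#' Computes each proband's mean parental age `(father_age + mother_age)/2`,
#' rounds it to `digits` decimals to form the age key, sums the per-type
#' counts of all probands sharing a key, and converts the summed counts to
#' fractions under the shared-denominator rule (the fraction of summed
#' counts, not the mean of per-proband fractions).  Age keys backed by
#' fewer than `min_probands` probands are discarded.
#'
#' @param table A `dnm_table`.
#' @param digits Rounding precision of the age key (default 1).
#' @param min_probands Minimum probands per key (default 2).
#' @return A data.frame with `mean_parental_age`, `n_probands`, the nine
#'   per-type fraction columns, and `total` (the denominator).
#' @export
aggregate_dnm <- function(table, digits = 1, min_probands = 2) {
  stopifnot(inherits(table, "dnm_table"))
  key <- round((table$father_age + table$mother_age) / 2, digits)
  cnt <- rowsum(as.matrix(table[dnm_count_cols()]), key)
  n <- as.vector(table(key)[rownames(cnt)])
  keep <- n >= min_probands
  cnt <- cnt[keep, , drop = FALSE]; n <- n[keep]
  ct <- cnt[, "CpG>TpG"] + cnt[, "TCC>TTC"] + cnt[, "C>T'"]
  denom <- cnt[, "C>A"] + cnt[, "C>G"] + ct +
    cnt[, "T>A"] + cnt[, "T>C"] + cnt[, "T>G"]
  frac <- cbind(cnt[, c("C>A", "C>G"), drop = FALSE], "C>T" = ct,
                cnt[, c("T>A", "T>C", "T>G", "CpG>TpG", "TCC>TTC", "C>T'"),
                    drop = FALSE]) / denom
  out <- data.frame(mean_parental_age = as.numeric(rownames(cnt)),
                    n_probands = n, check.names = FALSE)
  out <- cbind(out, as.data.frame(frac[, mutation_types_9(), drop = FALSE],
                                  check.names = FALSE))
  out$total <- denom
  rownames(out) <- NULL
  out[order(out$mean_parental_age), ]
}

#' Per-type weighted fits of DNM fraction on mean parental age
#'
#' Weighted least squares per mutation type on the aggregated table:
#' `lm(mutation_fraction ~ mean_parental_age, weights = n_probands)`.
#'
#' @param aggregated Output of [aggregate_dnm()] (>= 3 rows).
#' @return A data.frame of nine fits as in [fit_type_vs_fraglen()].
#' @export
fit_type_vs_age <- function(aggregated) {
  if (nrow(aggregated) < 3) stop("need at least three aggregated points")
  out <- do.call(rbind, lapply(mutation_types_9(), function(tp)
    fit_one_type(aggregated[[tp]], aggregated$mean_parental_age,
                 w = aggregated$n_probands, type = tp)))
  rownames(out) <- NULL
  out
}

#' Slope-vs-slope concordance between two sets of per-type fits
#'
#' Regresses the slopes of dataset A on the slopes of dataset B across the
#' matched mutation types (OLS).  A fitted slope near 1 with intercept near
#' 0 indicates the two datasets respond to parental age the same way.
#'
#' @param fits_a,fits_b Fit tables from [fit_type_vs_fraglen()] /
#'   [fit_type_vs_age()] with matching `type` labels.
#' @return One-row data.frame: `slope`, `intercept`, `slope_se`, `slope_p`,
#'   `r_squared`, `n_types`.
#' @export
compare_slopes <- function(fits_a, fits_b) {
  if (!setequal(fits_a$type, fits_b$type) ||
      nrow(fits_a) != nrow(fits_b))
    stop("fit tables have mismatched type labels")
  b <- fits_b$slope[match(fits_a$type, fits_b$type)]
  a <- fits_a$slope
  fit <- stats::lm(a ~ b)
  # identical slope sets give an exactly perfect fit; keep summary quiet
  sm <- suppressWarnings(summary(fit))
  data.frame(slope = sm$coefficients[2, 1],
             intercept = sm$coefficients[1, 1],
             slope_se = sm$coefficients[2, 2],
             slope_p = sm$coefficients[2, 4],
             r_squared = sm$r.squared,
             n_types = nrow(fits_a))
}
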