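#' X-to-autosome derived-allele accumulation ratio
#'
#' Per-base derived-allele density on the X chromosome divided by that on
#' the autosomes: `(d_X / L_X) / (d_A / L_A)`.  Because X chromosomes spend
#' 2/3 of their history in females versus 1/2 for autosomes, the ratio
#' shifts with the male-to-female generation-interval ratio.  The standard
#' comparison uses females only (two X copies, like autosomes), enforced by
#' default.
#'
#' @param d_X,d_A Derived-allele counts on X and autosomes (>= 0).
#' @param L_X,L_A Callable base pairs on X and autosomes (> 0).
#' @param sex Optional individual sex (`"F"`/`"M"`); checked when
#'   `require_female` is TRUE and `sex` is given.
#' @param require_female Enforce the females-only convention
#'   (default TRUE).
#' @return The X-to-A ratio.
#' @examples
#' x_to_a_ratio(100, 1000, 300, 3000)  # 1
#' @export
x_to_a_ratio <- function(d_X, L_X, d_A, L_A, sex = NULL,
                         require_female = TRUE) {
  if (L_X <= 0 || L_A <= 0) stop("callable lengths must be positive")
  if (d_A <= 0) stop("autosomal derived-allele count must be positive")
  if (require_female && !is.null(sex) && toupper(substr(sex, 1, 1)) != "F")
    stop("X-to-A ratio is computed for females only (set require_female = FALSE to override)")
  (d_X / L_X) / (d_A / L_A)
}

#' C>G enrichment ratio in clustered-DNM regions
#'
#' In 1 Mb windows, the per-window ratio `p = d_C>G / d_non-C>G` is
#' averaged separately over windows flagged as clustered-de-novo-mutation
#' (cDNM) regions and over the rest of the genome; the statistic is
#' `r = p-bar_cDNM / p-bar_non-cDNM`.  `r > 1` indicates an excess of C>G
#' derived alleles in cDNM regions, the maternal-age-driven signature.
#' Windows with zero non-C>G count (p undefined) are skipped and reported.
#'
#' @param windows A data.frame with columns `d_cg`, `d_non_cg`
#'   (counts >= 0) and logical `cdnm`.
#' @param weighted If TRUE, p-bar is the count-weighted mean
#'   (sum d_cg / sum d_non_cg per class) instead of the default unweighted
#'   mean over windows.
#' @return List with `r`, `p_bar_cdnm`, `p_bar_non_cdnm`, and
#'   `n_skipped` (windows with undefined p).
#' @examples
#' w <- data.frame(d_cg = c(2, 4, 1, 2), d_non_cg = c(10, 10, 10, 10),
#'                 cdnm = c(TRUE, TRUE, FALSE, FALSE))
#' cg_cdnm_ratio(w)$r  # 2
#' @export
cg_cdnm_ratio <- function(windows, weighted = FALSE) {
  stopifnot(all(c("d_cg", "d_non_cg", "cdnm") %in% names(windows)))
  usable <- windows$d_non_cg > 0
  n_skipped <- sum(!usable)
  w <- windows[usable, , drop = FALSE]
  if (!any(w$cdnm) || !any(!w$cdnm))
    stop("need at least one usable window in each of the cDNM and non-cDNM classes")
  pbar <- function(sub) {
    if (weighted) sum(sub$d_cg) / sum(sub$d_non_cg)
    else mean(sub$d_cg / sub$d_non_cg)
  }
  p1 <- pbar(w[w$cdnm, , drop = FALSE])
  p0 <- pbar(w[!w$cdnm, , drop = FALSE])
  list(r = p1 / p0, p_bar_cdnm = p1, p_bar_non_cdnm = p0,
       n_skipped = n_skipped)
}

#' Sensitivity of the paternal yearly mutation rate to generation time
#'
#' The Y chromosome accumulates mutations through the paternal lineage
#' only, at yearly rate `mu_f(a)/a` (defaults `6.05/a + 1.51`).  This
#' returns the magnitude of its relative change per +1 year of paternal
#' age, in percent:
#' \deqn{100 \cdot \frac{6.05/a^2}{6.05/a + 1.51}.}
#' Around a ~ 28-29 years this is roughly 0.4-0.5% per year, the expected
#' per-year difference in Y-linked accumulation between populations with
#' different paternal generation intervals.
#'
#' @param a Paternal age (years, > 0).
#' @param params A [pedigree_params()] object.
#' @return Percent change in the paternal yearly rate per year of age.
#' @examples
#' y_rate_sensitivity(28)  # ~0.447
#' @export
y_rate_sensitivity <- function(a, params = pedigree_params()) {
  if (any(a <= 0)) stop("paternal age must be positive")
  icpt <- params$paternal_intercept; slope <- params$paternal_slope
  100 * (icpt / a^2) / (icpt / a + slope)
}

#' Expected X-to-A yearly accumulation ratio under the exposure model
#'
#' Closed-form expectation used by the synthetic generator: autosomes
#' accumulate `(mu_f(a_f) + mu_m(a_m)) / a-bar` per year with
#' `a-bar = (a_f + a_m)/2`, while the X lineage spends 2/3 of its time in
#' females and 1/3 in males, giving
#' `((2/3) mu_m(a_m) + (1/3) mu_f(a_f)) / a-bar_X` with
#' `a-bar_X = (2 a_m + a_f)/3`, each per callable bp with L cancelling.
#'
#' @param a_f,a_m Parental ages (years, > 0).
#' @param params A [pedigree_params()] object.
#' @return Expected (d_X/L_X)/(d_A/L_A) up to the shared time span.
#' @export
expected_x_to_a <- function(a_f, a_m, params = pedigree_params()) {
  if (any(a_f <= 0) || any(a_m <= 0)) stop("ages must be positive")
  mu_f <- params$paternal_intercept + params$paternal_slope * a_f
  mu_m <- params$maternal_intercept + params$maternal_slope * a_m
  rate_a <- (mu_f + mu_m) / ((a_f + a_m) / 2)
  rate_x <- ((2 / 3) * mu_m + (1 / 3) * mu_f) / ((2 * a_m + a_f) / 3)
  rate_x / rate_a
}
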