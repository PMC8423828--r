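#' Pedigree regression coefficients for de novo mutation counts
#'
#' Trio sequencing studies model the expected number of de novo mutations
#' transmitted by each parent as a linear function of that parent's age at
#' reproduction.  The defaults are the published genome-wide Poisson
#' regression coefficients from the Icelandic (deCODE) trio analysis:
#' paternal mutations \eqn{\hat\mu_{f,g} = 6.05 + 1.51\,a_f} and maternal
#' mutations \eqn{\hat\mu_{m,g} = 3.61 + 0.37\,a_m}, with ages in years.
#' All downstream generation-time estimators take a `pedigree_params`
#' object, so sensitivity analyses can substitute alternative coefficients.
#'
#' @param paternal_intercept,paternal_slope Paternal regression intercept
#'   (mutations/generation) and slope (mutations/generation/year).
#' @param maternal_intercept,maternal_slope Maternal counterparts.
#' @return An object of class `pedigree_params` (a named list with the four
#'   coefficients).
#' @examples
#' p <- pedigree_params()
#' mu_per_generation(28, 28, p)  # 62.30
#' @export
pedigree_params <- function(paternal_intercept = 6.05, paternal_slope = 1.51,
                            maternal_intercept = 3.61, maternal_slope = 0.37) {
  stopifnot(paternal_intercept > 0, paternal_slope > 0,
            maternal_intercept > 0, maternal_slope > 0)
  structure(list(paternal_intercept = paternal_intercept,
                 paternal_slope = paternal_slope,
                 maternal_intercept = maternal_intercept,
                 maternal_slope = maternal_slope),
            class = "pedigree_params")
}

#' @export
print.pedigree_params <- function(x, ...) {
  cat(sprintf("pedigree regression: paternal %.2f + %.2f a_f; maternal %.2f + %.2f a_m\n",
              x$paternal_intercept, x$paternal_slope,
              x$maternal_intercept, x$maternal_slope))
  invisible(x)
}

#' Expected mutations per generation for given parental ages
#'
#' Sum of the paternal and maternal pedigree regressions.  With equal
#' parental ages \eqn{a_f = a_m = a} and the default coefficients this
#' reduces to \eqn{9.66 + 1.88a}.
#'
#' @param a_f,a_m Paternal and maternal age at reproduction (years, > 0).
#'   Zero is accepted to read off the intercept sum.
#' @param params A [pedigree_params()] object.
#' @return Expected de novo mutation count per generation.
#' @export
mu_per_generation <- function(a_f, a_m = a_f, params = pedigree_params()) {
  if (any(a_f < 0) || any(a_m < 0)) stop("parental ages must be non-negative")
  (params$paternal_intercept + params$paternal_slope * a_f) +
    (params$maternal_intercept + params$maternal_slope * a_m)
}

#' Expected mutations per year for a given mean parental age
#'
#' The per-generation rate divided by the generation interval:
#' \eqn{\hat\mu_y = \hat\mu_g / a = 9.66/a + 1.88} (defaults).  Strictly
#' decreasing in `a`: young parents pack the pre-pubertal mutational burst
#' into more generations per unit time.
#'
#' @param a Mean parental age (years, > 0), assumed shared by both parents.
#' @param params A [pedigree_params()] object.
#' @return Expected mutation count per year.
#' @export
mu_per_year <- function(a, params = pedigree_params()) {
  if (any(a <= 0)) stop("mean parental age must be positive")
  mu_per_generation(a, a, params) / a
}

#' Scale a derived-allele excess from total history to the post-split epoch
#'
#' An excess in derived-allele accumulation measured over the whole time
#' since the Out-of-Africa event can only have arisen while the two
#' populations were separated.  The observed percentage is therefore scaled
#' up by the ratio of the total accumulation time to the separation time:
#' `excess_pct * t_ooa / t_split`.
#'
#' @param excess_pct Observed percent excess over the full epoch.
#' @param t_ooa_years Time over which derived alleles accumulated (years).
#' @param t_split_years Time the two populations have been separated (years);
#'   must not exceed `t_ooa_years`.
#' @return Scaled percent excess attributable to the post-split epoch.
#' @examples
#' excess_scaling(1.09, 60000, 40000)  # 1.635
#' @export
excess_scaling <- function(excess_pct, t_ooa_years, t_split_years) {
  if (t_split_years <= 0) stop("t_split_years must be positive")
  if (t_split_years > t_ooa_years)
    stop("t_split_years must not exceed t_ooa_years")
  excess_pct * t_ooa_years / t_split_years
}

#' Estimate a population's mean parental age from a mutation-rate ratio
#'
#' Given the ratio of yearly derived-allele accumulation between two
#' populations (`d_ratio` = d_x / d_z) and the mean parental age of the
#' reference population (`a_z`), inverts the pedigree yearly-rate model
#' \deqn{\frac{d_x}{d_z} = \frac{9.66/a_x + 1.88}{9.66/a_z + 1.88}}
#' to obtain
#' \deqn{a_x = \frac{9.66}{\frac{d_x}{d_z}\left(\frac{9.66}{a_z} + 1.88\right) - 1.88}.}
#' (Coefficient symbols shown for the defaults; the general form uses the
#' intercept and slope sums from `params`.)
#'
#' @param d_ratio Ratio of derived-allele accumulation d_x/d_z (> 0).
#' @param a_z Reference population mean parental age (years, > 0).
#' @param params A [pedigree_params()] object.
#' @return An object of class `generation_estimate`: list with `d_ratio`,
#'   `a_z`, `a_x` (the estimate, years, full precision), `diff`
#'   (`a_z - a_x`), and the intermediates `mu_g_z`, `mu_y_z`, `denominator`.
#' @examples
#' est <- estimate_parental_age(1.0164, 28)
#' round(est$a_x, 2)   # 25.32
#' round(est$diff, 2)  # 2.68
#' @export
estimate_parental_age <- function(d_ratio, a_z, params = pedigree_params()) {
  if (d_ratio <= 0) stop("d_ratio must be positive")
  if (a_z <= 0) stop("a_z must be positive")
  icpt <- params$paternal_intercept + params$maternal_intercept
  slope <- params$paternal_slope + params$maternal_slope
  denom <- d_ratio * (icpt / a_z + slope) - slope
  if (denom <= 0)
    stop("ratio implies non-positive generation time (denominator <= 0)")
  a_x <- icpt / denom
  structure(list(d_ratio = d_ratio, a_z = a_z, a_x = a_x,
                 diff = a_z - a_x,
                 mu_g_z = mu_per_generation(a_z, a_z, params),
                 mu_y_z = mu_per_year(a_z, params),
                 denominator = denom),
            class = "generation_estimate")
}

#' @export
print.generation_estimate <- function(x, ...) {
  cat(sprintf(
    "generation estimate: d_ratio = %.4f, a_z = %.2f y -> a_x = %.2f y (difference %.2f y)\n",
    x$d_ratio, x$a_z, x$a_x, x$diff))
  invisible(x)
}

#' Expected derived-allele accumulation ratio for two parental ages
#'
#' The forward direction of [estimate_parental_age()]: the ratio of yearly
#' mutation rates \eqn{\mu_y(a_x)/\mu_y(a_z)}.  Optionally epoch-weighted:
#' `epochs` is a two-column structure of epoch durations (years) and a
#' logical `shared` flag; shared epochs contribute at ratio 1 (both
#' lineages accumulate at the same rate there), private epochs at the
#' age-specific ratio, and the result is the duration-weighted ratio of
#' total accumulations.
#'
#' @param a_x,a_z Mean parental ages (years, > 0).
#' @param params A [pedigree_params()] object.
#' @param epochs Optional data.frame with columns `years` and `shared`.
#'   When `NULL` (default) a single fully-private epoch is assumed, making
#'   this the exact algebraic inverse of [estimate_parental_age()].
#' @param a_shared Mean parental age during shared epochs (default `a_z`).
#' @return The expected d_x/d_z ratio.
#' @export
expected_accumulation_ratio <- function(a_x, a_z, params = pedigree_params(),
                                        epochs = NULL, a_shared = a_z) {
  if (a_x <= 0 || a_z <= 0) stop("ages must be positive")
  if (is.null(epochs))
    return(mu_per_year(a_x, params) / mu_per_year(a_z, params))
  stopifnot(all(c("years", "shared") %in% names(epochs)))
  rate_sh <- mu_per_year(a_shared, params)
  num <- sum(ifelse(epochs$shared, rate_sh, mu_per_year(a_x, params)) * epochs$years)
  den <- sum(ifelse(epochs$shared, rate_sh, mu_per_year(a_z, params)) * epochs$years)
  num / den
}
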