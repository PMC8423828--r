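#' Specify one sampled group of a synthetic cohort
#'
#' @param name Group label.
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param a_f,a_m Mean paternal and maternal age at reproduction along the
#'   group's private lineage (years, > 10).
#' @param sampling_time_years Sampling time in years before present
#'   (0 = extant; ancient samples use positive values).
#' @param prop_female Proportion of females in the sample.
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, n_individuals, a_f = 29, a_m = 29,
                       sampling_time_years = 0, prop_female = 0.5) {
  stopifnot(n_individuals >= 1, a_f > 10, a_m > 10,
            sampling_time_years >= 0,
            prop_female >= 0, prop_female <= 1)
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 a_f = a_f, a_m = a_m,
                 sampling_time_years = sampling_time_years,
                 prop_female = prop_female),
            class = "group_spec")
}

#' Default synthetic chromosome set
#'
#' Two 50 Mb autosomes, one 30 Mb X and one 10 Mb Y: large enough for
#' thousands of archaic tracts per cohort, small enough for minutes-scale
#' tests.
#'
#' @return A data.frame with columns `name`, `length`, `is_x`, `is_y`.
#' @export
default_chromosomes <- function() {
  data.frame(name = c("chr1", "chr2", "chrX", "chrY"),
             length = c(50e6, 50e6, 30e6, 10e6),
             is_x = c(FALSE, FALSE, TRUE, FALSE),
             is_y = c(FALSE, FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

#' Full synthetic-demography configuration
#'
#' Defines the study conditions every downstream stage assumes: a single
#' archaic admixture pulse into the common ancestor of all groups,
#' optionally a second younger pulse private to one group and/or dilution
#' of one group by unadmixed ancestry, per-group parental ages driving both
#' the recombination clock (generations since admixture) and the mutation
#' clock (derived-allele accumulation and spectrum).
#'
#' @param groups List of [group_spec()] objects.
#' @param chromosomes Chromosome table as from [default_chromosomes()].
#' @param admixture_time_years Time of the shared archaic pulse (years ago).
#' @param admixture_fraction Archaic ancestry proportion contributed by the
#'   pulse, in (0, 1).
#' @param split_time_years Time the groups' lineages separated (years ago);
#'   at most `admixture_time_years`.
#' @param ooa_time_years Start of derived-allele accumulation (time of the
#'   Out-of-Africa-like divergence from the outgroup; years ago).
#' @param ancestral_a Mean parental age along the shared lineage (years).
#' @param second_pulse Optional `list(group=, time_years=, fraction=)`:
#'   an additional archaic pulse private to `group`, at
#'   `time_years <= split_time_years`.
#' @param dilution Optional `list(group=, proportion=)`: admixture from an
#'   unadmixed source removing each archaic tract of the target group
#'   independently with the given probability (lengths unchanged).
#' @param recomb_rate_cM_Mb Constant recombination rate of the generated
#'   maps (cM/Mb).
#' @param n_pool Number of ancestral haplotypes in the shared tract pool;
#'   controls how much archaic sequence individuals (and groups) share.
#' @param lambda_background,lambda_archaic Expected private-SNP counts per
#'   fully-callable, unit-scale 1 kb window outside/inside archaic tracts.
#' @param callability_beta,mutrate_gamma Parameters (shape1/shape2 and
#'   shape/rate) of the per-window callability Beta and mutation-rate-scale
#'   Gamma distributions.
#' @param window_bp HMM window width (bp); tract boundaries are snapped to
#'   this grid.
#' @param mutation_scale Multiplier on expected derived-allele counts
#'   (1 = human genome-wide pedigree rates scaled to the synthetic genome
#'   size).
#' @param p_hom Probability that a derived-allele record is homozygous
#'   (dosage 2).
#' @param spectrum Optional 8 x 2 matrix (`intercept`, `slope` columns,
#'   disjoint-type rownames) giving each type's fraction as
#'   `intercept + slope * (a_bar - 29)`; defaults mimic the observed
#'   directions (TCC>TTC decreasing with age, CpG>TpG flat).
#' @param cdnm_fraction Fraction of autosomal 1 Mb windows flagged as
#'   clustered-DNM (cDNM) regions.
#' @param cdnm_gamma Per-year inflation slope of the C>G fraction inside
#'   cDNM windows: factor `1 + cdnm_gamma * (a_m - 20)`.
#' @param mask_fraction Fraction of each chromosome masked as
#'   repeat/uncallable.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams (one per individual per chromosome), so adding
#'   individuals or groups does not perturb existing draws.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(groups,
                          chromosomes = default_chromosomes(),
                          admixture_time_years = 55000,
                          admixture_fraction = 0.02,
                          split_time_years = 40000,
                          ooa_time_years = 60000,
                          ancestral_a = 29,
                          second_pulse = NULL,
                          dilution = NULL,
                          recomb_rate_cM_Mb = 1.2,
                          n_pool = 32,
                          lambda_background = 0.02,
                          lambda_archaic = 0.4,
                          callability_beta = c(20, 2),
                          mutrate_gamma = c(50, 50),
                          window_bp = 1000,
                          mutation_scale = 1,
                          p_hom = 0.1,
                          spectrum = NULL,
                          cdnm_fraction = 0.1,
                          cdnm_gamma = 0.02,
                          mask_fraction = 0.05,
                          seed = 1L) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_spec")))
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(names(groups))) stop("group names must be unique")
  if (!(admixture_fraction > 0 && admixture_fraction < 1))
    stop("admixture_fraction must be in (0, 1)")
  if (!(admixture_time_years >= split_time_years && split_time_years >= 0))
    stop("need admixture_time_years >= split_time_years >= 0")
  if (ooa_time_years < split_time_years)
    stop("ooa_time_years must be at least split_time_years")
  for (g in groups)
    if (g$sampling_time_years >= admixture_time_years)
      stop("group '", g$name, "' sampled at or before the admixture pulse")
  if (!is.null(second_pulse)) {
    stopifnot(all(c("group", "time_years", "fraction") %in% names(second_pulse)))
    if (!second_pulse$group %in% names(groups))
      stop("second_pulse targets unknown group")
    if (second_pulse$time_years > split_time_years)
      stop("second pulse must postdate the group split")
    stopifnot(second_pulse$fraction > 0, second_pulse$fraction < 1)
  }
  if (!is.null(dilution)) {
    stopifnot(all(c("group", "proportion") %in% names(dilution)))
    if (!dilution$group %in% names(groups))
      stop("dilution targets unknown group")
    stopifnot(dilution$proportion >= 0, dilution$proportion < 1)
  }
  if (is.null(spectrum)) spectrum <- default_spectrum_law()
  stopifnot(is.matrix(spectrum),
            identical(sort(rownames(spectrum)), sort(disjoint_types())),
            all(c("intercept", "slope") %in% colnames(spectrum)))
  if (n_pool < 2) stop("n_pool must be at least 2")
  structure(list(groups = groups, chromosomes = chromosomes,
                 admixture_time_years = admixture_time_years,
                 admixture_fraction = admixture_fraction,
                 split_time_years = split_time_years,
                 ooa_time_years = ooa_time_years,
                 ancestral_a = ancestral_a,
                 second_pulse = second_pulse, dilution = dilution,
                 recomb_rate_cM_Mb = recomb_rate_cM_Mb,
                 n_pool = as.integer(n_pool),
                 lambda_background = lambda_background,
                 lambda_archaic = lambda_archaic,
                 callability_beta = callability_beta,
                 mutrate_gamma = mutrate_gamma,
                 window_bp = as.integer(window_bp),
                 mutation_scale = mutation_scale,
                 p_hom = p_hom, spectrum = spectrum,
                 cdnm_fraction = cdnm_fraction, cdnm_gamma = cdnm_gamma,
                 mask_fraction = mask_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort config: %d group(s), %d chromosome(s), pulse %g ya (alpha = %g), split %g ya, seed %d\n",
    length(x$groups), nrow(x$chromosomes), x$admixture_time_years,
    x$admixture_fraction, x$split_time_years, x$seed))
  for (g in x$groups)
    cat(sprintf("  %s: n = %d, a_f = %g, a_m = %g, sampled %g ya\n",
                g$name, g$n_individuals, g$a_f, g$a_m, g$sampling_time_years))
  invisible(x)
}

disjoint_types <- function() {
  c("C>A", "C>G", "T>A", "T>C", "T>G", "CpG>TpG", "TCC>TTC", "C>T'")
}

# Baseline 9-type spectrum (at a_bar = 29 y) and per-year slopes over the
# eight disjoint classes.  Slopes sum to zero so fractions stay normalised;
# directions mimic the trio-data regressions (TCC>TTC decreasing with
# parental age, CpG>TpG flat, C>G increasing with maternal age).
default_spectrum_law <- function() {
  m <- rbind("C>A"     = c(0.090,  3e-4),
             "C>G"     = c(0.072,  6e-4),
             "T>A"     = c(0.070,  0),
             "T>C"     = c(0.260, -2e-4),
             "T>G"     = c(0.088, -1e-4),
             "CpG>TpG" = c(0.170,  0),
             "TCC>TTC" = c(0.030, -1e-3),
             "C>T'"    = c(0.220,  4e-4))
  colnames(m) <- c("intercept", "slope")
  m
}

spectrum_probs <- function(config, a_bar) {
  p <- config$spectrum[, "intercept"] +
    config$spectrum[, "slope"] * (a_bar - 29)
  p <- pmax(p, 1e-4)
  p / sum(p)
}

# ---- lineage bookkeeping ---------------------------------------------------

group_abar <- function(g) (g$a_f + g$a_m) / 2

#' Generations since admixture along a group's lineage
#'
#' Piecewise over the shared epoch (admixture to split, at the ancestral
#' mean parental age) and the group-private epoch (split to sampling, at
#' the group's own mean parental age).
#'
#' @param config A [cohort_config()].
#' @param group Group name.
#' @return List with `g_shared`, `g_private`, `g_total`.
#' @export
lineage_generations <- function(config, group) {
  g <- config$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  t_mid <- max(config$split_time_years, g$sampling_time_years)
  g_sh <- (config$admixture_time_years - t_mid) / config$ancestral_a
  g_pr <- max(0, config$split_time_years - g$sampling_time_years) /
    group_abar(g)
  list(g_shared = g_sh, g_private = g_pr, g_total = g_sh + g_pr)
}

mutation_epochs <- function(config, group) {
  g <- config$groups[[group]]
  t_mid <- max(config$split_time_years, g$sampling_time_years)
  data.frame(
    years = c(config$ooa_time_years - t_mid,
              max(0, config$split_time_years - g$sampling_time_years)),
    a_f = c(config$ancestral_a, g$a_f),
    a_m = c(config$ancestral_a, g$a_m),
    shared = c(TRUE, FALSE))
}

#' Expected derived-allele count per individual under the generator model
#'
#' Closed-form expectation of the dosage-weighted derived-allele count
#' accumulated since the outgroup divergence, summed over lineage epochs:
#' per epoch, `(years / a_lineage) * mu_lineage * (L / 3.03e9) *
#' mutation_scale`, where for autosomes the lineage rate is the full
#' pedigree regression at the epoch's parental ages, for X it is the
#' 2/3-maternal + 1/3-paternal exposure mix (per X copy; females carry the
#' full autosome-equivalent exposure, males half), and for Y the paternal
#' regression alone.
#'
#' @param config A [cohort_config()].
#' @param group Group name.
#' @param chrom_type `"autosome"`, `"X"` or `"Y"`.
#' @param sex `"F"` or `"M"` (matters for X and Y).
#' @param params [pedigree_params()] used by the generator.
#' @return Expected count (a single number).
#' @export
expected_variant_count <- function(config, group,
                                   chrom_type = c("autosome", "X", "Y"),
                                   sex = "F", params = pedigree_params()) {
  chrom_type <- match.arg(chrom_type)
  ep <- mutation_epochs(config, group)
  chr <- config$chromosomes
  L <- switch(chrom_type,
              autosome = sum(chr$length[!chr$is_x & !chr$is_y]),
              X = sum(chr$length[chr$is_x]),
              Y = sum(chr$length[chr$is_y]))
  male <- toupper(substr(sex, 1, 1)) == "M"
  if (chrom_type == "Y" && !male) return(0)
  per_year <- vapply(seq_len(nrow(ep)), function(i) {
    a_f <- ep$a_f[i]; a_m <- ep$a_m[i]
    mu_f <- params$paternal_intercept + params$paternal_slope * a_f
    mu_m <- params$maternal_intercept + params$maternal_slope * a_m
    switch(chrom_type,
           autosome = (mu_f + mu_m) / ((a_f + a_m) / 2),
           X = {
             r <- ((2 / 3) * mu_m + (1 / 3) * mu_f) / ((2 * a_m + a_f) / 3)
             if (male) r / 2 else r
           },
           Y = mu_f / a_f)
  }, numeric(1))
  sum(per_year * ep$years) * (L / 3.03e9) * config$mutation_scale
}

# ---- shared deterministic annotation tracks --------------------------------

#' Callable-sequence masks of a synthetic cohort
#'
#' Each chromosome carries a repeat-like uncallable mask covering about
#' `mask_fraction` of its length (10 kb blocks at uniform positions,
#' deterministic given the config seed).  Variants are only placed in the
#' callable complement.
#'
#' @param config A [cohort_config()].
#' @return List with interval data.frames `masked` and `callable`.
#' @export
callable_masks <- function(config) {
  chr <- config$chromosomes
  masked <- list()
  for (i in seq_len(nrow(chr))) {
    L <- chr$length[i]
    n_rep <- ceiling(config$mask_fraction * L / 1e4)
    if (n_rep == 0) next
    starts <- with_local_seed(
      substream_seed(config$seed, "mask", chr$name[i]),
      sort(floor(stats::runif(n_rep, 0, L - 1e4) / 1e3) * 1e3))
    masked[[chr$name[i]]] <- data.frame(chrom = chr$name[i], start = starts,
                                        end = starts + 1e4)
  }
  masked <- if (length(masked)) merge_intervals(masked) else empty_bed()
  whole <- data.frame(chrom = chr$name, start = 0, end = chr$length)
  callable <- if (nrow(masked)) {
    lv <- sort(unique(c(whole$chrom, masked$chrom)))
    gr_to_bed(GenomicRanges::setdiff(bed_to_gr(whole, lv),
                                     bed_to_gr(masked, lv)))
  } else whole
  list(masked = masked, callable = callable)
}

#' Clustered-DNM window annotation of a synthetic cohort
#'
#' Flags a deterministic `cdnm_fraction` of autosomal 1 Mb windows as
#' clustered-de-novo-mutation regions, inside which the generator inflates
#' the C>G fraction with maternal age.
#'
#' @param config A [cohort_config()].
#' @return Data.frame `chrom`, `start`, `end`, `cdnm` (logical).
#' @export
cdnm_windows <- function(config) {
  chr <- config$chromosomes
  aut <- chr[!chr$is_x & !chr$is_y, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(aut)), function(i) {
    s <- seq(0, aut$length[i] - 1, by = 1e6)
    data.frame(chrom = aut$name[i], start = s,
               end = pmin(s + 1e6, aut$length[i]))
  }))
  out$cdnm <- with_local_seed(substream_seed(config$seed, "cdnm"),
                              stats::runif(nrow(out)) < config$cdnm_fraction)
  out
}

#' Recombination maps of a synthetic cohort
#'
#' One map per group, constant at `recomb_rate_cM_Mb` over every non-Y
#' chromosome (the Y does not recombine).
#'
#' @param config A [cohort_config()].
#' @return Named list of [recomb_map()] objects, one per group.
#' @export
simulate_recomb_maps <- function(config) {
  chr <- config$chromosomes[!config$chromosomes$is_y, , drop = FALSE]
  seg <- data.frame(chrom = chr$name, start = 0, end = chr$length,
                    rate = config$recomb_rate_cM_Mb)
  stats::setNames(lapply(names(config$groups), function(g) recomb_map(seg, g)),
                  names(config$groups))
}

# ---- archaic tract simulation ----------------------------------------------

# Stationary two-state Markov ancestry chain along [0, L] Morgans: archaic
# segment lengths ~ Exp(g(1-alpha)), non-archaic ~ Exp(g*alpha), archaic
# stationary fraction alpha.  Returns a 2-column matrix of archaic
# (start, end) in Morgans.
markov_tracts <- function(L_M, g, alpha) {
  if (g <= 0)
    return(if (stats::runif(1) < alpha) cbind(0, L_M) else cbind(numeric(0), numeric(0)))
  r_arc <- g * (1 - alpha); r_bg <- g * alpha
  # expected segment count; draw in batches until past L
  pos <- 0
  state <- stats::runif(1) < alpha
  starts <- numeric(0); ends <- numeric(0)
  while (pos < L_M) {
    len <- stats::rexp(1, if (state) r_arc else r_bg)
    if (state) { starts <- c(starts, pos); ends <- c(ends, min(pos + len, L_M)) }
    pos <- pos + len
    state <- !state
  }
  cbind(starts, ends)
}

clip_tracts <- function(tr, lo, hi) {
  if (!nrow(tr)) return(tr)
  s <- pmax(tr[, 1], lo); e <- pmin(tr[, 2], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

# Decay a pool of ancestral tract sets through g_private further
# generations: the chromosome is cut into ancestry blocks (breakpoints
# Poisson per Morgan), each block copies a uniformly chosen pool
# haplotype, and the block's archaic content is inherited.  Because a cut
# re-picks the same pool haplotype with probability 1/n_pool (rejoining
# the tract it just cut), the cut rate is inflated by n_pool/(n_pool - 1)
# so the composite archaic tract-end hazard is exactly
# (g_shared + g_private)(1 - alpha) per Morgan in expectation.
compose_from_pool <- function(pool, L_M, g_private) {
  if (g_private <= 0) {
    return(pool[[sample.int(length(pool), 1)]])
  }
  n_pool <- length(pool)
  cut_rate <- g_private * n_pool / (n_pool - 1)
  nb <- stats::rpois(1, cut_rate * L_M)
  cuts <- sort(stats::runif(nb, 0, L_M))
  b <- c(0, cuts, L_M)
  picks <- sample.int(n_pool, length(b) - 1, replace = TRUE)
  sizes <- vapply(pool, nrow, integer(1))
  if (sum(sizes) == 0) return(cbind(numeric(0), numeric(0)))
  S <- do.call(rbind, pool)
  hap <- rep.int(seq_along(pool), sizes)
  # block range spanned by each pool tract (blocks partition [0, L])
  k_lo <- findInterval(S[, 1], b)
  k_hi <- findInterval(S[, 2], b)
  k_hi[b[pmin(k_hi, length(b))] == S[, 2]] <-
    k_hi[b[pmin(k_hi, length(b))] == S[, 2]] - 1
  k_hi <- pmin(k_hi, length(b) - 1)
  k_hi <- pmax(k_hi, k_lo)
  spans <- k_hi - k_lo + 1
  row_id <- rep.int(seq_along(spans), spans)
  blk <- sequence(spans, from = k_lo)
  keep <- picks[blk] == hap[row_id]
  s_piece <- pmax(S[row_id, 1], b[blk])
  e_piece <- pmin(S[row_id, 2], b[blk + 1])
  keep <- keep & e_piece > s_piece
  cbind(s_piece[keep], e_piece[keep])
}

snap_tracts_bp <- function(tr_M, L_M, L_bp, window_bp) {
  if (!nrow(tr_M)) return(empty_bed()[0, c("start", "end")])
  # constant-rate genetic->physical conversion within a chromosome
  s <- round(tr_M[, 1] / L_M * L_bp / window_bp) * window_bp
  e <- round(tr_M[, 2] / L_M * L_bp / window_bp) * window_bp
  keep <- e > s
  data.frame(start = s[keep], end = pmin(e[keep], L_bp))
}

#' Simulate archaic tract sets for one group
#'
#' Implements the Markovian (exponential tract length) approximation of
#' post-admixture ancestry decay.  Archaic ancestry enters as a pulse of
#' fraction alpha; after g generations, tract lengths are approximately
#' exponential with mean `1/(g(1-alpha))` Morgans.  Sharing of archaic
#' sequence within and between groups arises from a finite pool of
#' `n_pool` ancestral haplotypes simulated at the group split: every
#' sampled haplotype copies pool material in ancestry blocks broken at the
#' private-epoch recombination rate, so the composite tract lengths decay
#' with the total generation count while identical pool choices create
#' shared archaic sequence.  A second pulse adds an independent younger
#' layer with its own pool private to the target group; dilution removes
#' each tract of the target group independently with the configured
#' probability, reducing total archaic sequence without changing tract
#' lengths.  On X chromosomes the effective recombination generation count
#' is scaled by 2/3 (X recombines only in females).  Tract boundaries are
#' snapped to the `window_bp` grid.
#'
#' @param config A [cohort_config()].
#' @param group Group name.
#' @return Named list (one element per individual) of data.frames `chrom`,
#'   `start`, `end`, `haplotype`, sorted and non-overlapping within each
#'   haplotype.
#' @export
simulate_fragment_decay <- function(config, group) {
  gs <- config$groups[[group]]
  if (is.null(gs)) stop("unknown group: ", group)
  if (gs$sampling_time_years >= config$admixture_time_years)
    stop("group sampled at or before the admixture pulse")
  gens <- lineage_generations(config, group)
  alpha <- config$admixture_fraction
  chr <- config$chromosomes[!config$chromosomes$is_y, , drop = FALSE]
  rate_M_per_bp <- config$recomb_rate_cM_Mb * 1e-8
  sp <- config$second_pulse
  has_p2 <- !is.null(sp) && sp$group == group
  dil <- config$dilution
  dil_p <- if (!is.null(dil) && dil$group == group) dil$proportion else 0

  inds <- sprintf("%s_%d", group, seq_len(gs$n_individuals))
  sexes <- individual_sexes(gs)
  out <- stats::setNames(vector("list", length(inds)), inds)

  for (ci in seq_len(nrow(chr))) {
    cname <- chr$name[ci]
    L_bp <- chr$length[ci]
    L_M <- L_bp * rate_M_per_bp
    xfac <- if (chr$is_x[ci]) 2 / 3 else 1
    g_sh <- gens$g_shared * xfac
    g_pr <- gens$g_private * xfac
    # pulse-1 pool at the split: shared substream across groups
    pool1 <- lapply(seq_len(config$n_pool), function(j)
      with_local_seed(substream_seed(config$seed, "pool1", cname, j),
                      markov_tracts(L_M, g_sh, alpha)))
    if (has_p2) {
      g2 <- xfac * (sp$time_years - gs$sampling_time_years) / group_abar(gs)
      pool2 <- lapply(seq_len(config$n_pool), function(j)
        with_local_seed(substream_seed(config$seed, "pool2", group, cname, j),
                        markov_tracts(L_M, g2 / 2, sp$fraction)))
    }
    for (k in seq_along(inds)) {
      ploidy <- if (chr$is_x[ci] && sexes[k] == "M") 1L else 2L
      for (hap in seq_len(ploidy)) {
        tr <- with_local_seed(
          substream_seed(config$seed, "frag", group, inds[k], cname, hap), {
            t1 <- if (gens$g_total * xfac <= 0) {
              markov_tracts(L_M, 0, alpha)
            } else compose_from_pool(pool1, L_M, g_pr)
            t2 <- if (has_p2) compose_from_pool(pool2, L_M, g2 / 2) else
              cbind(numeric(0), numeric(0))
            if (dil_p > 0) {
              keep1 <- stats::runif(nrow(t1)) >= dil_p
              keep2 <- stats::runif(nrow(t2)) >= dil_p
              t1 <- t1[keep1, , drop = FALSE]
              t2 <- t2[keep2, , drop = FALSE]
            }
            rbind(t1, t2)
          })
        bp <- snap_tracts_bp(tr, L_M, L_bp, config$window_bp)
        if (!nrow(bp)) next
        df <- data.frame(chrom = cname, start = bp$start, end = bp$end,
                         haplotype = hap, stringsAsFactors = FALSE)
        out[[k]] <- rbind(out[[k]], df)
      }
    }
  }
  lapply(out, function(df) {
    if (is.null(df)) return(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), haplotype = integer()))
    parts <- lapply(split(df, df$haplotype), function(h) {
      m <- merge_intervals(h)
      m$haplotype <- h$haplotype[1]
      m
    })
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    df[order(df$chrom, df$haplotype, df$start), ]
  })
}

individual_sexes <- function(gs) {
  n_f <- round(gs$n_individuals * gs$prop_female)
  c(rep("F", n_f), rep("M", gs$n_individuals - n_f))
}

#' Diploid union of per-haplotype tract sets
#'
#' @param fragments A per-individual data.frame from
#'   [simulate_fragment_decay()].
#' @return Merged interval data.frame (chrom, start, end), non-overlapping.
#' @export
merged_fragments <- function(fragments) {
  if (!nrow(fragments)) return(empty_bed())
  merge_intervals(fragments[c("chrom", "start", "end")])
}

# ---- derived-allele simulation ---------------------------------------------

draw_positions <- function(n, callable_chr) {
  if (!n) return(integer(0))
  lens <- callable_chr$end - callable_chr$start
  cum <- cumsum(lens)
  u <- stats::runif(n, 0, cum[length(cum)])
  seg <- findInterval(u, c(0, cum[-length(cum)]))
  as.integer(floor(callable_chr$start[seg] + (u - c(0, cum)[seg]))) + 1L
}

context_for_type <- function(type9, n) {
  # returns list(ctx5, anc, der, ctx3) consistent with the collapsed class
  base <- c("A", "C", "G", "T")
  if (type9 == "CpG>TpG") {
    list(c5 = sample(base, n, TRUE), anc = rep("C", n), der = rep("T", n),
         c3 = rep("G", n))
  } else if (type9 == "TCC>TTC") {
    list(c5 = rep("T", n), anc = rep("C", n), der = rep("T", n),
         c3 = rep("C", n))
  } else if (type9 == "C>T'") {
    combos <- expand.grid(c5 = base, c3 = setdiff(base, "G"),
                          stringsAsFactors = FALSE)
    combos <- combos[!(combos$c5 == "T" & combos$c3 == "C"), ]
    pick <- sample.int(nrow(combos), n, TRUE)
    list(c5 = combos$c5[pick], anc = rep("C", n), der = rep("T", n),
         c3 = combos$c3[pick])
  } else {
    anc <- substr(type9, 1, 1); der <- substr(type9, 3, 3)
    list(c5 = sample(base, n, TRUE), anc = rep(anc, n), der = rep(der, n),
         c3 = sample(base, n, TRUE))
  }
}

simulate_records_one <- function(n_total, probs, p_hom) {
  # dosage-weighted total n_total split into records of dosage 1 or 2
  if (n_total <= 0)
    return(data.frame(dosage = integer(0), type9 = character(0)))
  d <- sample(1:2, n_total, TRUE, prob = c(1 - p_hom, p_hom))
  cs <- cumsum(d)
  m <- which(cs >= n_total)[1]
  d <- d[seq_len(m)]
  if (cs[m] > n_total) d[m] <- 1L
  data.frame(dosage = as.integer(d),
             type9 = sample(names(probs), length(d), TRUE, prob = probs),
             stringsAsFactors = FALSE)
}

#' Simulate derived-allele records for one group
#'
#' Per individual, the dosage-weighted autosomal derived-allele count is
#' Poisson with the closed-form mean of [expected_variant_count()]
#' (pedigree regression summed over shared and private lineage epochs); X
#' counts use the 2/3-maternal exposure mix and Y counts (males only) the
#' paternal regression.  Mutation types follow the configured linear
#' 9-type law at the lineage-weighted mean parental age; records landing in
#' cDNM-flagged 1 Mb windows have their C>G probability inflated by
#' `1 + cdnm_gamma * (a_m - 20)`.  Positions are uniform over the callable
#' mask, and each record is emitted on a random reference strand (so
#' classification must strand-collapse to recover the truth).
#'
#' @param config A [cohort_config()].
#' @param group Group name.
#' @param params [pedigree_params()] used for the expected counts.
#' @return Data.frame with columns `chrom`, `pos` (1-based), `ancestral`,
#'   `derived`, `ctx5`, `ctx3`, `dosage`, `individual`.
#' @export
simulate_mutations <- function(config, group, params = pedigree_params()) {
  gs <- config$groups[[group]]
  if (is.null(gs)) stop("unknown group: ", group)
  chr <- config$chromosomes
  masks <- callable_masks(config)
  cdnm <- cdnm_windows(config)
  ep <- mutation_epochs(config, group)
  w <- ep$years / sum(ep$years)
  abar_eff <- sum(w * (ep$a_f + ep$a_m) / 2)
  base_probs <- spectrum_probs(config, abar_eff)
  cg_fac <- max(0, 1 + config$cdnm_gamma * (gs$a_m - 20))
  inds <- sprintf("%s_%d", group, seq_len(gs$n_individuals))
  sexes <- individual_sexes(gs)

  exp_by_type <- list(
    autosome = expected_variant_count(config, group, "autosome", "F", params),
    X_F = expected_variant_count(config, group, "X", "F", params),
    X_M = expected_variant_count(config, group, "X", "M", params),
    Y = expected_variant_count(config, group, "Y", "M", params))
  L_aut <- sum(chr$length[!chr$is_x & !chr$is_y])
  L_x <- sum(chr$length[chr$is_x]); L_y <- sum(chr$length[chr$is_y])

  res <- list()
  for (k in seq_along(inds)) {
    for (ci in seq_len(nrow(chr))) {
      cname <- chr$name[ci]
      if (chr$is_y[ci] && sexes[k] == "F") next
      mu <- if (chr$is_y[ci]) {
        exp_by_type$Y * chr$length[ci] / L_y
      } else if (chr$is_x[ci]) {
        (if (sexes[k] == "M") exp_by_type$X_M else exp_by_type$X_F) *
          chr$length[ci] / L_x
      } else exp_by_type$autosome * chr$length[ci] / L_aut
      rec <- with_local_seed(
        substream_seed(config$seed, "mut", group, inds[k], cname), {
          n_tot <- stats::rpois(1, mu)
          rec <- simulate_records_one(n_tot, base_probs, config$p_hom)
          if (nrow(rec)) {
            callable_chr <- masks$callable[masks$callable$chrom == cname, ]
            rec$pos <- draw_positions(nrow(rec), callable_chr)
            # cDNM C>G inflation (autosomes only): re-draw types of
            # affected records with the C>G-boosted law
            if (!chr$is_x[ci] && !chr$is_y[ci] && cg_fac != 1) {
              flags <- cdnm$cdnm[cdnm$chrom == cname]
              in_cdnm <- flags[pmin(length(flags), (rec$pos - 1) %/% 1e6 + 1)]
              if (any(in_cdnm)) {
                p2 <- base_probs
                p2["C>G"] <- p2["C>G"] * cg_fac
                p2 <- p2 / sum(p2)
                rec$type9[in_cdnm] <- sample(names(p2), sum(in_cdnm), TRUE,
                                             prob = p2)
              }
            }
            rec$ctx5 <- rec$ancestral <- rec$derived <- rec$ctx3 <- NA_character_
            for (tp in unique(rec$type9)) {
              sel <- rec$type9 == tp
              cx <- context_for_type(tp, sum(sel))
              rec$ctx5[sel] <- cx$c5; rec$ancestral[sel] <- cx$anc
              rec$derived[sel] <- cx$der; rec$ctx3[sel] <- cx$c3
            }
            # emit half the records on the opposite reference strand
            flip <- stats::runif(nrow(rec)) < 0.5
            if (any(flip)) {
              a <- rec$ancestral[flip]; d <- rec$derived[flip]
              c5 <- rec$ctx5[flip]; c3 <- rec$ctx3[flip]
              rec$ancestral[flip] <- unname(COMP[a])
              rec$derived[flip] <- unname(COMP[d])
              rec$ctx5[flip] <- unname(COMP[c3])
              rec$ctx3[flip] <- unname(COMP[c5])
            }
          }
          rec
        })
      if (!nrow(rec)) next
      rec$chrom <- cname
      rec$individual <- inds[k]
      res[[length(res) + 1]] <- rec[c("chrom", "pos", "ancestral", "derived",
                                      "ctx5", "ctx3", "dosage", "individual")]
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), pos = integer(),
                      ancestral = character(), derived = character(),
                      ctx5 = character(), ctx3 = character(),
                      dosage = integer(), individual = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- window tracks ---------------------------------------------------------

#' Simulate per-window private-SNP counts given truth tracts
#'
#' Tiles every non-Y chromosome into `window_bp` windows; each window draws
#' a callability (Beta) and a mutation-rate scale (Gamma), and a private-
#' SNP count that is Poisson with mean `lambda_state * callability *
#' mutrate_scale`, where the state is archaic when the window lies inside a
#' truth tract and background otherwise.  This is the input the window HMM
#' consumes.
#'
#' @param truth_fragments Named list of per-individual tract sets
#'   (data.frames with chrom/start/end, snapped to the window grid, e.g.
#'   from [simulate_fragment_decay()]).
#' @param config A [cohort_config()].
#' @return Named list of per-individual window tracks: data.frames `chrom`,
#'   `start`, `end`, `count`, `callability`, `mutrate_scale`.
#' @export
simulate_window_counts <- function(truth_fragments, config) {
  chr <- config$chromosomes[!config$chromosomes$is_y, , drop = FALSE]
  wbp <- config$window_bp
  out <- stats::setNames(vector("list", length(truth_fragments)),
                         names(truth_fragments))
  for (ind in names(truth_fragments)) {
    frag <- merged_fragments(truth_fragments[[ind]])
    tracks <- lapply(seq_len(nrow(chr)), function(ci) {
      L <- chr$length[ci]; cname <- chr$name[ci]
      starts <- seq(0, L - 1, by = wbp)
      ends <- pmin(starts + wbp, L)
      arch <- rep(FALSE, length(starts))
      fr <- frag[frag$chrom == cname, , drop = FALSE]
      if (nrow(fr)) {
        mid <- (starts + ends) / 2
        idx <- findInterval(mid, fr$start)
        arch <- idx >= 1 & mid < fr$end[pmax(idx, 1)]
      }
      with_local_seed(substream_seed(config$seed, "track", ind, cname), {
        cb <- config$callability_beta; mg <- config$mutrate_gamma
        call <- stats::rbeta(length(starts), cb[1], cb[2])
        scale <- stats::rgamma(length(starts), shape = mg[1], rate = mg[2])
        lam <- ifelse(arch, config$lambda_archaic, config$lambda_background)
        data.frame(chrom = cname, start = starts, end = ends,
                   count = stats::rpois(length(starts), lam * call * scale),
                   callability = call, mutrate_scale = scale,
                   stringsAsFactors = FALSE)
      })
    })
    out[[ind]] <- do.call(rbind, tracks)
  }
  out
}

# ---- whole-cohort assembly and I/O -----------------------------------------

#' Simulate a complete synthetic cohort
#'
#' Runs the tract, window-track and mutation generators for every group and
#' bundles the shared annotation tracks (masks, cDNM windows,
#' recombination maps) and per-individual metadata.
#'
#' @param config A [cohort_config()].
#' @param window_tracks Also simulate per-individual window tracks
#'   (the costly part; default TRUE).
#' @return A `synthetic_cohort` list: `fragments`, `window_tracks`,
#'   `variants`, `recomb_maps`, `cdnm`, `masks`, `metadata`, `config`.
#' @export
simulate_cohort <- function(config, window_tracks = TRUE) {
  frags <- list(); vars <- list(); meta <- list()
  for (g in names(config$groups)) {
    gs <- config$groups[[g]]
    frags <- c(frags, simulate_fragment_decay(config, g))
    vars[[g]] <- simulate_mutations(config, g)
    meta[[g]] <- data.frame(
      individual = sprintf("%s_%d", g, seq_len(gs$n_individuals)),
      group = g, sex = individual_sexes(gs),
      sampling_time_years = gs$sampling_time_years,
      stringsAsFactors = FALSE)
  }
  structure(list(
    fragments = frags,
    window_tracks = if (window_tracks) simulate_window_counts(frags, config),
    variants = do.call(rbind, c(vars, list(make.row.names = FALSE))),
    recomb_maps = simulate_recomb_maps(config),
    cdnm = cdnm_windows(config),
    masks = callable_masks(config),
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d individuals, %d variant records, seed %d\n",
              nrow(x$metadata),
              if (is.null(x$variants)) 0L else nrow(x$variants),
              x$config$seed))
  invisible(x)
}

#' Simulate a per-proband trio DNM count table
#'
#' Emulates a trio-sequencing de novo mutation dataset: per proband,
#' parental ages are drawn (father age offset from mother age by
#' `age_gap_mean` +/- `age_gap_sd`), the total DNM count is Poisson with
#' the pedigree-regression mean at those ages, and counts are multinomial
#' over the eight disjoint mutation classes with the config's (or
#' supplied) linear age law evaluated at the proband's mean parental age.
#'
#' @param n_probands Number of probands.
#' @param age_range Range of mother ages (years), sampled uniformly.
#' @param age_gap_mean,age_gap_sd Father-minus-mother age offset (years).
#' @param spectrum 8 x 2 intercept/slope matrix as in [cohort_config()]
#'   (default [default_spectrum_law()] directions).
#' @param params [pedigree_params()] for the total counts.
#' @param seed Integer seed.
#' @return A `dnm_table` data.frame (see [as_dnm_table()]).
#' @export
simulate_dnm_table <- function(n_probands, age_range = c(18, 45),
                               age_gap_mean = 2.8, age_gap_sd = 4.2,
                               spectrum = NULL,
                               params = pedigree_params(), seed = 1L) {
  if (is.null(spectrum)) spectrum <- default_spectrum_law()
  with_local_seed(seed, {
    a_m <- stats::runif(n_probands, age_range[1], age_range[2])
    a_f <- pmax(11, a_m + stats::rnorm(n_probands, age_gap_mean, age_gap_sd))
    total <- stats::rpois(n_probands, mu_per_generation(a_f, a_m, params))
    abar <- (a_f + a_m) / 2
    cnt <- t(vapply(seq_len(n_probands), function(i) {
      p <- pmax(spectrum[, "intercept"] +
                  spectrum[, "slope"] * (abar[i] - 29), 1e-4)
      stats::rmultinom(1, total[i], p / sum(p))[, 1]
    }, stats::setNames(numeric(nrow(spectrum)), rownames(spectrum))))
    out <- data.frame(proband = sprintf("p%04d", seq_len(n_probands)),
                      father_age = a_f, mother_age = a_m,
                      check.names = FALSE)
    out <- cbind(out, as.data.frame(cnt, check.names = FALSE))
    as_dnm_table(out)
  })
}

#' Read/write variant records as TSV
#'
#' Columns: chrom, pos (1-based), ancestral, derived, ctx5, ctx3, dosage,
#' individual.
#'
#' @param records Variant data.frame.
#' @param path File path.
#' @export
write_variants_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(pos = "integer"))
}

#' Read/write a window track as TSV
#'
#' Columns: chrom, start, end, count, callability, mutrate_scale.
#'
#' @param track Window-track data.frame.
#' @param path File path.
#' @export
write_window_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_track
#' @export
read_window_track <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write/read a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- lapply(x$groups, unclass)
  x$chromosomes <- as.list(x$chromosomes)
  x$spectrum <- list(types = rownames(config$spectrum),
                     intercept = unname(config$spectrum[, "intercept"]),
                     slope = unname(config$spectrum[, "slope"]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- matrix(c(x$spectrum$intercept, x$spectrum$slope), ncol = 2,
                 dimnames = list(x$spectrum$types, c("intercept", "slope")))
  cohort_config(
    groups = lapply(x$groups, function(g) do.call(group_spec, g)),
    chromosomes = as.data.frame(x$chromosomes, stringsAsFactors = FALSE),
    admixture_time_years = x$admixture_time_years,
    admixture_fraction = x$admixture_fraction,
    split_time_years = x$split_time_years,
    ooa_time_years = x$ooa_time_years,
    ancestral_a = x$ancestral_a,
    second_pulse = x$second_pulse, dilution = x$dilution,
    recomb_rate_cM_Mb = x$recomb_rate_cM_Mb, n_pool = x$n_pool,
    lambda_background = x$lambda_background,
    lambda_archaic = x$lambda_archaic,
    callability_beta = unlist(x$callability_beta),
    mutrate_gamma = unlist(x$mutrate_gamma),
    window_bp = x$window_bp, mutation_scale = x$mutation_scale,
    p_hom = x$p_hom, spectrum = spec,
    cdnm_fraction = x$cdnm_fraction, cdnm_gamma = x$cdnm_gamma,
    mask_fraction = x$mask_fraction, seed = x$seed)
}
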