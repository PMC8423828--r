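#' Run the full generation-interval analysis on a synthetic cohort
#'
#' End-to-end orchestration of the package's stages on one
#' [cohort_config()]: simulate the cohort; call archaic fragments per
#' individual with the window HMM; joined/shared/private interval analysis
#' between the first two groups; fragment-length summaries, bootstrap CIs
#' and permutation tests; physical-to-genetic length conversion and
#' generation counts since admixture; derived-allele filtering, spectrum
#' classification and accumulation; generation-interval difference from
#' the count ratio; sex-specific signatures; and per-type regression
#' comparison (against a trio DNM table when one is supplied, otherwise
#' against a synthetic one).  All randomness flows from `config$seed`
#' plus the stage-level resampling seeds derived from it, so a rerun with
#' the same config is reproducible.
#'
#' @param config A [cohort_config()] with at least two groups.
#' @param outdir Optional directory; when given, per-stage artifacts (BED,
#'   TSV, YAML, JSON report) are written under it.
#' @param dnm_table Optional `dnm_table` for the regression comparison;
#'   default simulates one from the config's spectrum law.
#' @param n_boot,n_perm Resampling sizes for CIs and permutation tests.
#' @param posterior_threshold High-confidence cutoff for decoded
#'   fragments.
#' @param call_fragments Run the HMM caller (default TRUE); when FALSE the
#'   truth tracts are carried through instead (fast smoke runs).
#' @return A `pipeline_report` list (also written as JSON when `outdir` is
#'   given) with one element per stage.
#' @export
run_pipeline <- function(config, outdir = NULL, dnm_table = NULL,
                         n_boot = 2000, n_perm = 999,
                         posterior_threshold = 0.8, call_fragments = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$groups) < 2)
    stop("the pipeline compares groups; need at least two")
  t0 <- Sys.time()
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  save_tsv <- function(x, name) {
    if (!is.null(outdir))
      utils::write.table(x, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## stage: simulate
  cohort <- simulate_cohort(config, window_tracks = call_fragments)
  meta <- cohort$metadata
  groups <- names(config$groups)
  g1 <- groups[1]; g2 <- groups[2]

  ## stage: call fragments
  called <- if (call_fragments) {
    lapply(cohort$window_tracks, function(tr) {
      fit <- fit_hmm(tr)
      dec <- decode_fragments(tr, fit, posterior_threshold)
      dec[dec$high_confidence, c("chrom", "start", "end", "mean_posterior"),
          drop = FALSE]
    })
  } else {
    lapply(cohort$fragments, merged_fragments)
  }
  if (!is.null(outdir)) {
    for (ind in names(called)) write_bed(called[[ind]],
                                         file.path(outdir, paste0(ind, "_fragments.bed")))
  }

  ## stage: interval analysis (first two groups)
  by_group <- lapply(stats::setNames(groups, groups), function(g)
    called[meta$individual[meta$group == g]])
  joined <- lapply(by_group, merge_intervals)
  ix <- intersect_total(joined[[g1]], joined[[g2]])
  freq1 <- window_frequency(joined[[g1]], by_group[[g1]], config$window_bp)
  save_tsv(freq1, paste0(g1, "_frequency.tsv"))
  intervals <- list(
    joined_bp = vapply(joined, total_bp, numeric(1)),
    shared_bp = ix$shared_bp,
    private_bp = c(ix$private_a_bp, ix$private_b_bp))

  ## stage: fragment statistics
  frag_lengths <- lapply(called, function(f)
    if (nrow(f)) f$end - f$start else numeric(0))
  mean_len <- vapply(frag_lengths, function(l)
    if (length(l)) mean(l) else NA_real_, numeric(1))
  per_group_means <- lapply(stats::setNames(groups, groups), function(g)
    stats::na.omit(mean_len[meta$individual[meta$group == g]]))
  seed_stats <- substream_seed(config$seed, "stats")
  perm2 <- permutation_diff_means(per_group_means[[g1]],
                                  per_group_means[[g2]],
                                  n_perm = n_perm, seed = seed_stats)
  permF <- permutation_F(per_group_means, n_perm = n_perm, seed = seed_stats)
  cis <- lapply(per_group_means, function(v)
    if (length(v) >= 2) bootstrap_ci(v, mean, n_boot = n_boot,
                                     seed = seed_stats) else NULL)
  frag_stats <- list(
    group_mean_length = vapply(per_group_means, mean, numeric(1)),
    diff_means = list(observed = perm2$observed, p = perm2$p,
                      floored = perm2$floored),
    F_test = list(observed = permF$observed, p = permF$p),
    ci = lapply(cis, function(ci)
      if (is.null(ci)) NULL else c(lo = ci$lo, hi = ci$hi)))

  ## stage: genetic-distance conversion and generation counts
  maps <- rescale_maps(cohort$recomb_maps)
  mean_cM <- vapply(stats::setNames(groups, groups), function(g) {
    inds <- meta$individual[meta$group == g]
    lens <- unlist(lapply(inds, function(i) {
      f <- called[[i]]
      if (!nrow(f)) return(numeric(0))
      fragments_to_cM(f, maps[[g]])$length_cM
    }))
    if (length(lens)) mean(lens) else NA_real_
  }, numeric(1))
  generations <- vapply(mean_cM, function(m)
    if (is.na(m)) NA_real_ else
      estimate_generations(m, config$admixture_fraction), numeric(1))

  ## stage: mutation spectrum
  arch_mask <- merge_intervals(c(lapply(called, function(x)
    x[c("chrom", "start", "end")]), list(cohort$masks$masked)))
  filt <- filter_variants(cohort$variants, masks = arch_mask)
  chr <- config$chromosomes
  aut_names <- chr$name[!chr$is_x & !chr$is_y]
  aut_rec <- filt$records[filt$records$chrom %in% aut_names, , drop = FALSE]
  counts <- spectrum_counts(aut_rec)
  fracs <- spectrum_fractions(counts)
  save_tsv(as.data.frame(fracs), "spectrum_fractions.tsv")

  ## stage: generation-time estimate from the count ratio
  d_by_ind <- counts$denominator
  d_group <- vapply(stats::setNames(groups, groups), function(g)
    mean(d_by_ind[intersect(names(d_by_ind),
                            meta$individual[meta$group == g])]), numeric(1))
  d_ratio_total <- d_group[[g1]] / d_group[[g2]]
  excess_total_pct <- (d_ratio_total - 1) * 100
  excess_split_pct <- excess_scaling(excess_total_pct,
                                     config$ooa_time_years,
                                     config$split_time_years)
  est <- estimate_parental_age(1 + excess_split_pct / 100,
                               group_abar(config$groups[[g2]]))
  gentime <- list(d_group = d_group, d_ratio_total = d_ratio_total,
                  excess_total_pct = excess_total_pct,
                  excess_split_pct = excess_split_pct,
                  a_x = est$a_x, a_z = est$a_z, diff_years = est$diff)

  ## stage: sex-specific signatures
  Lx <- total_bp(cohort$masks$callable[
    cohort$masks$callable$chrom %in% chr$name[chr$is_x], , drop = FALSE])
  La <- total_bp(cohort$masks$callable[
    cohort$masks$callable$chrom %in% aut_names, , drop = FALSE])
  females <- meta$individual[meta$sex == "F"]
  xa <- vapply(females, function(i) {
    if (Lx == 0 || La == 0) return(NA_real_)
    v <- filt$records[filt$records$individual == i, ]
    dx <- sum(v$dosage[v$chrom %in% chr$name[chr$is_x]])
    da <- sum(v$dosage[v$chrom %in% aut_names])
    if (da == 0) return(NA_real_)
    x_to_a_ratio(dx, Lx, da, La)
  }, numeric(1))
  cg_r <- vapply(unique(meta$individual), function(i) {
    v <- aut_rec[aut_rec$individual == i, ]
    if (!nrow(v)) return(NA_real_)
    cls <- classify_mutations(v)
    win <- cohort$cdnm
    wi <- match(paste(cls$chrom, (cls$pos - 1) %/% 1e6 * 1e6),
                paste(win$chrom, win$start))
    cg <- tapply(cls$dosage * (cls$type6 == "C>G"), wi, sum)
    non <- tapply(cls$dosage * (cls$type6 != "C>G"), wi, sum)
    w <- data.frame(d_cg = as.numeric(cg), d_non_cg = as.numeric(non),
                    cdnm = win$cdnm[as.integer(names(cg))])
    tryCatch(cg_cdnm_ratio(w)$r, error = function(e) NA_real_)
  }, numeric(1))
  sex_sig <- list(
    x_to_a_group = vapply(stats::setNames(groups, groups), function(g)
      mean(xa[intersect(names(xa), meta$individual[meta$group == g])],
           na.rm = TRUE), numeric(1)),
    cg_ratio_group = vapply(stats::setNames(groups, groups), function(g)
      mean(cg_r[intersect(names(cg_r), meta$individual[meta$group == g])],
           na.rm = TRUE), numeric(1)),
    y_rate_sensitivity = vapply(stats::setNames(groups, groups), function(g)
      y_rate_sensitivity(config$groups[[g]]$a_f), numeric(1)))

  ## stage: regression comparison
  regress <- tryCatch({
    fits_len <- fit_type_vs_fraglen(fracs, mean_len[rownames(fracs)])
    if (is.null(dnm_table))
      dnm_table <- simulate_dnm_table(400, spectrum = config$spectrum,
                                      seed = substream_seed(config$seed, "dnm"))
    fits_age <- fit_type_vs_age(aggregate_dnm(dnm_table))
    list(fits_fraglen = fits_len, fits_age = fits_age,
         slope_concordance = compare_slopes(fits_len, fits_age))
  }, error = function(e) list(error = conditionMessage(e)))

  report <- structure(list(
    seed = config$seed,
    groups = groups,
    n_individuals = nrow(meta),
    intervals = intervals,
    fragment_stats = frag_stats,
    mean_length_bp = vapply(per_group_means, mean, numeric(1)),
    mean_length_cM = mean_cM,
    generations_since_admixture = generations,
    spectrum_dropped = filt$dropped,
    generation_time = gentime,
    sex_signatures = sex_sig,
    regression = regress,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write_cohort_config(config, file.path(outdir, "config.yaml"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report (seed %d, %d individuals)\n",
              x$seed, x$n_individuals))
  cat(sprintf("  mean fragment length (bp): %s\n",
              paste(sprintf("%s = %.0f", names(x$mean_length_bp),
                            x$mean_length_bp), collapse = ", ")))
  cat(sprintf("  generations since admixture: %s\n",
              paste(sprintf("%s = %.0f", names(x$generations_since_admixture),
                            x$generations_since_admixture), collapse = ", ")))
  gt <- x$generation_time
  cat(sprintf("  derived-allele excess: %.3f%% total, %.3f%% post-split\n",
              gt$excess_total_pct, gt$excess_split_pct))
  cat(sprintf("  estimated a_x = %.2f y vs a_z = %.2f y (diff %.2f y)\n",
              gt$a_x, gt$a_z, gt$diff_years))
  invisible(x)
}
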