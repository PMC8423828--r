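BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The six base mutation types and the nine reported types
#'
#' Strand-collapsed single-nucleotide mutation classes: the six pyrimidine-
#' ancestral base types, with C>T further subdivided into CpG>TpG (3'
#' context G after collapse), the TCC>TTC signature, and the remainder
#' C>T'.  The nine reported types are the six base types plus the three
#' C>T subtypes (so C>T is deliberately counted twice across the nine).
#'
#' @return Character vector of type labels.
#' @export
mutation_types_9 <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G",
    "CpG>TpG", "TCC>TTC", "C>T'")
}

#' @rdname mutation_types_9
#' @export
mutation_types_6 <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' All 96 strand-collapsed trinucleotide mutation types
#'
#' @return Character vector of 96 labels in `"5'[anc>der]3'"` form, e.g.
#'   `"T[C>T]C"`, ordered by base type then 5' then 3' context.
#' @export
mutation_types_96 <- function() {
  out <- character(0)
  for (anc in c("C", "T")) for (der in setdiff(BASES, anc))
    for (c5 in BASES) for (c3 in BASES)
      out <- c(out, sprintf("%s[%s>%s]%s", c5, anc, der, c3))
  out
}

#' Classify derived-allele records into 96 and 9 mutation types
#'
#' Applies the standard pyrimidine-ancestral strand collapse: records whose
#' ancestral allele is A or G are reverse-complemented (alleles
#' complemented, 5'/3' contexts swapped and complemented) so every record
#' is expressed with a C or T ancestral base.  The 96-type label is the
#' collapsed trinucleotide context; the 9-type label is the base type, with
#' C>T records sub-classified as CpG>TpG when the collapsed 3' context is G
#' (this takes precedence), TCC>TTC when the collapsed context spells
#' TCC>TTC, and C>T' otherwise.  Records containing a base outside ACGT are
#' dropped and counted in the `"skipped"` attribute.
#'
#' @param records A data.frame with columns `ancestral`, `derived`, `ctx5`,
#'   `ctx3` (reference-strand bases flanking the ancestral allele); other
#'   columns are preserved.
#' @return The records (minus skipped ones) with added columns `type96`,
#'   `type6`, `type9`; attribute `skipped` holds the dropped-record count.
#' @examples
#' classify_mutations(data.frame(ancestral = "C", derived = "T",
#'                               ctx5 = "T", ctx3 = "C"))$type9  # TCC>TTC
#' @export
classify_mutations <- function(records) {
  need <- c("ancestral", "derived", "ctx5", "ctx3")
  stopifnot(all(need %in% names(records)))
  ok <- Reduce(`&`, lapply(records[need], function(b) b %in% BASES))
  skipped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  if (!nrow(records)) {
    records$type96 <- records$type6 <- records$type9 <- character(0)
    attr(records, "skipped") <- skipped
    return(records)
  }
  anc <- records$ancestral; der <- records$derived
  c5 <- records$ctx5; c3 <- records$ctx3
  flip <- anc %in% c("A", "G")
  if (any(flip)) {
    anc2 <- ifelse(flip, COMP[anc], anc)
    der2 <- ifelse(flip, COMP[der], der)
    c5n <- ifelse(flip, COMP[c3], c5)
    c3n <- ifelse(flip, COMP[c5], c3)
    anc <- anc2; der <- der2; c5 <- c5n; c3 <- c3n
  }
  if (any(anc == der)) stop("ancestral and derived allele must differ")
  type6 <- paste0(anc, ">", der)
  type9 <- type6
  is_ct <- type6 == "C>T"
  type9[is_ct & c3 == "G"] <- "CpG>TpG"
  type9[is_ct & c3 != "G" & c5 == "T" & c3 == "C"] <- "TCC>TTC"
  type9[is_ct & type9 == "C>T"] <- "C>T'"
  records$type96 <- sprintf("%s[%s]%s", c5, type6, c3)
  records$type6 <- type6
  records$type9 <- type9
  attr(records, "skipped") <- skipped
  records
}

#' Dosage-aware mutation-spectrum counts per individual
#'
#' Homozygous derived records (`dosage = 2`) contribute two mutations,
#' heterozygous (`dosage = 1`) one.  Counts are tallied over the 96
#' trinucleotide types, the 6 base types, and the 3 C>T subtypes; the
#' denominator is the total over the 6 base types (C>T subtypes are a
#' relabelling of C>T, not extra mass).
#'
#' @param records A data.frame as accepted by [classify_mutations()], with
#'   in addition `individual` and optionally `dosage` (default 1) and
#'   `chrom`.
#' @param by Grouping: `"individual"` (default) or `"individual_chrom"`.
#' @return A `spectrum_counts` object: list with matrices `counts96`
#'   (groups x 96) and `counts9` (groups x 9), vector `denominator`, and
#'   `skipped`.
#' @export
spectrum_counts <- function(records, by = c("individual", "individual_chrom")) {
  by <- match.arg(by)
  stopifnot("individual" %in% names(records))
  if (!"dosage" %in% names(records)) records$dosage <- 1L
  stopifnot(all(records$dosage %in% c(1L, 2L)))
  cls <- classify_mutations(records)
  key <- if (by == "individual") as.character(cls$individual)
         else paste(cls$individual, cls$chrom, sep = ":")
  groups <- sort(unique(key))
  t96 <- mutation_types_96(); t9 <- mutation_types_9()
  tally <- function(types, levels) {
    m <- matrix(0, nrow = length(groups), ncol = length(levels),
                dimnames = list(groups, levels))
    if (!nrow(cls)) return(m)
    agg <- stats::aggregate(cls$dosage,
                            by = list(key = key, type = types), FUN = sum)
    m[cbind(match(agg$key, groups), match(agg$type, levels))] <- agg$x
    m
  }
  c96 <- tally(cls$type96, t96)
  c9 <- tally(cls$type9, t9)
  # the reported nine duplicate C>T: total C>T = sum of its three subtypes
  c9[, "C>T"] <- c9[, "CpG>TpG"] + c9[, "TCC>TTC"] + c9[, "C>T'"]
  denom <- rowSums(c9[, mutation_types_6(), drop = FALSE])
  structure(list(counts96 = c96, counts9 = c9, denominator = denom,
                 skipped = attr(cls, "skipped")),
            class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf("mutation spectrum counts: %d group(s), %s total mutations\n",
              nrow(x$counts9), format(sum(x$denominator))))
  invisible(x)
}

#' Mutation-type fractions under the shared-denominator rule
#'
#' Each of the nine reported fractions divides by the same denominator,
#' the total count over the six base types; the six base-type fractions
#' therefore sum to 1 and the three C>T subtypes sum to the C>T fraction.
#'
#' @param counts A `spectrum_counts` object from [spectrum_counts()].
#' @return A groups x 9 matrix of fractions.
#' @export
spectrum_fractions <- function(counts) {
  stopifnot(inherits(counts, "spectrum_counts"))
  if (any(counts$denominator == 0))
    stop("zero denominator for group(s): ",
         paste(names(counts$denominator)[counts$denominator == 0], collapse = ", "))
  sweep(counts$counts9, 1, counts$denominator, "/")
}

#' Filter derived-allele records before spectrum and accumulation analyses
#'
#' Drops, in order: records at positions where the derived allele is also
#' observed in the outgroup (archaic admixture or shared ancestral
#' polymorphism), records at multi-allelic positions (more than one
#' distinct allele pair at a chrom/pos across the dataset), and records
#' falling inside any mask interval (repeats, regions with evidence of
#' archaic introgression).
#'
#' @param records Variant data.frame with `chrom`, `pos` (1-based) plus
#'   allele columns.
#' @param outgroup_sites Optional data.frame `chrom`, `pos` of sites whose
#'   derived allele segregates in the outgroup.
#' @param masks Optional interval data.frame (0-based half-open) or list of
#'   them; merged internally.
#' @return List with `records` (retained) and `dropped`, a named count
#'   vector (`outgroup`, `multiallelic`, `masked`) plus `retained_fraction`.
#' @export
filter_variants <- function(records, outgroup_sites = NULL, masks = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(records)))
  n0 <- nrow(records)
  dropped <- c(outgroup = 0L, multiallelic = 0L, masked = 0L)
  if (!is.null(outgroup_sites) && nrow(outgroup_sites)) {
    bad <- paste(records$chrom, records$pos) %in%
      paste(outgroup_sites$chrom, outgroup_sites$pos)
    dropped["outgroup"] <- sum(bad)
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) && all(c("ancestral", "derived") %in% names(records))) {
    site <- paste(records$chrom, records$pos)
    nall <- tapply(paste(records$ancestral, records$derived), site,
                   function(x) length(unique(x)))
    bad <- nall[site] > 1
    dropped["multiallelic"] <- sum(bad)
    records <- records[!bad, , drop = FALSE]
  }
  if (!is.null(masks)) {
    masks <- merge_intervals(masks)
    if (nrow(masks) && nrow(records)) {
      lv <- sort(unique(c(as.character(records$chrom), masks$chrom)))
      pgr <- GenomicRanges::GRanges(
        factor(as.character(records$chrom), levels = lv),
        IRanges::IRanges(records$pos, records$pos))
      bad <- GenomicRanges::countOverlaps(pgr, bed_to_gr(masks, lv)) > 0
      dropped["masked"] <- sum(bad)
      records <- records[!bad, , drop = FALSE]
    }
  }
  list(records = records, dropped = dropped,
       retained_fraction = if (n0) nrow(records) / n0 else NA_real_)
}

#' Write per-individual, per-chromosome 96-type counts as TSV
#'
#' Long-format table (individual, chrom, type96, count), the package's
#' analogue of a per-chromosome mutation-spectrum source file.
#'
#' @param records Variant records (see [spectrum_counts()]).
#' @param path Output path.
#' @export
write_spectrum_counts <- function(records, path) {
  sc <- spectrum_counts(records, by = "individual_chrom")
  m <- sc$counts96
  long <- data.frame(
    individual = sub(":[^:]*$", "", rownames(m)[row(m)]),
    chrom = sub("^.*:", "", rownames(m)[row(m)]),
    type96 = colnames(m)[col(m)],
    count = as.vector(m), stringsAsFactors = FALSE)
  long <- long[long$count > 0, ]
  long <- long[order(long$individual, long$chrom, long$type96), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
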