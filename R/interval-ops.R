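#' @useDynLib genclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import IRanges
#' @import GenomicRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All interval sets are plain data.frames with columns chrom, start, end in
# 0-based half-open (BED) coordinates, optionally carrying extra columns.
# GRanges (1-based closed) is used internally for the set arithmetic.

validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must have columns chrom, start, end")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("malformed interval in %s: record %d (%s:%d-%d)",
                 what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  invisible(x)
}

bed_to_gr <- function(x, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- sort(unique(as.character(x$chrom)))
  GenomicRanges::GRanges(
    factor(as.character(x$chrom), levels = seqlevels),
    IRanges::IRanges(start = x$start + 1, end = x$end))
}

gr_to_bed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_bed <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Merge one or more interval sets into a sorted, non-overlapping union
#'
#' Overlapping and book-ended (end == start) intervals are joined, matching
#' the default behaviour of `bedtools merge` on the concatenated inputs.
#'
#' @param ... One or more interval data.frames (chrom, start, end; 0-based
#'   half-open), or a single list of them.
#' @return A merged interval data.frame, sorted by chrom then start.
#' @examples
#' merge_intervals(data.frame(chrom = "1", start = c(0, 100), end = c(100, 200)))
#' @export
merge_intervals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  sets <- Filter(function(s) nrow(s) > 0, lapply(sets, function(s) {
    validate_intervals(s)
    s[c("chrom", "start", "end")]
  }))
  if (!length(sets)) return(empty_bed())
  all <- do.call(rbind, sets)
  gr_to_bed(GenomicRanges::reduce(bed_to_gr(all)))
}

#' Total base pairs covered by an interval set
#'
#' @param x An interval data.frame.
#' @return Total covered bp (the set is merged first, so overlap is not
#'   double-counted).
#' @export
total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

#' Intersect two merged interval sets and report shared/private sequence
#'
#' Mirrors `bedtools intersect -a A -b B` on merged inputs: returns the
#' overlap segments plus the bp bookkeeping of the shared/private
#' decomposition (shared is symmetric; private is per side).
#'
#' @param a,b Interval data.frames (merged internally if not already).
#' @return A list with `intervals` (the overlap segments), `shared_bp`,
#'   `private_a_bp`, `private_b_bp`, `total_a_bp`, `total_b_bp`.
#' @export
intersect_total <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    inter <- empty_bed()
  } else {
    lv <- sort(unique(c(a$chrom, b$chrom)))
    inter <- gr_to_bed(GenomicRanges::intersect(bed_to_gr(a, lv),
                                                bed_to_gr(b, lv)))
  }
  shared <- if (nrow(inter)) sum(as.numeric(inter$end - inter$start)) else 0
  ta <- total_bp(a); tb <- total_bp(b)
  list(intervals = inter, shared_bp = shared,
       private_a_bp = ta - shared, private_b_bp = tb - shared,
       total_a_bp = ta, total_b_bp = tb)
}

#' Partition an individual's fragments into shared and private
#'
#' A fragment is "shared" iff it overlaps the other group's joined
#' fragments by at least 1 bp (any-overlap semantics, the fragment is kept
#' whole), as with `bedtools intersect -u`; book-ended contact does not
#' count as overlap.  The two parts partition the input exactly.
#'
#' @param ind Individual fragment data.frame (rows kept intact, extra
#'   columns preserved).
#' @param other_joined Merged joined fragments of the other group.
#' @return A list with data.frames `shared` and `private`.
#' @export
classify_individual_fragments <- function(ind, other_joined) {
  validate_intervals(ind, "individual fragments")
  if (nrow(ind) == 0) return(list(shared = ind, private = ind))
  other_joined <- merge_intervals(other_joined)
  if (nrow(other_joined) == 0)
    return(list(shared = ind[0, , drop = FALSE], private = ind))
  lv <- sort(unique(c(ind$chrom, other_joined$chrom)))
  hits <- GenomicRanges::countOverlaps(bed_to_gr(ind, lv),
                                       bed_to_gr(other_joined, lv),
                                       minoverlap = 1L)
  list(shared = ind[hits > 0, , drop = FALSE],
       private = ind[hits == 0, , drop = FALSE])
}

#' Per-window archaic frequency across individuals
#'
#' Tiles the joined fragments into `window_bp` segments (the last segment
#' of each joined block may be shorter) and, for each window, counts how
#' many distinct individuals have at least one overlapping fragment.
#' Counting distinct individuals (rather than raw overlap events) is the
#' quantity interpreted as "number of individuals"; set
#' `count = "overlaps"` for raw overlap-event counts.
#'
#' @param joined Merged joined fragments of the group.
#' @param individuals A named list of per-individual interval data.frames.
#' @param window_bp Window width in bp (default 1000).
#' @param count `"individuals"` (default) or `"overlaps"`.
#' @return A BED4-style data.frame: chrom, start, end, count.
#' @export
window_frequency <- function(joined, individuals, window_bp = 1000,
                             count = c("individuals", "overlaps")) {
  count <- match.arg(count)
  if (window_bp <= 0) stop("window_bp must be positive")
  joined <- merge_intervals(joined)
  if (nrow(joined) == 0)
    return(cbind(empty_bed(), count = integer()))
  win <- do.call(rbind, lapply(seq_len(nrow(joined)), function(i) {
    s <- seq(joined$start[i], joined$end[i] - 1, by = window_bp)
    data.frame(chrom = joined$chrom[i], start = s,
               end = pmin(s + window_bp, joined$end[i]),
               stringsAsFactors = FALSE)
  }))
  n <- integer(nrow(win))
  for (ind in individuals) {
    validate_intervals(ind, "individual fragments")
    if (nrow(ind) == 0) next
    lv <- sort(unique(c(win$chrom, ind$chrom)))
    ov <- GenomicRanges::countOverlaps(bed_to_gr(win, lv), bed_to_gr(ind, lv))
    n <- n + if (count == "individuals") (ov > 0) else ov
  }
  win$count <- as.integer(n)
  rownames(win) <- NULL
  win
}

#' Seeded down-sampling of individuals for balanced group comparisons
#'
#' @param individuals Named list of per-individual fragment sets.
#' @param n Number to keep.
#' @param seed Integer seed making the choice reproducible.
#' @return The down-sampled named list.
#' @export
downsample_individuals <- function(individuals, n, seed = 1L) {
  if (n > length(individuals)) stop("cannot downsample to more than available")
  keep <- with_local_seed(seed, sample(names(individuals), n))
  individuals[keep]
}

#' Read a BED file (3+ columns, trailing columns tolerated)
#'
#' @param path File path.
#' @return Interval data.frame with chrom, start, end plus any extra
#'   columns named `V4`, `V5`, ...
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  validate_intervals(x, basename(path))
}

#' Write an interval data.frame as BED
#'
#' @param x Interval data.frame; columns beyond chrom/start/end are written
#'   as extra BED columns.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
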