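#' Construct a recombination map
#'
#' A piecewise-constant recombination-rate track for one population:
#' per-chromosome segments (0-based half-open, tiling each chromosome)
#' with rates in cM/Mb.
#'
#' @param segments A data.frame with columns `chrom`, `start`, `end`,
#'   `rate` (cM/Mb, >= 0); segments must tile each chromosome contiguously
#'   from 0 with no gaps or overlaps.
#' @param population Population label.
#' @return An object of class `recomb_map`.
#' @export
recomb_map <- function(segments, population = "pop") {
  stopifnot(all(c("chrom", "start", "end", "rate") %in% names(segments)))
  if (any(segments$rate < 0)) stop("rates must be non-negative")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (s$start[1] != 0 || any(s$start[-1] != s$end[-nrow(s)]))
      stop("segments must tile chromosome ", ch, " contiguously from 0")
  }
  rownames(segments) <- NULL
  structure(list(population = population, segments = segments),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  gl <- genetic_length(x)
  cat(sprintf("recombination map '%s': %d chromosome(s), %d segment(s)\n",
              x$population, length(gl), nrow(x$segments)))
  for (ch in names(gl)) cat(sprintf("  %s: %.3f cM\n", ch, gl[[ch]]))
  invisible(x)
}

#' Genetic length of each chromosome in a map
#'
#' @param map A [recomb_map()].
#' @param chrom Optional chromosome name; default all.
#' @return Named numeric vector of genetic lengths in cM
#'   (sum of segment_bp * rate * 1e-6).
#' @export
genetic_length <- function(map, chrom = NULL) {
  seg <- map$segments
  if (!is.null(chrom)) seg <- seg[seg$chrom %in% chrom, , drop = FALSE]
  out <- tapply((seg$end - seg$start) * seg$rate * 1e-6, seg$chrom, sum)
  out <- out[unique(seg$chrom)]
  unlist(as.list(out))
}

#' Rescale population maps to a common per-chromosome genetic length
#'
#' Inferred maps give the same chromosome different genetic lengths in
#' different populations; since map length itself should not differ, rates
#' are rescaled per chromosome so every population matches the shortest
#' population's genetic length (each rate multiplied by l_qc / l_pc, where
#' q is the shortest population).  `mode = "printed"` instead multiplies by
#' l_pc / l_qc, which inflates rather than equalises lengths; it is kept
#' only for exact-replication experiments of that alternative convention.
#'
#' @param maps A named list of [recomb_map()] objects covering identical
#'   chromosome extents.
#' @param mode `"match-shortest"` (default; fulfils the same-total-length
#'   contract) or `"printed"`.
#' @return A list of rescaled `recomb_map` objects (same names).
#' @export
rescale_maps <- function(maps, mode = c("match-shortest", "printed")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 1)
  extents <- lapply(maps, function(m)
    tapply(m$segments$end, m$segments$chrom, max))
  for (e in extents[-1])
    if (!identical(sort(names(e)), sort(names(extents[[1]]))) ||
        any(e[sort(names(e))] != extents[[1]][sort(names(e))]))
      stop("maps cover mismatched chromosome extents")
  gl <- lapply(maps, genetic_length)
  chroms <- names(gl[[1]])
  shortest <- vapply(chroms, function(ch)
    min(vapply(gl, function(g) g[[ch]], numeric(1))), numeric(1))
  lapply(maps, function(m) {
    seg <- m$segments
    for (ch in chroms) {
      lpc <- genetic_length(m, ch)
      fac <- if (mode == "match-shortest") shortest[[ch]] / lpc else lpc / shortest[[ch]]
      if (lpc == 0) fac <- 1
      seg$rate[seg$chrom == ch] <- seg$rate[seg$chrom == ch] * fac
    }
    recomb_map(seg, m$population)
  })
}

#' Overlap-weighted mean recombination rate of a fragment
#'
#' Intersects a fragment with the map's rate segments and averages the
#' segment rates weighted by overlap_bp / fragment_bp (weights sum to 1).
#'
#' @param fragment A one-row interval data.frame (chrom, start, end) or a
#'   list/vector with those fields.
#' @param map A [recomb_map()]; the fragment must be fully covered.
#' @return Mean rate r-bar in cM/Mb.
#' @export
fragment_mean_rate <- function(fragment, map) {
  chrom <- as.character(fragment$chrom)
  start <- as.numeric(fragment$start); end <- as.numeric(fragment$end)
  if (end <= start) stop("fragment must have positive length")
  seg <- map$segments[map$segments$chrom == chrom, , drop = FALSE]
  if (!nrow(seg) || start < min(seg$start) || end > max(seg$end))
    stop("fragment extends beyond the recombination map")
  ov <- pmin(seg$end, end) - pmax(seg$start, start)
  ov[ov < 0] <- 0
  sum(seg$rate * ov) / (end - start)
}

#' Convert a physical length to genetic length
#'
#' `s(cM) = s(bp) * 1e-6 (Mb/bp) * r (cM/Mb)`.
#'
#' @param length_bp Physical length (bp, >= 0).
#' @param rate Mean recombination rate (cM/Mb, >= 0).
#' @return Genetic length in cM.
#' @examples
#' bp_to_cM(100000, 2)  # 0.2
#' @export
bp_to_cM <- function(length_bp, rate) {
  if (any(length_bp < 0)) stop("length must be non-negative")
  if (any(rate < 0)) stop("rate must be non-negative")
  length_bp * 1e-6 * rate
}

#' Annotate fragments with mean rate and genetic length
#'
#' @param fragments Interval data.frame.
#' @param map A [recomb_map()].
#' @return The input with added columns `mean_rate` (cM/Mb) and
#'   `length_cM`.
#' @export
fragments_to_cM <- function(fragments, map) {
  validate_intervals(fragments, "fragments")
  r <- vapply(seq_len(nrow(fragments)), function(i)
    fragment_mean_rate(fragments[i, ], map), numeric(1))
  fragments$mean_rate <- r
  fragments$length_cM <- bp_to_cM(fragments$end - fragments$start, r)
  fragments
}

#' Read a HapMap-style recombination map text file
#'
#' Expects whitespace- or tab-separated columns chromosome, position (bp,
#' 1-based), rate (cM/Mb), with or without a header line.  The rate on each
#' line applies from that position to the next; the final position closes
#' the map.  Converted internally to 0-based half-open segments starting at
#' 0 (rate of the first segment extends to the first listed position).
#'
#' @param path File path.
#' @param population Population label for the returned map.
#' @return A [recomb_map()].
#' @export
read_recomb_map <- function(path, population = basename(path)) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\\s+[0-9]+\\s+[0-9.eE+-]+", first) ||
    grepl("[Pp]osition|[Rr]ate|[Cc]hrom", first)
  x <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "pos", "rate")
  x$chrom <- as.character(x$chrom)
  seg <- do.call(rbind, lapply(split(x, x$chrom), function(s) {
    s <- s[order(s$pos), ]
    if (nrow(s) < 2) stop("need at least two positions per chromosome in map")
    b <- unique(c(0, s$pos - 1))            # 0-based segment boundaries
    starts <- b[-length(b)]
    idx <- findInterval(starts, s$pos - 1)  # rate of last position <= start
    idx[idx == 0] <- 1                      # extend first rate down to 0
    data.frame(chrom = s$chrom[1], start = starts, end = b[-1],
               rate = s$rate[idx], stringsAsFactors = FALSE)
  }))
  rownames(seg) <- NULL
  recomb_map(seg, population)
}

#' Write a recombination map as HapMap-style text
#'
#' @param map A [recomb_map()].
#' @param path Output path.
#' @export
write_recomb_map <- function(map, path) {
  seg <- map$segments
  out <- do.call(rbind, lapply(split(seg, seg$chrom), function(s) {
    s <- s[order(s$start), ]
    data.frame(chrom = s$chrom[1],
               pos = c(s$start[1], s$end) + 1,
               rate = c(s$rate, 0))
  }))
  names(out) <- c("Chromosome", "Position(bp)", "Rate(cM/Mb)")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
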