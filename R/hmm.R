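#' Parameters of the two-state archaic-ancestry window HMM
#'
#' The caller classifies non-overlapping genomic windows into archaic and
#' non-archaic ancestry from the density of private derived alleles: a
#' hidden two-state Markov chain along the window sequence with Poisson
#' emissions whose mean is the state rate scaled per window by
#' `callability * mutrate_scale`.
#'
#' @param p_stay_background,p_stay_archaic Self-transition probabilities,
#'   in (0, 1).
#' @param lambda_background,lambda_archaic Expected private-SNP counts per
#'   fully-callable, unit-scale window in each state.
#' @param pi_archaic Initial probability of the archaic state.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(p_stay_background = 0.999, p_stay_archaic = 0.98,
                       lambda_background = 0.02, lambda_archaic = 0.4,
                       pi_archaic = 0.02) {
  probs <- c(p_stay_background, p_stay_archaic, pi_archaic)
  if (any(probs <= 0) || any(probs >= 1))
    stop("transition and initial probabilities must be in (0, 1)")
  if (lambda_background < 0 || lambda_archaic < 0)
    stop("emission rates must be non-negative")
  structure(list(p_stay_background = p_stay_background,
                 p_stay_archaic = p_stay_archaic,
                 lambda_background = lambda_background,
                 lambda_archaic = lambda_archaic,
                 pi_archaic = pi_archaic),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "HMM: stay bg %.4f / arc %.4f, lambda bg %.4g / arc %.4g, pi_arc %.3g\n",
    x$p_stay_background, x$p_stay_archaic, x$lambda_background,
    x$lambda_archaic, x$pi_archaic))
  invisible(x)
}

validate_track <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("chrom", "start", "end", "count") %in% names(track)))
  if (!"callability" %in% names(track)) track$callability <- 1
  if (!"mutrate_scale" %in% names(track)) track$mutrate_scale <- 1
  if (any(track$count < 0)) stop("window counts must be non-negative")
  if (any(track$callability < 0 | track$callability > 1))
    stop("callability must be in [0, 1]")
  if (any(track$mutrate_scale < 0)) stop("mutrate_scale must be non-negative")
  for (ch in unique(track$chrom)) {
    s <- track[track$chrom == ch, ]
    if (is.unsorted(s$start) ||
        any(s$start[-1] != s$end[-nrow(s)]))
      stop("windows must tile chromosome ", ch, " without gaps or overlaps")
  }
  track
}

# One forward-backward sweep per chromosome; sums log-likelihood and the
# EM sufficient statistics.
fb_sweep <- function(track, params, min_callability = 0.05) {
  by_chrom <- split(track, track$chrom)
  stats <- list(loglik = 0, gamma = NULL, xi = matrix(0, 2, 2),
                first = matrix(0, 0, 2))
  gam <- vector("list", length(by_chrom))
  for (i in seq_along(by_chrom)) {
    s <- by_chrom[[i]]
    expo <- s$callability * s$mutrate_scale
    miss <- s$callability < min_callability
    fb <- hmm_forward_backward(as.integer(s$count), expo, miss,
                               params$p_stay_background,
                               params$p_stay_archaic,
                               params$lambda_background,
                               params$lambda_archaic,
                               params$pi_archaic)
    stats$loglik <- stats$loglik + fb$loglik
    stats$xi <- stats$xi + fb$xi
    stats$first <- rbind(stats$first, fb$gamma[1, , drop = FALSE])
    gam[[i]] <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                           posterior_archaic = fb$gamma[, 2],
                           exposure = expo, missing = miss,
                           count = s$count, stringsAsFactors = FALSE)
  }
  stats$gamma <- do.call(rbind, gam)
  stats
}

#' Fit the window HMM by expectation-maximisation
#'
#' Baum-Welch on the Poisson-emission two-state chain: the E-step runs a
#' scaled forward-backward sweep per chromosome; the M-step re-estimates
#' the state rates as posterior-weighted counts over posterior-weighted
#' exposures and the self-transition probabilities from expected
#' transition counts.  Windows with callability below `min_callability`
#' are treated as missing (no emission term, transitions still apply).
#' The log-likelihood is non-decreasing across iterations; fitting stops
#' when the improvement drops below `tol` or after `max_iter` iterations.
#' An all-zero track yields a degenerate fit (rates collapse towards 0),
#' returned with `degenerate = TRUE` and a warning.
#'
#' @param track Window track data.frame (`chrom`, `start`, `end`, `count`,
#'   optionally `callability`, `mutrate_scale`), >= 100 windows.
#' @param init Optional [hmm_params()] starting point; by default the
#'   emission rates are initialised from the 50th and 99th percentiles of
#'   the exposure-corrected counts.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param min_callability Windows below this callability are missing.
#' @return An `hmm_fit`: list with `params` (fitted [hmm_params()]),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `degenerate`.
#' @export
fit_hmm <- function(track, init = NULL, max_iter = 500, tol = 1e-6,
                    min_callability = 0.05) {
  track <- validate_track(track)
  if (nrow(track) < 100) stop("need at least 100 windows to fit the HMM")
  expo <- track$callability * track$mutrate_scale
  usable <- track$callability >= min_callability & expo > 0
  degenerate <- FALSE
  if (is.null(init)) {
    if (!any(usable) || all(track$count[usable] == 0)) {
      warning("all usable window counts are zero; degenerate fit")
      return(structure(list(
        params = hmm_params(lambda_background = 0, lambda_archaic = 0),
        loglik = NA_real_, loglik_trace = numeric(0), n_iter = 0L,
        converged = FALSE, degenerate = TRUE), class = "hmm_fit"))
    }
    dens <- track$count[usable] / expo[usable]
    q <- stats::quantile(dens, c(0.5, 0.99), names = FALSE)
    l_b <- max(q[1], 1e-3)
    l_a <- max(q[2], 2 * l_b)
    init <- hmm_params(lambda_background = l_b, lambda_archaic = l_a)
  }
  params <- init
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- fb_sweep(track, params, min_callability)
    trace <- c(trace, st$loglik)
    g <- st$gamma
    ok <- !g$missing & g$exposure > 0
    denom <- c(sum(g$posterior_archaic[ok] * g$exposure[ok]),
               sum((1 - g$posterior_archaic[ok]) * g$exposure[ok]))
    num <- c(sum(g$posterior_archaic[ok] * g$count[ok]),
             sum((1 - g$posterior_archaic[ok]) * g$count[ok]))
    l_a <- if (denom[1] > 0) num[1] / denom[1] else 0
    l_b <- if (denom[2] > 0) num[2] / denom[2] else 0
    if (l_a <= 0 || l_b <= 0) degenerate <- TRUE
    clamp <- function(p) min(max(p, 1e-6), 1 - 1e-6)
    p_bb <- clamp(st$xi[1, 1] / max(sum(st$xi[1, ]), 1e-12))
    p_aa <- clamp(st$xi[2, 2] / max(sum(st$xi[2, ]), 1e-12))
    pi_a <- clamp(mean(st$first[, 2]))
    params <- hmm_params(p_stay_background = p_bb, p_stay_archaic = p_aa,
                         lambda_background = l_b, lambda_archaic = l_a,
                         pi_archaic = pi_a)
    if (it > 1 && trace[it] - trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
  }
  # keep the archaic state the denser one
  if (params$lambda_archaic < params$lambda_background) {
    params <- hmm_params(p_stay_background = params$p_stay_archaic,
                         p_stay_archaic = params$p_stay_background,
                         lambda_background = params$lambda_archaic,
                         lambda_archaic = params$lambda_background,
                         pi_archaic = 1 - params$pi_archaic)
  }
  if (degenerate) warning("degenerate emission rates during fitting")
  structure(list(params = params, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = length(trace),
                 converged = converged, degenerate = degenerate),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("HMM fit: loglik %.2f after %d iteration(s)%s%s\n",
              x$loglik, x$n_iter,
              if (x$converged) " (converged)" else "",
              if (x$degenerate) " [degenerate]" else ""))
  print(x$params)
  invisible(x)
}

#' Decode archaic fragments from a fitted window HMM
#'
#' Computes forward-backward posteriors per window and reports maximal
#' runs of windows with archaic posterior > 0.5 as fragments, each
#' annotated with its mean archaic posterior and length.  The
#' high-confidence subset comprises fragments with mean posterior at or
#' above `posterior_threshold`.
#'
#' @param track Window track data.frame (see [fit_hmm()]).
#' @param params An [hmm_params()] object (or an `hmm_fit`).
#' @param posterior_threshold High-confidence cutoff in (0.5, 1]
#'   (default 0.8).
#' @param min_callability Missing-window cutoff as in [fit_hmm()].
#' @return A data.frame of fragments: `chrom`, `start`, `end`,
#'   `mean_posterior`, `length`, `high_confidence`.
#' @export
decode_fragments <- function(track, params, posterior_threshold = 0.8,
                             min_callability = 0.05) {
  if (inherits(params, "hmm_fit")) params <- params$params
  if (posterior_threshold <= 0.5 || posterior_threshold > 1)
    stop("posterior_threshold must be in (0.5, 1]")
  track <- validate_track(track)
  g <- fb_sweep(track, params, min_callability)$gamma
  frags <- list()
  for (ch in unique(g$chrom)) {
    s <- g[g$chrom == ch, ]
    arc <- s$posterior_archaic > 0.5
    if (!any(arc)) next
    r <- rle(arc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      frags[[length(frags) + 1]] <- data.frame(
        chrom = ch, start = s$start[i0], end = s$end[i1],
        mean_posterior = mean(s$posterior_archaic[i0:i1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(frags))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_posterior = numeric(),
                      length = numeric(), high_confidence = logical()))
  out <- do.call(rbind, frags)
  out$length <- out$end - out$start
  out$high_confidence <- out$mean_posterior >= posterior_threshold
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}

#' Posterior archaic probabilities per window
#'
#' @param track Window track data.frame.
#' @param params An [hmm_params()] or `hmm_fit`.
#' @param min_callability Missing-window cutoff.
#' @return The track with an added `posterior_archaic` column.
#' @export
hmm_posteriors <- function(track, params, min_callability = 0.05) {
  if (inherits(params, "hmm_fit")) params <- params$params
  track <- validate_track(track)
  g <- fb_sweep(track, params, min_callability)$gamma
  g[c("chrom", "start", "end", "count", "posterior_archaic")]
}
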