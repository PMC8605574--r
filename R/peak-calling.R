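#' Median-standardize replicate probe tracks
#'
#' Standardizes every track to mean 0, sd 1 and returns one track whose value
#' per probe is the median across replicates ("median standardized array
#' values").  All tracks must share one probe grid.
#'
#' @param tracks List of probe-track data.frames (`chrom`, `start`, `end`,
#'   `log2_ratio`, `replicate`).
#' @return One probe-track data.frame with `replicate = "median"`.
#' @export
median_standardize <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  ref <- tracks[[1L]][c("chrom", "start", "end")]
  z <- vapply(tracks, function(tr) {
    if (!identical(tr[c("chrom", "start", "end")], ref))
      stop("probe grids differ between replicates")
    s <- stats::sd(tr$log2_ratio)
    if (!is.finite(s) || s == 0) stop("zero-variance track")
    (tr$log2_ratio - mean(tr$log2_ratio)) / s
  }, numeric(nrow(ref)))
  data.frame(ref, log2_ratio = apply(z, 1L, stats::median),
             replicate = "median", stringsAsFactors = FALSE)
}

#' Sliding-window peak calling with a mirrored-Gaussian null
#'
#' The published sliding-window scheme for tiling arrays: windows of
#' `window_bp` tile each chromosome at `step_bp`; a window's score is the
#' mean log2 ratio of probes overlapping it.  The null is a zero-mean
#' Gaussian whose sd is estimated by mirroring the negative window scores
#' about zero (the signal is assumed one-sided positive, so the negative tail
#' is pure noise); one-sided p-values are Bonferroni-corrected over the
#' number of scored windows.  Significant windows that overlap or abut are
#' merged, and each merged peak carries the smallest adjusted p among its
#' windows.
#'
#' @param track A probe-track data.frame.
#' @param window_bp,step_bp Window and step size in bp (defaults 500/125,
#'   matching a 200-1000 bp chromatin fragment size).
#' @param alpha Significance cut-off on the Bonferroni-adjusted p (0.05).
#' @param assembly Optional assembly for chromosome lengths; inferred from
#'   the probe grid when absent.
#' @return A `GRanges` of peaks with metadata `window_p` (smallest adjusted
#'   p) and `n_windows` (significant windows merged).
#' @export
call_peaks <- function(track, window_bp = 500L, step_bp = 125L, alpha = 0.05,
                       assembly = NULL) {
  stopifnot(alpha > 0, alpha < 1, window_bp > 0, step_bp > 0)
  lens <- if (!is.null(assembly)) chrom_lengths(assembly) else
    vapply(split(track$end, track$chrom), max, numeric(1))
  chroms <- unique(track$chrom)
  win <- list()
  for (ch in chroms) {
    tr <- track[track$chrom == ch, ]
    if (nrow(tr) == 0L) stop("no probes on chromosome ", ch)
    o <- order(tr$start)
    ps <- tr$start[o]; pe <- tr$end[o]; pv <- tr$log2_ratio[o]
    L <- lens[[ch]]
    ws <- seq.int(0L, max(0L, L - 1L), by = step_bp)
    we <- pmin(ws + window_bp, L)
    ## probes overlap window [ws, we): probe end > ws and probe start < we
    lo <- findInterval(ws, pe) + 1L
    hi <- findInterval(we - 1L, ps)
    n <- hi - lo + 1L
    keep <- n >= 1L
    cv <- cumsum(c(0, pv))
    score <- (cv[hi[keep] + 1L] - cv[lo[keep]]) / n[keep]
    win[[ch]] <- data.frame(chrom = ch, start = ws[keep], end = we[keep],
                            score = score, stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, win)
  neg <- win$score[win$score < 0]
  if (length(neg) == 0L)
    stop("all window scores are positive; cannot estimate the noise null")
  sd0 <- sqrt(mean(neg^2))
  p <- stats::pnorm(win$score, mean = 0, sd = sd0, lower.tail = FALSE)
  p_adj <- pmin(1, p * nrow(win))
  sig <- win[p_adj <= alpha, , drop = FALSE]
  sig_p <- p_adj[p_adj <= alpha]
  if (nrow(sig) == 0L)
    return(GenomicRanges::GRanges(seqlengths = lens))
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start + 1L, sig$end),
                               seqlengths = lens)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  S4Vectors::mcols(merged)$window_p <-
    vapply(split(sig_p[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits)), min, numeric(1))
  S4Vectors::mcols(merged)$n_windows <-
    as.integer(table(S4Vectors::queryHits(hits)))
  merged
}

#' Replicate consensus of peak sets
#'
#' Candidate regions are the union of all peaks across replicates; a merged
#' region is retained iff peaks from at least `min_support` distinct
#' replicates intersect it by >= 1 bp ("present in at least 3 out of 5
#' independent experiments").
#'
#' @param peaksets List of `GRanges`, one per replicate.
#' @param min_support Minimum number of supporting replicates (default 3).
#' @return A `GRanges` of consensus regions with metadata `support` and,
#'   when available, `window_p` (the smallest adjusted p among supporting
#'   peaks).
#' @export
replicate_consensus <- function(peaksets, min_support = 3L) {
  stopifnot(length(peaksets) >= min_support)
  all_peaks <- do.call(c, lapply(peaksets, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  }))
  if (length(all_peaks) == 0L) return(all_peaks)
  merged <- GenomicRanges::reduce(sort(all_peaks))
  support <- rep(0L, length(merged))
  best_p <- rep(NA_real_, length(merged))
  for (g in peaksets) {
    hits <- GenomicRanges::findOverlaps(merged, g)
    qh <- unique(S4Vectors::queryHits(hits))
    support[qh] <- support[qh] + 1L
    if (!is.null(S4Vectors::mcols(g)$window_p) && length(hits)) {
      p_by_region <- vapply(
        split(S4Vectors::mcols(g)$window_p[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits)), min, numeric(1))
      i <- as.integer(names(p_by_region))
      best_p[i] <- pmin(best_p[i], p_by_region, na.rm = TRUE)
    }
  }
  keep <- support >= min_support
  out <- merged[keep]
  S4Vectors::mcols(out)$support <- support[keep]
  S4Vectors::mcols(out)$window_p <- best_p[keep]
  out
}

#' Remove peaks overlapping telomeric windows
#'
#' Peaks intersecting any telomere window by >= 1 bp are removed whole (not
#' trimmed); a peak that merely abuts a window boundary is retained.
#'
#' @param peaks `GRanges` of peaks.
#' @param telomere_set `GRanges` of telomere windows ([telomere_windows()]).
#' @return The retained `GRanges` (the non-telomeric site set).
#' @export
subtract_telomeric <- function(peaks, telomere_set) {
  peaks[!IRanges::overlapsAny(peaks, telomere_set, minoverlap = 1L)]
}
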