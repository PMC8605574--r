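#' Count query intervals overlapping a subject set
#'
#' Number of `query` intervals intersecting at least one `subject` interval
#' by >= 1 bp; each query interval is counted at most once (the field-standard
#' "k / n sites" numerator).
#'
#' @param query,subject `GRanges` on one assembly.
#' @return Integer count.
#' @export
count_site_overlaps <- function(query, subject) {
  sum(GenomicRanges::countOverlaps(query, subject, minoverlap = 1L) > 0L)
}

## ---- fast internal machinery (plain vectors, 0-based half-open) -----------
## Used inside permutation loops where building GRanges per iteration would
## dominate runtime.

# Merge intervals into disjoint sorted form; s, e are 0-based half-open.
merge_intervals0 <- function(s, e) {
  if (length(s) == 0L) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me[k]) me[k] <- max(me[k], e[i])
    else { k <- k + 1L; ms[k] <- s[i]; me[k] <- e[i] }
  }
  list(s = ms, e = me)
}

# For query intervals [qs, qe) and a merged subject (ms, me): TRUE where the
# query hits any subject interval.
hits_any0 <- function(qs, qe, ms, me) {
  if (length(ms) == 0L) return(rep(FALSE, length(qs)))
  idx <- findInterval(qs, ms)
  hit <- idx >= 1L & me[pmax(idx, 1L)] > qs
  more <- idx < length(ms)
  hit[more] <- hit[more] | ms[idx[more] + 1L] < qe[more]
  hit
}

# Split a GRanges into per-chromosome 0-based merged interval lists.
as_merged_by_chrom <- function(gr) {
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1
  e <- as.numeric(GenomicRanges::end(gr))
  lapply(split(seq_along(ch), ch), function(i) merge_intervals0(s[i], e[i]))
}

# Sample non-overlapping starts for intervals of widths w on [0, L), avoiding
# the merged exclusion (ex). Round-based rejection; deterministic given RNG.
shuffle_starts0 <- function(w, L, ex = NULL, max_rounds = 200L) {
  n <- length(w)
  if (n == 0L) return(numeric(0))
  avail <- L - w
  if (any(avail < 0)) stop("interval longer than chromosome")
  starts <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    prop <- floor(stats::runif(length(todo)) * (avail[todo] + 1))
    if (!is.null(ex) && length(ex$s))
      bad <- hits_any0(prop, prop + w[todo], ex$s, ex$e)
    else bad <- rep(FALSE, length(todo))
    starts[todo[!bad]] <- prop[!bad]
    ## resolve self-overlaps among all currently placed intervals greedily:
    ## keep the earliest (by start) of each clashing run, re-draw the rest
    placed <- which(!is.na(starts))
    o <- placed[order(starts[placed])]
    keep <- rep(TRUE, length(o))
    if (length(o) > 1L) {
      last_end <- starts[o[1]] + w[o[1]]
      for (i in seq_along(o)[-1]) {
        if (starts[o[i]] < last_end) keep[i] <- FALSE
        else last_end <- starts[o[i]] + w[o[i]]
      }
    }
    starts[o[!keep]] <- NA_real_
    todo <- which(is.na(starts))
    if (length(todo) == 0L) return(starts)
  }
  stop("could not place ", length(todo),
       " shuffled interval(s) after ", max_rounds, " rounds")
}

## ---------------------------------------------------------------------------

#' Randomly relocate intervals within their chromosomes
#'
#' Each interval keeps its length and chromosome; its new start is uniform
#' over the valid positions.  Placements avoid `exclude` and do not overlap
#' each other.  This is the randomization engine behind the permutation
#' tests ("randomized control regions").
#'
#' @param gr `GRanges` to shuffle.
#' @param assembly See [chrom_lengths()].
#' @param exclude Optional `GRanges` that shuffled intervals must avoid.
#' @param seed Optional seed.
#' @param max_rounds Bounded retries before giving up on a placement.
#' @return A `GRanges` parallel to `gr` (same order, names and widths).
#' @export
shuffle_intervals <- function(gr, assembly, exclude = NULL, seed = NULL,
                              max_rounds = 200L) {
  lens <- chrom_lengths(assembly)
  validate_intervals(gr, assembly, "interval")
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  w <- GenomicRanges::width(gr)
  ex <- if (!is.null(exclude) && length(exclude)) as_merged_by_chrom(exclude)
  new_start <- numeric(length(gr))
  with_seed_if(seed, {
    for (c0 in unique(ch)) {
      i <- which(ch == c0)
      new_start[i] <- shuffle_starts0(w[i], lens[[c0]], ex[[c0]], max_rounds)
    }
  })
  out <- GenomicRanges::GRanges(ch, IRanges::IRanges(new_start + 1L,
                                                     new_start + w),
                                seqlengths = lens)
  names(out) <- names(gr)
  out
}

#' Permutation test for interval-set overlap enrichment
#'
#' The observed statistic is the number of `query` intervals overlapping
#' `subject` (see [count_site_overlaps()]).  The null is built by shuffling
#' the query within chromosomes `n_iter` times and recounting; the one-sided
#' (enrichment) empirical p uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_iter)`, so p is never 0 and its
#' floor is `1 / (n_iter + 1)`.
#'
#' @param query,subject `GRanges` on one assembly.
#' @param assembly See [chrom_lengths()].
#' @param n_iter Number of shuffles (default 1000; resolving p < 1e-4 needs
#'   >= 10000).
#' @param seed Optional seed.
#' @param exclude Optional `GRanges` the shuffled placements must avoid.
#' @return An object of class `perm_test`: `observed`, `null` (vector),
#'   `p_value`, `n_iter`, `statistic` label.
#' @export
overlap_permutation_test <- function(query, subject, assembly,
                                     n_iter = 1000L, seed = NULL,
                                     exclude = NULL) {
  stopifnot(n_iter >= 1L)
  lens <- chrom_lengths(assembly)
  validate_intervals(query, assembly, "query interval")
  subj <- as_merged_by_chrom(subject)
  ch <- as.character(GenomeInfoDb::seqnames(query))
  qs <- GenomicRanges::start(query) - 1
  qe <- as.numeric(GenomicRanges::end(query))
  w <- GenomicRanges::width(query)
  ex <- if (!is.null(exclude) && length(exclude)) as_merged_by_chrom(exclude)
  groups <- split(seq_along(ch), ch)

  count_fast <- function(starts_by_group) {
    tot <- 0L
    for (c0 in names(groups)) {
      i <- groups[[c0]]
      sb <- subj[[c0]]
      if (is.null(sb)) next
      st <- starts_by_group[[c0]]
      tot <- tot + sum(hits_any0(st, st + w[i], sb$s, sb$e))
    }
    tot
  }

  observed <- count_fast(lapply(groups, function(i) qs[i]))
  null <- integer(n_iter)
  with_seed_if(seed, {
    for (k in seq_len(n_iter)) {
      st <- lapply(names(groups), function(c0) {
        shuffle_starts0(w[groups[[c0]]], lens[[c0]], ex[[c0]])
      })
      names(st) <- names(groups)
      null[k] <- count_fast(st)
    }
  })
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_iter),
                 n_iter = n_iter, statistic = "overlap count",
                 n_query = length(query)),
            class = "perm_test")
}

#' Permutation test for GC-content enrichment
#'
#' The statistic is [gc_content()] of the set; the null distribution comes
#' from GC content of within-chromosome shuffles.  One-sided (G-richness)
#' empirical p with the add-one rule.
#'
#' @inheritParams overlap_permutation_test
#' @param set `GRanges` whose composition is tested.
#' @param assembly A named `DNAStringSet` carrying sequence.
#' @return A `perm_test` object (statistic "gc fraction").
#' @export
gc_permutation_test <- function(set, assembly, n_iter = 1000L, seed = NULL,
                                exclude = NULL) {
  stopifnot(methods::is(assembly, "DNAStringSet"), n_iter >= 1L)
  observed <- gc_content(set, assembly)
  null <- numeric(n_iter)
  with_seed_if(seed, {
    for (k in seq_len(n_iter)) {
      sh <- shuffle_intervals(set, assembly, exclude = exclude)
      null[k] <- gc_content(sh, assembly)
    }
  })
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_iter),
                 n_iter = n_iter, statistic = "gc fraction",
                 n_query = length(set)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$statistic, ")\n", sep = "")
  cat("  observed:", format(x$observed, digits = 4),
      " null mean:", format(mean(x$null), digits = 4),
      "+/-", format(stats::sd(x$null), digits = 3), "\n")
  cat("  empirical p =", format(x$p_value, digits = 4),
      "(", x$n_iter, "iterations, one-sided )\n")
  invisible(x)
}
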