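# Shared fixtures for the test suite: everything is generated in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# A small, fast study configuration for unit tests (the full-scale defaults
# are exercised in test-acceptance.R).
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chrom = 4L, chrom_length_bp = 100000L,
               n_ntbs = 8L, telomere_window_bp = 5000L, n_pairs = 5e4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Deterministic random assembly without planted structure.
random_assembly <- function(lens = c(chrA = 20000L, chrB = 15000L),
                            seed = 42L, gc = 0.5) {
  withr::with_seed(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(lens)
  out
}

# Random interval set on an assembly.
random_intervals <- function(assembly, n, width = 100L, seed = 7L) {
  lens <- chrom_lengths(assembly)
  withr::with_seed(seed, {
    ch <- sample(names(lens), n, replace = TRUE)
    st <- vapply(ch, function(c0) sample.int(lens[[c0]] - width, 1L),
                 integer(1))
  })
  GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + width - 1L),
                         seqlengths = lens)
}

# Brute-force O(n * m) overlap counter used as an independent oracle.
brute_count_overlaps <- function(query, subject) {
  qc <- as.character(seqnames(query)); sc <- as.character(seqnames(subject))
  qs <- start(query); qe <- end(query)
  ss <- start(subject); se <- end(subject)
  n <- 0L
  for (i in seq_along(query)) {
    hit <- FALSE
    for (j in seq_along(subject)) {
      if (qc[i] == sc[j] && qs[i] <= se[j] && ss[j] <= qe[i]) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

# Naive two-vector alternating row/column normalization, run long past the
# package default, as an independent balancing oracle.
brute_balance <- function(m, iters = 10000L) {
  supp <- rowSums(m) > 0
  S <- m[supp, supp, drop = FALSE]
  for (k in seq_len(iters)) {
    S <- S / rowSums(S)
    S <- t(t(S) / colSums(S))
  }
  out <- matrix(0, nrow(m), ncol(m))
  out[supp, supp] <- S
  out
}
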