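#' Generate a toy genome with planted TG-rich binding sites
#'
#' Background bases are drawn i.i.d. with per-base GC probability
#' `config$base_gc`; planted sites are TG-biased stretches with GC
#' `config$ntbs_gc` (G carries most of the GC and T most of the AT, giving
#' the TG-richness of telomere-like repeats).  Sites are placed without
#' overlap, separated by at least `ntbs_min_gap_bp`, and entirely outside the
#' telomere windows, so every planted site is a non-telomeric site by
#' construction.
#'
#' @param config A [synthetic_config()].
#' @return A list with `assembly` (named `DNAStringSet`) and `ntbs` (a named
#'   `GRanges` of planted site coordinates, the ground-truth answer key).
#' @export
make_genome <- function(config) {
  lens <- config_chrom_lengths(config)
  w <- config$ntbs_width_bp
  ## placement margin: the telomere window plus one contact-map bin, so a
  ## site's bin never abuts a telomere bin (proportional read binning bleeds
  ## near-diagonal mass across bin boundaries; see the methods vignette)
  tw <- config$telomere_window_bp + config$bin_size
  interior <- pmax(lens - 2L * tw - w + 1L, 0L)  # available start positions
  if (sum(interior > 0) == 0 || config$n_ntbs > sum(interior %/% (w + config$ntbs_min_gap_bp)))
    stop("genome too small to place ", config$n_ntbs, " sites of ", w, " bp")

  with_seed_if(derive_seed(config$seed, 1L), {
    ## placement (0-based starts), rejection sampling with a spacing buffer
    placed_chrom <- character(config$n_ntbs)
    placed_start <- integer(config$n_ntbs)
    occupied <- lapply(lens, function(...) matrix(numeric(0), ncol = 2))
    used_bin <- character(0)   # one site per contact-map bin (see vignette)
    gap <- config$ntbs_min_gap_bp
    for (i in seq_len(config$n_ntbs)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        ch <- sample(names(lens), 1L, prob = interior / sum(interior))
        s <- tw + sample.int(interior[[ch]], 1L) - 1L
        occ <- occupied[[ch]]
        bin <- paste0(ch, ":", (s + w %/% 2) %/% config$bin_size)
        if ((nrow(occ) == 0 ||
             all(s + w + gap <= occ[, 1] | s >= occ[, 2] + gap)) &&
            !(bin %in% used_bin)) {
          occupied[[ch]] <- rbind(occ, c(s, s + w))
          used_bin <- c(used_bin, bin)
          placed_chrom[i] <- ch; placed_start[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place site ", i, " without overlap")
    }

    ## sequence: background then planted stretches
    bases <- c("A", "C", "G", "T")
    p_bg <- c(0.5 * (1 - config$base_gc), 0.5 * config$base_gc,
              0.5 * config$base_gc, 0.5 * (1 - config$base_gc))
    p_tg <- c(0.15 * (1 - config$ntbs_gc), 0.15 * config$ntbs_gc,
              0.85 * config$ntbs_gc, 0.85 * (1 - config$ntbs_gc))
    seqs <- lapply(names(lens), function(ch) {
      x <- sample.int(4L, lens[[ch]], replace = TRUE, prob = p_bg)
      for (j in which(placed_chrom == ch)) {
        idx <- (placed_start[j] + 1L):(placed_start[j] + w)
        x[idx] <- sample.int(4L, w, replace = TRUE, prob = p_tg)
      }
      paste(bases[x], collapse = "")
    })
  })

  assembly <- Biostrings::DNAStringSet(unlist(seqs))
  names(assembly) <- names(lens)
  ord <- order(match(placed_chrom, names(lens)), placed_start)
  ntbs <- GenomicRanges::GRanges(placed_chrom[ord],
                                 IRanges::IRanges(placed_start[ord] + 1L,
                                                  placed_start[ord] + w),
                                 seqlengths = lens)
  names(ntbs) <- sprintf("ntbs_%03d", seq_along(ntbs))
  list(assembly = assembly, ntbs = ntbs)
}

#' Generate a feature track with a controlled overlap count
#'
#' Places `n_features` intervals so that exactly `n_overlapping` of them
#' intersect distinct planted sites by at least 1 bp and the remainder avoid
#' all planted sites.  Used to emulate published feature tracks (G4 regions,
#' R-loops, helicase binding sites, DNA-damage marks) whose overlap with the
#' binding-site set is known by construction.
#'
#' @param planted_ntbs `GRanges` of planted sites.
#' @param assembly See [chrom_lengths()].
#' @param n_features,n_overlapping Total features and how many must overlap.
#' @param feature_width_bp Feature width (default 500).
#' @param seed Optional seed.
#' @return A `GRanges` of features.
#' @export
make_feature_track <- function(planted_ntbs, assembly, n_features,
                               n_overlapping, feature_width_bp = 500L,
                               seed = NULL) {
  stopifnot(n_overlapping <= n_features, n_overlapping <= length(planted_ntbs))
  lens <- chrom_lengths(assembly)
  fw <- as.integer(feature_width_bp)
  with_seed_if(seed, {
    out_chrom <- character(0); out_start <- integer(0)
    if (n_overlapping > 0) {
      hit <- sample(seq_along(planted_ntbs), n_overlapping)
      for (j in hit) {
        ch <- as.character(GenomeInfoDb::seqnames(planted_ntbs))[j]
        s0 <- GenomicRanges::start(planted_ntbs)[j] - 1L
        e0 <- GenomicRanges::end(planted_ntbs)[j]
        lo <- max(0L, s0 - fw + 1L)
        hi <- min(e0 - 1L, lens[[ch]] - fw)
        st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        out_chrom <- c(out_chrom, ch); out_start <- c(out_start, st)
      }
    }
    n_bg <- n_features - n_overlapping
    if (n_bg > 0) {
      pl <- split(planted_ntbs, GenomeInfoDb::seqnames(planted_ntbs))
      k <- 0L
      while (k < n_bg) {
        ch <- sample(names(lens), 1L, prob = lens / sum(lens))
        st <- sample.int(lens[[ch]] - fw + 1L, 1L) - 1L
        p <- pl[[ch]]
        clash <- length(p) > 0 &&
          any(st < GenomicRanges::end(p) & st + fw > GenomicRanges::start(p) - 1L)
        if (!clash) {
          out_chrom <- c(out_chrom, ch); out_start <- c(out_start, st)
          k <- k + 1L
        }
      }
    }
  })
  gr <- GenomicRanges::GRanges(out_chrom,
                               IRanges::IRanges(out_start + 1L, out_start + fw),
                               seqlengths = lens)
  sort(gr)
}

#' Generate colony counts for the telomere-healing assay
#'
#' Resistant-colony counts are drawn as `Binomial(n_colonies, freq)` per
#' construct: the genetic readout in which loss of the distal marker (scored
#' by alpha-aminoadipate resistance) reports de novo telomere addition at the
#' break.  `freq = 1` models a pure telomeric-repeat control (TG80), `freq =
#' 0` a non-telomeric control (N80).
#'
#' @param freq Named (or unnamed) vector of telomere-addition frequencies in
#'   `[0, 1]`, one per construct.
#' @param n_colonies Total colonies per construct (scalar or vector).
#' @param seed Optional seed.
#' @return A data.frame with columns `construct`, `total`, `resistant`.
#' @export
make_healing_counts <- function(freq, n_colonies, seed = NULL) {
  stopifnot(all(freq >= 0 & freq <= 1), all(n_colonies > 0))
  nm <- names(freq)
  if (is.null(nm)) nm <- sprintf("construct_%d", seq_along(freq))
  total <- as.integer(rep_len(n_colonies, length(freq)))
  res <- with_seed_if(seed, stats::rbinom(length(freq), total, freq))
  data.frame(construct = nm, total = total, resistant = res,
             stringsAsFactors = FALSE)
}
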