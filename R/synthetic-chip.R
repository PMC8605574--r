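#' Generate replicate tiling-array probe tracks
#'
#' Probes tile every chromosome on a regular grid; background log2 IP/input
#' ratios are `Normal(0, noise_sd)`.  In each replicate, each planted site is
#' detected independently with probability `replicate_detect_prob` (dropout
#' models replicate irreproducibility); probes overlapping a detected site
#' are shifted by `+peak_amplitude * noise_sd`.
#'
#' @param assembly See [chrom_lengths()].
#' @param planted `GRanges` of planted sites.
#' @param config A [synthetic_config()].
#' @param n_reps Number of replicates (default `config$n_reps`).
#' @return A list of probe-track data.frames with columns `chrom`, `start`,
#'   `end` (0-based half-open), `log2_ratio`, `replicate`.
#' @export
make_chip_replicates <- function(assembly, planted, config,
                                 n_reps = config$n_reps) {
  lens <- chrom_lengths(assembly)
  sp <- config$probe_spacing_bp
  pw <- min(config$probe_width_bp, sp)
  grid <- do.call(rbind, lapply(names(lens), function(ch) {
    st <- seq.int(0L, lens[[ch]] - pw, by = sp)
    data.frame(chrom = ch, start = st, end = st + pw, stringsAsFactors = FALSE)
  }))
  n_probes <- nrow(grid)
  probes_gr <- GenomicRanges::GRanges(grid$chrom,
                                      IRanges::IRanges(grid$start + 1L, grid$end))
  hits <- GenomicRanges::findOverlaps(probes_gr, planted)
  amp <- config$peak_amplitude * config$noise_sd

  with_seed_if(derive_seed(config$seed, 2L), {
    lapply(seq_len(n_reps), function(r) {
      v <- stats::rnorm(n_probes, 0, config$noise_sd)
      detected <- stats::runif(length(planted)) < config$replicate_detect_prob
      on <- S4Vectors::queryHits(hits)[detected[S4Vectors::subjectHits(hits)]]
      v[on] <- v[on] + amp
      data.frame(grid, log2_ratio = v, replicate = r, stringsAsFactors = FALSE)
    })
  })
}

#' Read / write probe-track tables
#'
#' Tab-delimited, one probe per row: `chrom`, `start`, `end` (0-based
#' half-open), `log2_ratio`, `replicate`.  Multiple replicates may share one
#' file; [read_probe_tracks()] returns one data.frame per replicate.
#'
#' @param tracks A probe-track data.frame or list of them.
#' @param path File path.
#' @return For the reader, a list of probe-track data.frames.
#' @export
write_probe_tracks <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, tracks)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_tracks
#' @export
read_probe_tracks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "log2_ratio", "replicate")
  if (!all(need %in% names(df)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$log2_ratio))) stop("non-finite log2 ratios in ", path)
  unname(split(df, df$replicate))
}
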