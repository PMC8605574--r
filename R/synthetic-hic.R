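# Ground-truth contact model for the synthetic Hi-C generator.
#
# The truth is a symmetric weight matrix over genome bins built from:
#   1. intra-chromosomal distance decay  w(s) ~ s^-alpha  (s in bins; the
#      self-bin diagonal is set to twice the one-bin contact),
#   2. a uniform inter-chromosomal floor,
#   3. a Rabl-like telomere cluster: telomere-bin x telomere-bin contacts
#      multiplied by `telomere_boost`, telomere-bin x internal-bin contacts
#      multiplied by `tel_arm_depletion` (< 1),
#   4. an NTBS compartment: NTBS-bin x NTBS-bin contacts multiplied by
#      `ntbs_affinity`; the matrix is then Sinkhorn-balanced so every locus
#      keeps a unit contact budget,
#   5. a set-wide NTBS-telomere affinity: contacts between every NTBS bin
#      and the two telomere bins of its own chromosome multiplied by
#      `ntbs_tel_affinity`,
#   6. the planted truth: a random ceiling(f * n_sites) subset of sites gets
#      its cis-telomere contacts SET to `planted_tel_level` (telomere-level
#      contact), making those sites telomere-proximal by construction.
build_truth_map <- function(lens, ntbs_bins, planted_bins, config) {
  bin_size <- config$bin_size
  bins <- make_bins(lens, bin_size)
  nb_per <- as.integer(ceiling(lens / bin_size))
  offset <- c(0L, cumsum(nb_per))[seq_along(lens)]
  n <- nrow(bins)
  chrom_id <- rep(seq_along(lens), nb_per)
  local <- unlist(lapply(nb_per, seq_len)) - 1L

  W <- matrix(config$trans_floor, n, n)
  for (i in seq_along(lens)) {
    idx <- which(chrom_id == i)
    d <- abs(outer(local[idx], local[idx], "-"))
    w <- ifelse(d == 0, 2, d^(-config$decay_exponent))
    W[idx, idx] <- w
  }
  tel <- sort(unlist(lapply(seq_along(lens), function(i)
    c(offset[i] + 1L, offset[i] + nb_per[i]))))
  is_tel <- seq_len(n) %in% tel
  W[is_tel, !is_tel] <- W[is_tel, !is_tel] * config$tel_arm_depletion
  W[!is_tel, is_tel] <- W[!is_tel, is_tel] * config$tel_arm_depletion
  W[is_tel, is_tel] <- W[is_tel, is_tel] * config$telomere_boost

  ## baseline: unit contact budget per locus, before the NTBS compartment.
  ## Its telomere entries are the reference level a random locus has, so the
  ## set-wide NTBS-telomere affinity below is expressed relative to controls
  ## and survives the balancing of the sampled map.
  balanced <- function(mat) {
    cm0 <- new_contact_matrix(mat, bins, bin_size, lens, state = "raw")
    balance_matrix(cm0, tol = 1e-10, max_iter = 2000L)$matrix
  }
  B0 <- balanced(W)

  ub <- unique(ntbs_bins)
  if (length(ub) > 1) {
    off_diag <- outer(ub, ub, "!=")
    W[ub, ub][off_diag] <- W[ub, ub][off_diag] * config$ntbs_affinity
  }
  W <- balanced(W)

  cis_tel_of <- function(b) {
    i <- chrom_id[b]
    c(offset[i] + 1L, offset[i] + nb_per[i])
  }
  for (b in ub) {
    tt <- cis_tel_of(b)
    W[b, tt] <- config$ntbs_tel_affinity * B0[b, tt]
    W[tt, b] <- W[b, tt]
  }
  ## reference level: the baseline map's mean one-bin-neighbour contact,
  ## i.e. the strongest ordinary cis contact a locus has
  adj <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  adj <- adj[chrom_id[adj[, 1]] == chrom_id[adj[, 2]], , drop = FALSE]
  ref_level <- mean(B0[adj])
  for (b in unique(planted_bins)) {
    tt <- cis_tel_of(b)
    W[b, tt] <- config$planted_tel_level * ref_level
    W[tt, b] <- W[b, tt]
  }
  list(W = W, bins = bins, tel_bins = tel, chrom_id = chrom_id,
       offset = offset, nb_per = nb_per)
}

#' Generate synthetic Hi-C read pairs
#'
#' Draws `config$n_pairs` read pairs from a ground-truth contact model (see
#' the package vignette): intra-chromosomal distance decay `P(s) ~ s^-alpha`,
#' a uniform inter-chromosomal floor, a Rabl-like telomere cluster, an NTBS
#' mutual-affinity compartment, and a planted `ceiling(f * n)` subset of
#' sites with telomere-level contact (the planted telomere-proximal class).
#' Read positions are uniform within the sampled bins with strands uniform,
#' so that nearly all pairs fall on distinct restriction fragments and
#' survive [classify_pairs()] as valid products.
#'
#' @param assembly See [chrom_lengths()].
#' @param ntbs `GRanges` of (planted) binding sites.
#' @param config A [synthetic_config()].
#' @return A list: `pairs` (BEDPE-like data.frame), `planted` (logical per
#'   site: telomere-proximal truth), `truth` (the ground-truth
#'   `contact_matrix`, state `"truth"`), `ntbs_bins` (global bin per site).
#' @export
make_hic_pairs <- function(assembly, ntbs, config) {
  lens <- chrom_lengths(assembly)
  bin_size <- config$bin_size
  n_pairs <- as.integer(config$n_pairs)

  mid0 <- (GenomicRanges::start(ntbs) - 1 + GenomicRanges::end(ntbs)) %/% 2
  nb_per <- stats::setNames(as.integer(ceiling(lens / bin_size)), names(lens))
  offset <- stats::setNames(c(0L, cumsum(nb_per))[seq_along(lens)], names(lens))
  ch <- as.character(GenomeInfoDb::seqnames(ntbs))
  ntbs_bins <- unname(offset[ch]) + pmin(mid0 %/% bin_size, nb_per[ch] - 1L) + 1L

  n_planted <- ceiling(config$planted_tel_fraction * length(ntbs))
  with_seed_if(derive_seed(config$seed, 3L), {
    planted_idx <- if (n_planted > 0) sort(sample(seq_along(ntbs), n_planted))
                   else integer(0)
    truth <- build_truth_map(lens, ntbs_bins, ntbs_bins[planted_idx], config)
    W <- truth$W
    n <- nrow(W)

    ut <- which(upper.tri(W, diag = TRUE), arr.ind = TRUE)
    pw <- W[ut]
    pick <- sample.int(nrow(ut), n_pairs, replace = TRUE, prob = pw)
    bi <- ut[pick, 1L]; bj <- ut[pick, 2L]
    ## random side swap so (i, j) ordering carries no information
    swap <- stats::runif(n_pairs) < 0.5
    tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp

    bins <- truth$bins
    rl <- config$read_len_bp
    draw_pos <- function(b) {
      wdt <- bins$end[b] - bins$start[b]
      p <- bins$start[b] + floor(stats::runif(length(b)) * wdt)
      L <- lens[bins$chrom[b]]
      pmin(pmax(p, rl), L - rl - 1)   # keep both strand spans in bounds
    }
    pairs <- data.frame(
      chrom1 = bins$chrom[bi], pos1 = as.integer(draw_pos(bi)),
      strand1 = sample(c("+", "-"), n_pairs, replace = TRUE),
      chrom2 = bins$chrom[bj], pos2 = as.integer(draw_pos(bj)),
      strand2 = sample(c("+", "-"), n_pairs, replace = TRUE),
      stringsAsFactors = FALSE)
  })

  planted <- seq_along(ntbs) %in% planted_idx
  names(planted) <- names(ntbs)
  truth_cm <- new_contact_matrix(W, truth$bins, bin_size, lens,
                                 state = "truth")
  list(pairs = pairs, planted = planted, truth = truth_cm,
       ntbs_bins = ntbs_bins)
}
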