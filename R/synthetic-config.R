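#' Configuration for the synthetic data generator
#'
#' One object holds every parameter of the synthetic study: the toy genome,
#' the planted binding sites, the replicate probe tracks, the Hi-C
#' ground-truth contact model, and the healing-assay counts.  The defaults ARE
#' the study conditions used throughout the package's tests: a 16 x 200 kb
#' genome at 38% GC with 60 planted TG-rich sites at 52% GC, five replicate
#' tracks with 5-sigma peaks detected with probability 0.9 per replicate, and
#' 2e6 Hi-C pairs drawn from a distance-decay contact model with a Rabl-like
#' telomere cluster and a planted telomere-proximal fraction of 0.14.
#'
#' @param seed Integer master seed; all generators derive child seeds from it,
#'   so one config yields byte-identical outputs across runs.
#' @param n_chrom,chrom_length_bp Number of chromosomes and length of each
#'   (scalar or vector of length `n_chrom`).
#' @param base_gc Background per-base GC probability (yeast genome-wide 0.38).
#' @param n_ntbs,ntbs_gc,ntbs_width_bp Number, GC fraction (0.52, TG-biased),
#'   and width of planted binding sites.
#' @param ntbs_min_gap_bp Minimum spacing between planted sites so that peak
#'   calls do not merge neighbouring sites.
#' @param telomere_window_bp Terminal window excluded from site placement and
#'   subtracted from peak calls (see [telomere_windows()]).
#' @param probe_spacing_bp,probe_width_bp Tiling-array probe grid.
#' @param peak_amplitude Planted peak height in units of `noise_sd`.
#' @param noise_sd Standard deviation of background probe log2 ratios.
#' @param replicate_detect_prob Probability that a planted site produces
#'   signal in a given replicate (per-replicate dropout).
#' @param n_reps Number of replicate tracks.
#' @param n_pairs Number of Hi-C read pairs to draw.
#' @param bin_size Contact-map bin size in bp.
#' @param decay_exponent Intra-chromosomal contact decay exponent `alpha` in
#'   `P(s) ~ s^-alpha` (generic polymer decay, default 1).
#' @param trans_floor Inter-chromosomal contact weight relative to the
#'   one-bin intra-chromosomal contact (default 0.01, ~30% trans pairs).
#' @param telomere_boost Multiplier `beta` on telomere-bin x telomere-bin
#'   contacts (Rabl-like telomere clustering, default 3).
#' @param tel_arm_depletion Multiplier < 1 on telomere-bin x internal-bin
#'   contacts: telomeres sequestered at the nuclear periphery contact
#'   chromosome arms less than plain distance decay predicts.
#' @param ntbs_affinity Multiplier on NTBS-bin x NTBS-bin contacts: the
#'   mutual spatial proximity of binding sites that the classifier is meant
#'   to detect as the majority class.
#' @param ntbs_tel_affinity Multiplier on NTBS-bin x cis-telomere-bin
#'   contacts applied to ALL planted sites: binding sites as a set sit closer
#'   to telomeres than random regions (the randomization-test signal),
#'   without flipping the per-site classification.
#' @param planted_tel_level Absolute contact weight (same scale as the
#'   one-bin intra contact, 1.0) assigned between a planted telomere-proximal
#'   site and the two telomere bins of its chromosome.
#' @param planted_tel_fraction Fraction `f` of sites planted as
#'   telomere-proximal (default 0.14, the scaled-down analogue of 137 of 978 sites).
#' @param read_len_bp Aligned read length of synthetic Hi-C reads.
#' @param healing_freq Telomere-addition frequency at a planted site under
#'   damage (10-15% reported; default 0.125).
#' @param n_colonies Colonies plated per healing-assay construct.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chrom = 16L,
                             chrom_length_bp = 200000L,
                             base_gc = 0.38,
                             n_ntbs = 60L,
                             ntbs_gc = 0.52,
                             ntbs_width_bp = 800L,
                             ntbs_min_gap_bp = 2000L,
                             telomere_window_bp = 15000L,
                             probe_spacing_bp = 250L,
                             probe_width_bp = 50L,
                             peak_amplitude = 5,
                             noise_sd = 0.25,
                             replicate_detect_prob = 0.9,
                             n_reps = 5L,
                             n_pairs = 2e6,
                             bin_size = 10000L,
                             decay_exponent = 1.0,
                             trans_floor = 0.01,
                             telomere_boost = 3,
                             tel_arm_depletion = 0.04,
                             ntbs_affinity = 100,
                             ntbs_tel_affinity = 2.5,
                             planted_tel_level = 1.0,
                             planted_tel_fraction = 0.14,
                             read_len_bp = 75L,
                             healing_freq = 0.125,
                             n_colonies = 400L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length_bp = as.integer(chrom_length_bp),
              base_gc = base_gc, n_ntbs = as.integer(n_ntbs),
              ntbs_gc = ntbs_gc, ntbs_width_bp = as.integer(ntbs_width_bp),
              ntbs_min_gap_bp = as.integer(ntbs_min_gap_bp),
              telomere_window_bp = as.integer(telomere_window_bp),
              probe_spacing_bp = as.integer(probe_spacing_bp),
              probe_width_bp = as.integer(probe_width_bp),
              peak_amplitude = peak_amplitude, noise_sd = noise_sd,
              replicate_detect_prob = replicate_detect_prob,
              n_reps = as.integer(n_reps), n_pairs = n_pairs,
              bin_size = as.integer(bin_size),
              decay_exponent = decay_exponent, trans_floor = trans_floor,
              telomere_boost = telomere_boost,
              tel_arm_depletion = tel_arm_depletion,
              ntbs_affinity = ntbs_affinity,
              ntbs_tel_affinity = ntbs_tel_affinity,
              planted_tel_level = planted_tel_level,
              planted_tel_fraction = planted_tel_fraction,
              read_len_bp = as.integer(read_len_bp),
              healing_freq = healing_freq,
              n_colonies = as.integer(n_colonies))
  frac <- c("base_gc", "ntbs_gc", "replicate_detect_prob",
            "planted_tel_fraction", "healing_freq", "tel_arm_depletion")
  for (f in frac)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (cfg$telomere_boost < 1) stop("telomere_boost must be >= 1")
  if (any(cfg$chrom_length_bp <= 0)) stop("chromosome lengths must be > 0")
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1")
  if (cfg$probe_spacing_bp >= cfg$ntbs_width_bp)
    stop("probe_spacing_bp must be smaller than ntbs_width_bp")
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: seed", x$seed, "|", x$n_chrom, "chromosomes x",
      paste(unique(x$chrom_length_bp), collapse = "/"), "bp |",
      x$n_ntbs, "planted sites |", format(x$n_pairs, big.mark = ","),
      "Hi-C pairs | planted telomere-proximal fraction",
      x$planted_tel_fraction, "\n")
  invisible(x)
}

# Lengths vector with chromosome names for a config.
config_chrom_lengths <- function(config) {
  lens <- rep_len(config$chrom_length_bp, config$n_chrom)
  stats::setNames(as.integer(lens), sprintf("chr%02d", seq_len(config$n_chrom)))
}
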