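#' Map sites to contact-matrix bins
#'
#' Each site is assigned to the bin containing its midpoint (a midpoint
#' exactly on a bin boundary belongs to the downstream bin); sites whose bin
#' is masked are flagged excluded.
#'
#' @param sites `GRanges` of sites.
#' @param cm A `contact_matrix`.
#' @return data.frame: `name`, `chrom`, `bin` (global 1-based), `excluded`.
#' @export
sites_to_bins <- function(sites, cm) {
  ch <- as.character(GenomeInfoDb::seqnames(sites))
  mid0 <- (GenomicRanges::start(sites) - 1 + GenomicRanges::end(sites)) %/% 2
  b <- bin_of(cm, ch, mid0)
  data.frame(name = names(sites) %||% sprintf("site_%03d", seq_along(sites)),
             chrom = ch, bin = b, excluded = cm$mask[b],
             stringsAsFactors = FALSE)
}

# tel_score per bin: max balanced contact with the telomere bins of the
# bin's own chromosome (or all telomeres); NA when nothing is scorable.
tel_scores_of_bins <- function(cm, bins, k_tel = 1L, all_telomeres = FALSE) {
  tb <- telomere_bins(cm, k = k_tel)
  chrom_of_bin <- cm$bins$chrom
  vapply(bins, function(b) {
    tt <- if (all_telomeres) unlist(tb) else tb[[chrom_of_bin[b]]]
    v <- contact_probability(cm, rep(b, length(tt)), tt)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
}

#' Classify sites as telomere-proximal or mutually proximal
#'
#' For each site the telomere score is the maximum balanced contact
#' probability with the telomere bins of its own chromosome ("one of the two
#' telomeres", max contact), and the site score is the mean contact with the
#' bins of all the other sites (self-bin excluded, missing entries dropped;
#' sites sharing a bin are collapsed to one bin for scoring).  A site is
#' telomere-proximal iff its telomere score is strictly higher than its site
#' score; ties classify as site-proximal.
#'
#' @param cm A balanced `contact_matrix`.
#' @param sites `GRanges` of >= 2 sites.
#' @param k_tel Number of terminal bins per chromosome end treated as
#'   telomeric (default 1).
#' @param all_telomeres Score against the telomere bins of every chromosome
#'   rather than the site's own.
#' @return An object of class `proximity_result`: `sites` data.frame
#'   (`name`, `chrom`, `bin`, `tel_score`, `ntbs_score`, `class`,
#'   `excluded`) and `summary` (counts and fractions over non-excluded
#'   sites).
#' @export
classify_sites <- function(cm, sites, k_tel = 1L, all_telomeres = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"), length(sites) >= 2L)
  if (cm$state != "balanced") stop("classify_sites needs a balanced matrix")
  sb <- sites_to_bins(sites, cm)
  ub <- unique(sb$bin[!sb$excluded])
  tel <- tel_scores_of_bins(cm, sb$bin, k_tel, all_telomeres)
  ntbs <- vapply(seq_len(nrow(sb)), function(i) {
    others <- setdiff(ub, sb$bin[i])
    if (length(others) == 0L) return(NA_real_)
    v <- contact_probability(cm, rep(sb$bin[i], length(others)), others)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  excluded <- sb$excluded | (is.na(tel) & is.na(ntbs))
  cls <- ifelse(excluded, NA_character_,
                ifelse(!is.na(tel) & !is.na(ntbs) & tel > ntbs,
                       "telomere_proximal", "ntbs_proximal"))
  df <- data.frame(sb[c("name", "chrom", "bin")], tel_score = tel,
                   ntbs_score = ntbs, class = cls, excluded = excluded,
                   stringsAsFactors = FALSE)
  n_ok <- sum(!excluded)
  n_tel <- sum(cls == "telomere_proximal", na.rm = TRUE)
  res <- list(sites = df,
              summary = list(n = nrow(df), n_scored = n_ok,
                             n_excluded = sum(excluded),
                             n_telomere_proximal = n_tel,
                             n_ntbs_proximal = n_ok - n_tel,
                             frac_telomere_proximal = n_tel / n_ok,
                             frac_ntbs_proximal = (n_ok - n_tel) / n_ok))
  class(res) <- "proximity_result"
  res
}

#' @export
print.proximity_result <- function(x, ...) {
  s <- x$summary
  cat("proximity_result:", s$n_scored, "sites scored (",
      s$n_excluded, "excluded )\n")
  cat(sprintf("  telomere-proximal: %d (%.1f%%)   site-proximal: %d (%.1f%%)\n",
              s$n_telomere_proximal, 100 * s$frac_telomere_proximal,
              s$n_ntbs_proximal, 100 * s$frac_ntbs_proximal))
  invisible(x)
}

#' Randomization test of site-telomere proximity
#'
#' Compares the per-site telomere scores of the site set against the pooled
#' telomere scores of `n_iter` within-chromosome shuffles of the set, with a
#' one-sided two-sample Wilcoxon rank-sum test (sites closer to telomeres
#' than randomized control regions).
#'
#' @param cm A balanced `contact_matrix`.
#' @param sites `GRanges` of sites.
#' @param assembly See [chrom_lengths()].
#' @param n_iter Number of control shuffles pooled (default 1000).
#' @param seed Optional seed.
#' @param exclude Optional `GRanges` control placements must avoid (pass the
#'   telomere windows to match the placement constraints of the site set).
#' @param k_tel,all_telomeres See [classify_sites()].
#' @return A list: `W`, `p_value`, `median_sites`, `median_controls`,
#'   `n_sites`, `n_controls`.
#' @export
proximity_randomization_test <- function(cm, sites, assembly,
                                         n_iter = 1000L, seed = NULL,
                                         exclude = NULL, k_tel = 1L,
                                         all_telomeres = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"), n_iter >= 1L)
  sb <- sites_to_bins(sites, cm)
  x <- tel_scores_of_bins(cm, sb$bin, k_tel, all_telomeres)
  x <- x[!is.na(x)]
  y <- with_seed_if(seed, {
    unlist(lapply(seq_len(n_iter), function(k) {
      sh <- shuffle_intervals(sites, assembly, exclude = exclude)
      tel_scores_of_bins(cm, sites_to_bins(sh, cm)$bin, k_tel, all_telomeres)
    }))
  })
  y <- y[!is.na(y)]
  if (length(unique(c(x, y))) <= 1L) {
    warning("degenerate (all-tied) proximity scores; p = 1")
    return(list(W = NA_real_, p_value = 1, median_sites = stats::median(x),
                median_controls = stats::median(y), n_sites = length(x),
                n_controls = length(y)))
  }
  wt <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
  list(W = unname(wt$statistic), p_value = wt$p.value,
       median_sites = stats::median(x), median_controls = stats::median(y),
       n_sites = length(x), n_controls = length(y))
}
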