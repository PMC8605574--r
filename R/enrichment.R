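#' qPCR IP over Input ratio
#'
#' `efficiency^(Ct_input - Ct_ip)`: one cycle less to threshold in the IP
#' channel means `efficiency`-fold more template.
#'
#' @param ct_ip,ct_input Threshold cycles (vectors recycle).
#' @param efficiency Per-cycle amplification factor in (1, 2]; 2 is perfect
#'   doubling.
#' @return Numeric ratio(s) > 0.
#' @export
ip_over_input <- function(ct_ip, ct_input, efficiency = 2.0) {
  stopifnot(efficiency > 1, efficiency <= 2)
  if (!all(is.finite(ct_ip)) || !all(is.finite(ct_input)))
    stop("non-finite Ct value")
  if (any(ct_ip <= 0) || any(ct_input <= 0)) stop("Ct values must be > 0")
  efficiency^(ct_input - ct_ip)
}

#' Fold enrichment of a locus relative to a control locus
#'
#' Per replicate, fold = IP/Input at the target divided by IP/Input at the
#' control ("IP/Input method normalized to ARO1").  Reports mean, SEM
#' (sd/sqrt(n), n-1 sample sd) and a two-tailed two-sample Student's t
#' against the control's per-replicate folds (identically 1).
#'
#' @param measurements data.frame with columns `locus`, `channel` (`"IP"` or
#'   `"Input"`), `replicate`, `ct`.
#' @param target_locus,control_locus Locus labels.
#' @param efficiency Per-cycle amplification factor (see [ip_over_input()]).
#' @param welch Use the Welch (unequal-variance) t variant.
#' @return A one-row data.frame: `locus`, `fold_mean`, `sem`, `n`, `p_value`,
#'   plus the per-replicate folds as attribute `"folds"`.
#' @export
fold_vs_control <- function(measurements, target_locus,
                            control_locus = "ARO1", efficiency = 2.0,
                            welch = FALSE) {
  need <- c("locus", "channel", "replicate", "ct")
  stopifnot(all(need %in% names(measurements)))
  one <- function(locus, channel, rep) {
    x <- measurements$ct[measurements$locus == locus &
                         measurements$channel == channel &
                         measurements$replicate == rep]
    if (length(x) != 1L)
      stop("locus ", locus, " replicate ", rep,
           ": expected exactly one ", channel, " Ct, found ", length(x))
    x
  }
  reps <- sort(unique(measurements$replicate[measurements$locus == target_locus]))
  n <- length(reps)
  if (n < 2L) stop("need >= 2 replicates for SEM")
  folds <- vapply(reps, function(r) {
    ip_over_input(one(target_locus, "IP", r), one(target_locus, "Input", r),
                  efficiency) /
      ip_over_input(one(control_locus, "IP", r), one(control_locus, "Input", r),
                    efficiency)
  }, numeric(1))
  s <- stats::sd(folds)
  p <- if (s == 0) {
    if (all(folds == 1)) 1 else 0   # degenerate: constant folds
  } else {
    stats::t.test(folds, rep(1, n), var.equal = !welch)$p.value
  }
  out <- data.frame(locus = target_locus, fold_mean = mean(folds),
                    sem = s / sqrt(n), n = n, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "folds") <- folds
  out
}

#' Telomere-healing frequency per construct
#'
#' The frequency of de novo telomere addition is the percentage of colonies
#' resistant to alpha-aminoadipate after break induction (loss of the distal
#' LYS2 marker).
#'
#' @param table data.frame with columns `construct`, `total`, `resistant`
#'   (extra columns such as `condition` are carried through).
#' @return The input with an added `frequency` column in percent (exact
#'   rational `100 * resistant / total`).
#' @export
healing_frequency <- function(table) {
  stopifnot(all(c("construct", "total", "resistant") %in% names(table)))
  if (any(table$total <= 0)) stop("colony totals must be > 0")
  if (any(table$resistant < 0 | table$resistant > table$total))
    stop("resistant counts must be within [0, total]")
  table$frequency <- 100 * table$resistant / table$total
  table
}
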