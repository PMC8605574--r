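#' In-silico restriction digestion
#'
#' Cuts every chromosome at the first base of each motif occurrence (DpnII
#' cuts `^GATC`); fragments are the spans between consecutive cuts plus the
#' chromosome ends.  A motif-free chromosome yields one fragment.
#'
#' @param assembly Named `DNAStringSet`.
#' @param motif Recognition/cut motif (default `"GATC"`).
#' @return An object of class `restriction_map`: per-chromosome 0-based
#'   fragment boundaries and global fragment-id offsets.
#' @export
digest_genome <- function(assembly, motif = "GATC") {
  stopifnot(methods::is(assembly, "DNAStringSet"))
  lens <- chrom_lengths(assembly)
  frag_start <- list(); n_frag <- integer(length(lens))
  for (i in seq_along(lens)) {
    ch <- names(lens)[i]
    m <- Biostrings::matchPattern(motif, assembly[[ch]])
    cuts0 <- BiocGenerics::start(m) - 1L
    b <- sort(unique(c(0L, cuts0[cuts0 > 0L & cuts0 < lens[[i]]])))
    frag_start[[ch]] <- b
    n_frag[i] <- length(b)
  }
  structure(list(chrom_lengths = lens, frag_start = frag_start,
                 offset = stats::setNames(c(0L, cumsum(n_frag))[seq_along(lens)],
                                          names(lens)),
                 n_fragments = sum(n_frag), motif = motif),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("restriction_map:", x$n_fragments, "fragments (motif", x$motif, ") on",
      length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

#' Assign positions to restriction fragments
#'
#' Returns the global id of the unique fragment whose half-open span contains
#' each position; a position sitting exactly on a cut belongs to the
#' downstream fragment.
#'
#' @param map A [digest_genome()] result.
#' @param chrom,pos Chromosome names and 0-based positions (vectors recycle
#'   to common length).
#' @return Integer vector of global fragment ids (1-based).
#' @export
assign_fragment <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% names(map$frag_start)) stop("unknown chromosome ", ch)
    p <- pos[i]
    if (any(p < 0 | p >= map$chrom_lengths[[ch]]))
      stop("position out of bounds on ", ch)
    out[i] <- map$offset[[ch]] + findInterval(p, map$frag_start[[ch]])
  }
  out
}

#' Classify Hi-C read pairs
#'
#' Pairs whose two reads map to different restriction fragments are valid
#' Hi-C products.  Same-fragment pairs are artifacts: convergent (inward
#' facing) strands mark an unligated fragment (`non_ligation`); divergent or
#' equal strands mark a self-circularized fragment (`self_ligation`).
#'
#' @param pairs data.frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (positions 0-based).
#' @param map A [digest_genome()] result.
#' @return A list: `pairs` (input plus `frag1`, `frag2`, `class`) and
#'   `census` (named counts of the three classes).
#' @export
classify_pairs <- function(pairs, map) {
  frag1 <- assign_fragment(map, pairs$chrom1, pairs$pos1)
  frag2 <- assign_fragment(map, pairs$chrom2, pairs$pos2)
  cls <- rep("valid", nrow(pairs))
  same <- frag1 == frag2
  if (any(same)) {
    first_left <- pairs$pos1[same] <= pairs$pos2[same]
    s_left  <- ifelse(first_left, pairs$strand1[same], pairs$strand2[same])
    s_right <- ifelse(first_left, pairs$strand2[same], pairs$strand1[same])
    cls[same] <- ifelse(s_left == "+" & s_right == "-",
                        "non_ligation", "self_ligation")
  }
  pairs$frag1 <- frag1; pairs$frag2 <- frag2; pairs$class <- cls
  census <- c(valid = sum(cls == "valid"),
              self_ligation = sum(cls == "self_ligation"),
              non_ligation = sum(cls == "non_ligation"))
  list(pairs = pairs, census = census)
}

## ---- contact matrix container ---------------------------------------------

# Global bin table for an assembly at bin_size.
make_bins <- function(lens, bin_size) {
  nb <- as.integer(ceiling(lens / bin_size))
  chrom <- rep(names(lens), nb)
  local <- unlist(lapply(nb, seq_len)) - 1L
  start <- local * bin_size
  end <- pmin(start + bin_size, rep(unname(lens), nb))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

new_contact_matrix <- function(m, bins, bin_size, lens, state,
                               n_pairs = NA_real_, mask = NULL,
                               balance = NULL) {
  structure(list(matrix = m, bins = bins, bin_size = as.integer(bin_size),
                 chrom_lengths = lens, state = state, n_pairs = n_pairs,
                 mask = mask %||% rep(FALSE, nrow(bins)),
                 balance = balance),
            class = "contact_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a contact matrix from a dense symmetric matrix
#'
#' Mostly useful for tests and for importing matrices produced elsewhere;
#' pipelines normally obtain one from [bin_pairs()].
#'
#' @param m Symmetric non-negative numeric matrix, one row/column per bin.
#' @param assembly See [chrom_lengths()]; bins tile the chromosomes in order.
#' @param bin_size Bin width in bp.
#' @param state `"raw"` or `"balanced"`.
#' @param mask Optional logical vector of masked bins.
#' @return A `contact_matrix`.
#' @export
contact_matrix <- function(m, assembly, bin_size, state = "raw",
                           mask = NULL) {
  lens <- chrom_lengths(assembly)
  bins <- make_bins(lens, bin_size)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) == nrow(bins))
  if (any(m < 0)) stop("contact matrix must be non-negative")
  if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1))
    stop("contact matrix must be symmetric")
  new_contact_matrix(m, bins, bin_size, lens, state = state, mask = mask)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins of", x$bin_size, "bp on",
      length(x$chrom_lengths), "chromosomes | state:", x$state, "\n")
  if (!is.na(x$n_pairs)) cat("  pairs binned:", format(x$n_pairs, big.mark = ","), "\n")
  if (sum(x$mask)) cat("  masked bins:", sum(x$mask), "\n")
  if (!is.null(x$balance))
    cat("  balancing:", x$balance$iterations, "iterations, residual",
        format(x$balance$residual, digits = 3),
        if (!x$balance$converged) "(NOT converged)" else "", "\n")
  invisible(x)
}

#' Total mass of a contact matrix
#'
#' Sum over the upper triangle including the diagonal: each pair is counted
#' once even though the stored matrix is fully symmetric.
#'
#' @param cm A `contact_matrix`.
#' @return Numeric total.
#' @export
matrix_mass <- function(cm) {
  m <- cm$matrix
  sum(m[upper.tri(m, diag = TRUE)])
}

#' Bin valid Hi-C pairs into a raw contact matrix
#'
#' The genome is divided into bins of `bin_size` bp.  Each read end is an
#' aligned span of `read_len` bp starting at its 5' position on its strand;
#' each pair contributes a total count of one, split between bins in
#' proportion to the base overlap of its two read spans ("proportional to
#' their overlap").  The result is symmetric; off-diagonal entries are
#' mirrored and the diagonal is not doubled, so [matrix_mass()] equals the
#' number of pairs.
#'
#' @param pairs data.frame of valid pairs (`chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`; positions 0-based 5' ends).
#' @param assembly See [chrom_lengths()].
#' @param bin_size Bin width in bp (default 10000).
#' @param read_len Aligned read length in bp (default 75).
#' @return A `contact_matrix` in state `"raw"`.
#' @export
bin_pairs <- function(pairs, assembly, bin_size = 10000L, read_len = 75L) {
  stopifnot(bin_size > 0, read_len > 0, read_len <= bin_size)
  lens <- chrom_lengths(assembly)
  bins <- make_bins(lens, bin_size)
  nb_per <- stats::setNames(as.integer(ceiling(lens / bin_size)), names(lens))
  offset <- stats::setNames(c(0L, cumsum(nb_per))[seq_along(lens)], names(lens))
  n_bins <- nrow(bins)

  end_weights <- function(chrom, pos, strand) {
    L <- unname(lens[chrom])
    a <- ifelse(strand == "+", pos, pos - read_len + 1)
    a <- pmax(0, pmin(a, L - read_len))
    b <- a + read_len
    b1 <- a %/% bin_size
    b2 <- (b - 1) %/% bin_size
    maxb <- unname(nb_per[chrom]) - 1L
    b1 <- pmin(b1, maxb); b2 <- pmin(b2, maxb)
    w1 <- ifelse(b2 > b1, ((b1 + 1) * bin_size - a) / read_len, 1)
    g1 <- unname(offset[chrom]) + b1 + 1L
    g2 <- ifelse(b2 > b1, unname(offset[chrom]) + b2 + 1L, NA_integer_)
    list(g1 = g1, w1 = w1, g2 = g2, w2 = 1 - w1)
  }

  e1 <- end_weights(pairs$chrom1, pairs$pos1, pairs$strand1)
  e2 <- end_weights(pairs$chrom2, pairs$pos2, pairs$strand2)

  ii <- c(e1$g1, e1$g1, e1$g2, e1$g2)
  jj <- c(e2$g1, e2$g2, e2$g1, e2$g2)
  xx <- c(e1$w1 * e2$w1, e1$w1 * e2$w2, e1$w2 * e2$w1, e1$w2 * e2$w2)
  keep <- !is.na(ii) & !is.na(jj) & xx > 0
  A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(n_bins, n_bins))
  A <- as.matrix(A)
  M <- A + t(A)
  diag(M) <- diag(A)
  new_contact_matrix(M, bins, bin_size, lens, state = "raw",
                     n_pairs = nrow(pairs))
}

#' Sinkhorn-Knopp balancing of a contact matrix
#'
#' Normalizes a raw symmetric contact map so that every row and column over
#' the support sums to 1, removing coverage biases (restriction-site density,
#' GC content, mappability).  Uses the symmetric variant (a single scaling
#' vector, updated by the inverse square root of the current row sums), which
#' preserves symmetry at machine precision.  Bins with zero raw marginal are
#' masked out of the support and left zero.
#'
#' @param cm A `contact_matrix` in state `"raw"`.
#' @param tol Convergence tolerance on `max |row_sum - 1|` (default 1e-8).
#' @param max_iter Iteration cap (default 1000); non-convergence is reported
#'   with a warning and flagged on the result.
#' @return A `contact_matrix` in state `"balanced"` with `mask`, and
#'   `balance` recording iterations, residual and convergence.
#' @export
balance_matrix <- function(cm, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state == "balanced") return(cm)
  m <- cm$matrix
  if (any(m < 0)) stop("contact matrix must be non-negative")
  support <- Matrix::rowSums(m) > 0
  S <- m[support, support, drop = FALSE]
  iter <- 0L; resid <- Inf
  while (iter < max_iter) {
    rs <- rowSums(S)
    resid <- max(abs(rs - 1))
    if (resid < tol) break
    d <- 1 / sqrt(rs)
    S <- S * d               # rows   (column-major recycling over rows)
    S <- t(t(S) * d)         # columns
    iter <- iter + 1L
  }
  converged <- resid < tol
  if (!converged)
    warning("balancing did not converge in ", max_iter,
            " iterations (residual ", format(resid, digits = 3), ")")
  out <- matrix(0, nrow(m), ncol(m))
  out[support, support] <- S
  new_contact_matrix(out, cm$bins, cm$bin_size, cm$chrom_lengths,
                     state = "balanced", n_pairs = cm$n_pairs,
                     mask = !support,
                     balance = list(iterations = iter, residual = resid,
                                    converged = converged))
}

#' Contact probability between two bins
#'
#' Symmetric accessor on a balanced matrix; querying a masked bin returns
#' `NA` (a distinguished missing value, not zero).
#'
#' @param cm A balanced `contact_matrix`.
#' @param bin_i,bin_j Global bin indices (1-based, rows of `cm$bins`).
#' @return Numeric score or `NA_real_`.
#' @export
contact_probability <- function(cm, bin_i, bin_j) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state != "balanced") stop("matrix is not balanced")
  ifelse(cm$mask[bin_i] | cm$mask[bin_j], NA_real_,
         cm$matrix[cbind(bin_i, bin_j)])
}

#' Global bin index of genomic positions
#'
#' @param cm A `contact_matrix`.
#' @param chrom,pos Chromosome and 0-based position vectors.
#' @return Integer global bin ids (1-based).
#' @export
bin_of <- function(cm, chrom, pos) {
  lens <- cm$chrom_lengths
  nb_per <- stats::setNames(as.integer(ceiling(lens / cm$bin_size)), names(lens))
  offset <- stats::setNames(c(0L, cumsum(nb_per))[seq_along(lens)], names(lens))
  if (any(pos < 0 | pos >= lens[chrom])) stop("position out of bounds")
  unname(offset[chrom]) + pmin(pos %/% cm$bin_size, nb_per[chrom] - 1L) + 1L
}

# Global ids of the k terminal bins at each end of every chromosome.
telomere_bins <- function(cm, k = 1L) {
  lens <- cm$chrom_lengths
  nb_per <- as.integer(ceiling(lens / cm$bin_size))
  offset <- c(0L, cumsum(nb_per))[seq_along(lens)]
  out <- lapply(seq_along(lens), function(i) {
    left <- offset[i] + seq_len(min(k, nb_per[i]))
    right <- offset[i] + nb_per[i] - seq_len(min(k, nb_per[i])) + 1L
    sort(unique(c(left, right)))
  })
  names(out) <- names(lens)
  out
}

#' Write / read a contact matrix as text
#'
#' Coordinate-list text format with a `#`-comment header recording bin size,
#' chromosome lengths, state and mask; entries are upper-triangle `i j value`
#' triplets.
#'
#' @param cm A `contact_matrix`.
#' @param path File path.
#' @return For the reader, a `contact_matrix`.
#' @export
write_contact_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ntbsmap contact matrix v1"),
    paste0("# bin_size\t", cm$bin_size),
    paste0("# state\t", cm$state),
    paste0("# n_pairs\t", format(cm$n_pairs, digits = 17)),
    paste0("# chrom\t", paste(names(cm$chrom_lengths), collapse = ",")),
    paste0("# length\t", paste(cm$chrom_lengths, collapse = ",")),
    paste0("# masked\t", paste(which(cm$mask), collapse = ","))), con)
  m <- cm$matrix
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   value = format(m[idx], digits = 17, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  hdr <- readLines(path, n = 7L)
  get <- function(key) sub(paste0("^# ", key, "\t"), "", grep(paste0("^# ", key, "\t"), hdr, value = TRUE))
  bin_size <- as.integer(get("bin_size"))
  state <- get("state")
  n_pairs <- as.numeric(get("n_pairs"))
  chroms <- strsplit(get("chrom"), ",")[[1]]
  lens <- stats::setNames(as.integer(strsplit(get("length"), ",")[[1]]), chroms)
  masked_txt <- get("masked")
  masked <- if (nzchar(masked_txt)) as.integer(strsplit(masked_txt, ",")[[1]]) else integer(0)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("i", "j", "value"))
  bins <- make_bins(lens, bin_size)
  m <- matrix(0, nrow(bins), nrow(bins))
  m[cbind(df$i, df$j)] <- df$value
  m[cbind(df$j, df$i)] <- df$value
  mask <- rep(FALSE, nrow(bins)); mask[masked] <- TRUE
  new_contact_matrix(m, bins, bin_size, lens, state = state,
                     n_pairs = n_pairs, mask = mask)
}

#' Read / write Hi-C pair tables
#'
#' Tab-delimited BEDPE-like layout: `chrom1`, `pos1`, `strand1`, `chrom2`,
#' `pos2`, `strand2` (positions 0-based 5' ends).
#'
#' @param pairs data.frame of pairs.
#' @param path File path.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  utils::write.table(pairs[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character",
                                   "character", "integer", "character"))
}
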