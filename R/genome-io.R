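#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet],
#' one record per chromosome, preserving record order.  Sequence names are
#' truncated at the first whitespace; bases are stored uppercase.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; chromosome lengths are `width()` of the
#'   result (see [chrom_lengths()]).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in ", path)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record(s) in ", path)
  seqs
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly, path)
  invisible(path)
}

#' Chromosome lengths of an assembly
#'
#' @param assembly A named `DNAStringSet` carrying sequence, or an already
#'   named numeric vector of chromosome lengths (a chrom-sizes table).
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(assembly) {
  if (methods::is(assembly, "DNAStringSet")) {
    return(stats::setNames(Biostrings::width(assembly), names(assembly)))
  }
  if (is.numeric(assembly) && !is.null(names(assembly))) {
    if (any(assembly <= 0)) stop("chromosome lengths must be > 0")
    return(stats::setNames(as.integer(assembly), names(assembly)))
  }
  stop("`assembly` must be a named DNAStringSet or a named length vector")
}

#' Read / write a chrom-sizes table (name TAB length)
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names in ", path)
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param lengths Named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(lengths, path) {
  utils::write.table(data.frame(names(lengths), unname(lengths)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate a GRanges against an assembly; `what` names the source for errors.
validate_intervals <- function(gr, assembly, what = "interval") {
  lens <- chrom_lengths(assembly)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- !(chr %in% names(lens))
  if (any(unknown))
    stop(what, " ", which(unknown)[1L], ": unknown chromosome '",
         chr[which(unknown)[1L]], "'")
  too_long <- GenomicRanges::end(gr) > lens[chr]
  if (any(too_long))
    stop(what, " ", which(too_long)[1L], ": end ",
         GenomicRanges::end(gr)[which(too_long)[1L]],
         " exceeds length of ", chr[which(too_long)[1L]])
  if (any(GenomicRanges::width(gr) < 1L))
    stop(what, " ", which(GenomicRanges::width(gr) < 1L)[1L], ": empty range")
  invisible(gr)
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open on disk; the returned `GRanges` uses the usual
#' 1-based closed convention.  When `assembly` is supplied every record is
#' validated against it and offending records are reported by line number.
#'
#' @param path Path to a BED3/BED6 file.
#' @param assembly Optional assembly (see [chrom_lengths()]) for validation.
#' @return A `GRanges`, with `name`/`score` metadata columns when present.
#' @export
read_bed <- function(path, assembly = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(assembly)) {
    validate_intervals(gr, assembly, what = paste0(basename(path), " line"))
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths(assembly))
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_lengths(assembly))
  }
  gr
}

#' Write a GRanges to BED
#'
#' Writes BED3 (or BED6 when `name`/`score` metadata are present or
#' `bed6 = TRUE`), converting back to 0-based half-open coordinates.  Score
#' values are written in full precision so `write_bed()` then [read_bed()]
#' round-trips exactly.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param bed6 Force BED6 output.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, bed6 = NULL) {
  mc <- S4Vectors::mcols(gr)
  has6 <- !is.null(bed6) && bed6 || any(c("name", "score") %in% names(mc)) ||
    !is.null(names(gr))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end   = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (isTRUE(has6)) {
    nm <- if (!is.null(mc$name)) mc$name else names(gr)
    if (is.null(nm)) nm <- rep(".", length(gr))
    sc <- if (!is.null(mc$score)) format(mc$score, digits = 17, trim = TRUE,
                                         scientific = FALSE)
          else rep("0", length(gr))
    df$name <- nm
    df$score <- sc
    df$strand <- sub("\\*", ".", as.character(GenomicRanges::strand(gr)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Telomere windows of an assembly
#'
#' Returns the two terminal windows of every chromosome: `[0, window_bp)` and
#' `[L - window_bp, L)` in BED coordinates, clamped to the chromosome and
#' merged when they meet.  The window width is the operational definition of
#' "telomeric sequence" used when internal (non-telomeric) sites are reported;
#' the 15 kb default covers telomeric repeats plus subtelomeric X/Y' elements.
#'
#' @param assembly See [chrom_lengths()].
#' @param window_bp Window width in bp per chromosome end (default 15000).
#' @return A `GRanges` of at most two windows per chromosome.
#' @export
telomere_windows <- function(assembly, window_bp = 15000) {
  stopifnot(window_bp >= 0)
  lens <- chrom_lengths(assembly)
  if (window_bp == 0)
    return(GenomicRanges::GRanges(seqlengths = lens))
  w <- pmin(as.integer(window_bp), lens)
  left  <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1L, w),
                                  seqlengths = lens)
  right <- GenomicRanges::GRanges(names(lens),
                                  IRanges::IRanges(pmax(1L, lens - as.integer(window_bp) + 1L), lens),
                                  seqlengths = lens)
  GenomicRanges::reduce(sort(c(left, right)))
}

#' GC content of an interval set
#'
#' Computes (G + C) / (A + C + G + T) over the union of the interval bases
#' (overlapping intervals are not double-counted); `N` bases are excluded from
#' the denominator.
#'
#' @param x A `GRanges`, or `NULL`/missing to use the whole assembly.
#' @param assembly A named `DNAStringSet` carrying sequence.
#' @return A fraction in `[0, 1]`.
#' @export
gc_content <- function(x = NULL, assembly) {
  stopifnot(methods::is(assembly, "DNAStringSet"))
  if (is.null(x)) {
    x <- GenomicRanges::GRanges(names(assembly),
                                IRanges::IRanges(1L, Biostrings::width(assembly)))
  }
  if (length(x) == 0L) stop("empty interval set")
  validate_intervals(x, assembly, "interval")
  red <- GenomicRanges::reduce(x)
  gc <- 0; acgt <- 0
  for (ch in unique(as.character(GenomeInfoDb::seqnames(red)))) {
    r <- red[GenomeInfoDb::seqnames(red) == ch]
    v <- Biostrings::Views(assembly[[ch]], start = GenomicRanges::start(r),
                           end = GenomicRanges::end(r))
    f <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    gc <- gc + sum(f[, c("C", "G")])
    acgt <- acgt + sum(f)
  }
  if (acgt == 0) stop("intervals cover only non-ACGT bases")
  gc / acgt
}
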