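#' N50 of a set of contig lengths
#'
#' The smallest contig length L such that contigs of length >= L together
#' account for at least half the total assembly length. Ties at exactly
#' half are inclusive. With at least one contig the result is always one of
#' the input lengths.
#'
#' @param lengths Vector of positive integer contig lengths.
#' @return Integer N50; 0 (with a warning) for empty input.
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) {
    warning("n50 of an empty assembly is 0", call. = FALSE)
    return(0L)
  }
  stopifnot(all(lengths >= 1))
  lengths <- as.numeric(sort(lengths, decreasing = TRUE))
  half <- sum(lengths) / 2
  as.integer(lengths[which(cumsum(lengths) >= half)[1L]])
}

#' Pooled GC fraction of nucleotide sequences
#'
#' (G + C) / (A + C + G + T) pooled over all sequences; ambiguity codes
#' (including N) are excluded from both numerator and denominator.
#'
#' @param seqs Character vector of nucleotide sequences, or a
#'   [read_fasta()] data frame.
#' @return GC fraction in [0,1].
#' @export
gc_fraction <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  set <- Biostrings::DNAStringSet(gsub("U", "T", toupper(seqs), fixed = TRUE))
  freq <- Biostrings::alphabetFrequency(set, baseOnly = TRUE)
  tot <- colSums(freq)
  unambig <- sum(tot[c("A", "C", "G", "T")])
  if (unambig == 0) {
    stop("no unambiguous bases; GC fraction undefined", call. = FALSE)
  }
  sum(tot[c("G", "C")]) / unambig
}

#' Summary statistics for an assembly
#'
#' Contig count, total length, N50 and pooled GC fraction, as reported for
#' transcriptome assemblies before and after decontamination.
#'
#' @param assembly A [read_fasta()] data frame (or a path to a FASTA file).
#' @return An object of class \code{assembly_stats}: list with
#'   \code{n_contigs}, \code{total_len}, \code{n50}, \code{gc_fraction}.
#' @export
summarize_assembly <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1L) {
    assembly <- read_fasta(assembly)
  }
  stopifnot(is.data.frame(assembly))
  if (nrow(assembly) == 0L) {
    return(structure(list(n_contigs = 0L, total_len = 0L, n50 = 0L,
                          gc_fraction = NA_real_),
                     class = "assembly_stats"))
  }
  lens <- nchar(assembly$seq)
  structure(list(n_contigs = nrow(assembly),
                 total_len = sum(lens),
                 n50 = n50(lens),
                 gc_fraction = gc_fraction(assembly$seq)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  gc <- if (is.na(x$gc_fraction)) "NA" else sprintf("%.2f%%",
                                                    100 * x$gc_fraction)
  cat(sprintf("<assembly_stats> %d contigs, %d bp total, N50 = %d, GC = %s\n",
              x$n_contigs, x$total_len, x$n50, gc))
  invisible(x)
}

#' @rdname summarize_assembly
#' @param stats An \code{assembly_stats} object.
#' @param path Output TSV path.
#' @export
write_assembly_stats <- function(stats, path) {
  df <- data.frame(n_contigs = stats$n_contigs, total_len = stats$total_len,
                   n50 = stats$n50,
                   gc_pct = if (is.na(stats$gc_fraction)) NA else
                     sprintf("%.2f", 100 * stats$gc_fraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
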