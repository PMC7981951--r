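#' Locate introns by exact transcript-to-genomic comparison
#'
#' Given a genomic amplicon and its spliced transcript, finds the deletion
#' blocks (introns) whose removal from the genomic sequence reconstructs
#' the transcript byte-exactly. Matching is exact (mismatch tolerance 0):
#' the method targets Sanger-verified amplicon/transcript pairs. Exons are
#' anchored by longest common prefix/suffix and blocks resolved by
#' recursive exact matching; when a junction repeat makes a block's
#' placement ambiguous, the leftmost placement is reported.
#'
#' @param transcript Transcript (spliced) nucleotide string, or a
#'   single-record [read_fasta()] data frame.
#' @param genomic Genomic nucleotide string, or a single-record data frame.
#' @return Data frame of intron calls in genomic order: columns
#'   \code{transcript_pos} (transcript position after which the intron
#'   inserts; 0 means before the first base), \code{genomic_start},
#'   \code{genomic_end} (1-based inclusive), \code{length},
#'   \code{donor_acceptor} (e.g. \code{"GT..AG"}) and \code{canonical}
#'   (block starts GT and ends AG). Empty when the sequences are
#'   identical.
#' @examples
#' locate_introns("ACGTACGT", "ACGTGTAAAGACGT")  # hypothetical 6-bp block
#' @export
locate_introns <- function(transcript, genomic) {
  transcript <- as_single_seq(transcript, "transcript")
  genomic <- as_single_seq(genomic, "genomic")
  t <- toupper(transcript); g <- toupper(genomic)
  if (nchar(t) > nchar(g)) {
    stop("sequences do not align exon-exact: transcript longer than genomic",
         call. = FALSE)
  }
  blocks <- find_deletion_blocks(t, g)
  if (is.null(blocks)) {
    stop("sequences do not align exon-exact (mismatch tolerance 0)",
         call. = FALSE)
  }
  if (length(blocks) == 0L) return(empty_intron_calls())
  # Leftmost normalization: slide each block left across junction repeats.
  starts <- vapply(blocks, `[`, integer(1), 1L)
  ends <- vapply(blocks, `[`, integer(1), 2L)
  gc <- strsplit(g, "", fixed = TRUE)[[1L]]
  for (i in seq_along(starts)) {
    floor_pos <- if (i == 1L) 1L else ends[i - 1L] + 1L
    while (starts[i] > floor_pos && gc[starts[i] - 1L] == gc[ends[i]]) {
      starts[i] <- starts[i] - 1L
      ends[i] <- ends[i] - 1L
    }
  }
  cum_intron <- cumsum(c(0L, ends - starts + 1L))[seq_along(starts)]
  transcript_pos <- starts - 1L - cum_intron
  don_acc <- vapply(seq_along(starts), function(i) {
    paste0(substr(g, starts[i], starts[i] + 1L), "..",
           substr(g, ends[i] - 1L, ends[i]))
  }, character(1))
  calls <- data.frame(
    transcript_pos = transcript_pos,
    genomic_start = starts, genomic_end = ends,
    length = ends - starts + 1L,
    donor_acceptor = don_acc,
    canonical = substr(g, starts, starts + 1L) == "GT" &
      substr(g, ends - 1L, ends) == "AG",
    stringsAsFactors = FALSE)
  # Reconstruction identity is part of the contract; verify before return.
  if (splice_out(g, calls) != t) {
    stop("internal error: spliced genomic does not reconstruct transcript",
         call. = FALSE)
  }
  calls
}

empty_intron_calls <- function() {
  data.frame(transcript_pos = integer(), genomic_start = integer(),
             genomic_end = integer(), length = integer(),
             donor_acceptor = character(), canonical = logical(),
             stringsAsFactors = FALSE)
}

as_single_seq <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop(what, " must be a single sequence", call. = FALSE)
    }
    x <- x$seq
  }
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  x
}

#' Remove intron intervals from a genomic sequence
#'
#' @param genomic Genomic nucleotide string.
#' @param calls Intron-call data frame from [locate_introns()] (uses
#'   \code{genomic_start}/\code{genomic_end}).
#' @return The spliced (exonic) sequence.
#' @export
splice_out <- function(genomic, calls) {
  genomic <- as_single_seq(genomic, "genomic")
  if (nrow(calls) == 0L) return(genomic)
  keep <- rep(TRUE, nchar(genomic))
  for (i in seq_len(nrow(calls))) {
    keep[calls$genomic_start[i]:calls$genomic_end[i]] <- FALSE
  }
  paste(strsplit(genomic, "", fixed = TRUE)[[1L]][keep], collapse = "")
}

lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n)); bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

lcs_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(substr(a, na - n + 1L, na)))
  bv <- rev(utf8ToInt(substr(b, nb - n + 1L, nb)))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Is `t` obtainable from `g` by deleting characters (subsequence test)?
is_subsequence <- function(t, g) {
  if (nchar(t) == 0L) return(TRUE)
  tv <- utf8ToInt(t); gv <- utf8ToInt(g)
  i <- 1L
  for (j in seq_along(gv)) {
    if (gv[j] == tv[i]) {
      i <- i + 1L
      if (i > length(tv)) return(TRUE)
    }
  }
  FALSE
}

# Recursive exact matching: returns a list of c(start, end) deletion blocks
# in genomic coordinates (1-based), or NULL if no exact-deletion alignment
# exists. Anchors the longest common prefix and suffix, then opens the
# shortest feasible block and recurses on what remains.
find_deletion_blocks <- function(t, g, g_off = 0L) {
  if (t == g) return(list())
  p <- lcp_len(t, g)
  nt <- nchar(t); ng <- nchar(g)
  if (nt > ng) return(NULL)
  if (p == nt) {
    # transcript exhausted: the genomic remainder is one terminal block
    return(list(c(g_off + p + 1L, g_off + ng)))
  }
  if (p == ng) return(NULL)  # genomic exhausted first: impossible
  s <- lcs_len(t, g)
  s <- min(s, nt - p, ng - p - 1L)
  it <- substr(t, p + 1L, nt - s)
  ig <- substr(g, p + 1L, ng - s)
  if (nchar(it) == 0L) {
    # both ends anchored: everything between is one block
    return(list(c(g_off + p + 1L, g_off + ng - s)))
  }
  first_t <- substr(it, 1L, 1L)
  max_block <- nchar(ig) - nchar(it)
  if (max_block < 1L) return(NULL)
  # Candidate block ends resume at a position matching the next exon's
  # first base. The true resumption point carries the longest exon match,
  # so rank candidates by match length (ties: leftmost) before recursing;
  # this is what keeps the block set minimal when exon anchors are unique.
  cand <- which(vapply(seq_len(max_block), function(L) {
    substr(ig, L + 1L, L + 1L) == first_t
  }, logical(1)))
  if (!length(cand)) return(NULL)
  match_len <- vapply(cand, function(L) {
    lcp_len(it, substr(ig, L + 1L, nchar(ig)))
  }, integer(1))
  for (L in cand[order(-match_len, cand)]) {
    g_after <- substr(ig, L + 1L, nchar(ig))
    if (!is_subsequence(it, g_after)) next
    rest <- find_deletion_blocks(it, g_after, g_off + p + L)
    if (!is.null(rest)) {
      return(c(list(c(g_off + p + 1L, g_off + p + L)), rest))
    }
  }
  NULL
}
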