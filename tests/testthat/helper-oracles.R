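# Independent brute-force oracles and tiny fixture builders used across
# the suite. Oracles deliberately use a different mechanism than the
# implementation they check.

# Per-base max-identity array: the reference computation for the
# identity-weighted hit-coverage score.
oracle_similarity_score <- function(hsps, contig_len) {
  base_id <- numeric(contig_len)
  for (i in seq_len(nrow(hsps))) {
    span <- hsps$q_start[i]:hsps$q_end[i]
    base_id[span] <- pmax(base_id[span], hsps$pct_identity[i] / 100)
  }
  sum(base_id) / contig_len
}

# N50 by direct definition: the largest contig length L such that contigs
# of length >= L still account for at least half the total.
oracle_n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(as.integer(L))
  }
  stop("unreachable")
}

oracle_gc <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE))
  num <- sum(chars %in% c("G", "C"))
  den <- sum(chars %in% c("A", "C", "G", "T"))
  num / den
}

# CRD matching by regex with overlapping lookahead capture.
oracle_find_crd_starts <- function(protein, gap_ranges, tolerance) {
  widened <- lapply(gap_ranges, function(r) {
    c(max(0L, r[1L] - tolerance), r[2L] + tolerance)
  })
  pat <- paste0("(?=(", paste0("C", vapply(widened, function(r) {
    sprintf("[^C]{%d,%d}", r[1L], r[2L])
  }, character(1)), collapse = ""), "C))")
  m <- gregexpr(pat, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

# Longest Gly-led triplet run by direct scan over every offset.
oracle_count_gxy <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  best <- 0L
  if (n < 3L) return(best)
  for (i in seq_len(n - 2L)) {
    k <- 0L
    j <- i
    while (j + 2L <= n && chars[j] == "G") {
      k <- k + 1L
      j <- j + 3L
    }
    if (k > best) best <- k
  }
  best
}

# Count integer positions strictly between two genes by enumeration.
oracle_igr_count <- function(a, b) {
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (b$start - 1L < a$end + 1L) return(0L)
  length(seq.int(a$end + 1L, b$start - 1L))
}

empty_hsps_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

random_hsps <- function(contig_id, contig_len, n) {
  if (n == 0L) {
    return(empty_hsps_df())
  }
  qs <- sample.int(contig_len, n, replace = TRUE)
  qe <- pmin(contig_len, qs + sample.int(200L, n, replace = TRUE))
  data.frame(query_id = contig_id,
             subject_id = paste0("subj", sample.int(5L, n, replace = TRUE)),
             pct_identity = round(stats::runif(n, 50, 100), 2),
             aln_len = qe - qs + 1L,
             mismatches = 0L, gap_opens = 0L,
             q_start = qs, q_end = qe,
             s_start = 1L, s_end = qe - qs + 1L,
             evalue = 10^-stats::runif(n, 1, 50),
             bitscore = round(stats::runif(n, 40, 500), 1),
             stringsAsFactors = FALSE)
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tmpfile <- function(ext) tempfile(fileext = ext)
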