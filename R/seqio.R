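#' Read a FASTA file
#'
#' Parses a nucleotide or protein FASTA file into a data frame of sequence
#' records. Record ids are the first whitespace-delimited token of the
#' header; the full header (without the leading \code{>}) is kept as the
#' description. Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with character columns \code{id}, \code{description}
#'   and \code{seq}, one row per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a x", "AC", "gt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(empty_fasta())
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA: sequence data before first header at line ",
         nonblank[1L], " of ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty record id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, description = headers, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

empty_fasta <- function() {
  data.frame(id = character(), description = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: the description (or id, when no description is
#' present) becomes the header. Round-tripping preserves ids and sequences
#' exactly.
#'
#' @param records Data frame with columns \code{id}, \code{seq} and
#'   optionally \code{description}.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- if ("description" %in% names(records) &&
                    all(nzchar(records$description))) {
    records$description
  } else {
    records$id
  }
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

blast12_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bitscore")

#' Parse a BLAST tabular (outfmt 6) hit file
#'
#' Reads the default 12-column tabular BLAST dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) into a data frame of HSP records, preserving input
#' order. Query coordinates must be ascending; subject coordinates may be
#' inverted for minus-strand HSPs.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A data frame with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_len}, \code{mismatches},
#'   \code{gap_opens}, \code{q_start}, \code{q_end}, \code{s_start},
#'   \code{s_end}, \code{evalue}, \code{bitscore}.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop("hit file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_hsps())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("BLAST tabular line ", bad, " has ", nf[bad],
         " columns; expected 12 (", path, ")", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric ", what, " at line ", bad, " of ", path,
           ": '", m[bad, j], "'", call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  hsps <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "pct_identity"),
    aln_len = num(4L, "aln_len", integer = TRUE),
    mismatches = num(5L, "mismatches", integer = TRUE),
    gap_opens = num(6L, "gap_opens", integer = TRUE),
    q_start = num(7L, "q_start", integer = TRUE),
    q_end = num(8L, "q_end", integer = TRUE),
    s_start = num(9L, "s_start", integer = TRUE),
    s_end = num(10L, "s_end", integer = TRUE),
    evalue = num(11L, "evalue"),
    bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  validate_hsps(hsps, path)
  hsps
}

empty_hsps <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hsps <- function(hsps, origin = "hit table") {
  bad <- which(hsps$q_start > hsps$q_end)
  if (length(bad)) {
    stop("q_start > q_end at line ", bad[1L], " of ", origin,
         " (query coordinates must be ascending)", call. = FALSE)
  }
  if (any(hsps$q_start < 1L)) {
    stop("q_start < 1 at line ", which(hsps$q_start < 1L)[1L], " of ",
         origin, call. = FALSE)
  }
  if (any(hsps$pct_identity < 0 | hsps$pct_identity > 100)) {
    stop("pct_identity outside [0,100] at line ",
         which(hsps$pct_identity < 0 | hsps$pct_identity > 100)[1L],
         " of ", origin, call. = FALSE)
  }
  if (any(hsps$evalue < 0)) {
    stop("negative evalue at line ", which(hsps$evalue < 0)[1L], " of ",
         origin, call. = FALSE)
  }
  invisible(hsps)
}

#' Write a BLAST tabular hit table
#'
#' Serializes a data frame of HSP records back to the 12-column tabular
#' dialect; \code{parse_blast_tab(write_blast_tab(x))} is the identity.
#'
#' @param hsps HSP data frame as returned by [parse_blast_tab()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_blast_tab <- function(hsps, path) {
  stopifnot(all(blast12_cols %in% names(hsps)))
  utils::write.table(hsps[, blast12_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Percent-escape the characters reserved in GFF3 attribute values.
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

gff3_unescape <- function(x) {
  vapply(x, utils::URLdecode, character(1), USE.NAMES = FALSE)
}

#' Write domain annotations as GFF3
#'
#' Serializes annotations (for example, minicollagen domain calls from
#' [build_architecture()]) to a GFF3 file with the version pragma.
#' Coordinates are 1-based inclusive. Features are written in
#' (seqid, start) order.
#'
#' @param annotations Data frame with columns \code{seqid}, \code{type},
#'   \code{start}, \code{end}; optional \code{source}, \code{score},
#'   \code{strand}, \code{attributes} (named list column or preformatted
#'   attribute strings).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(annotations, path) {
  header <- "##gff-version 3"
  if (is.null(annotations) || nrow(annotations) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(c("seqid", "type", "start", "end") %in% names(annotations)))
  if (any(annotations$start > annotations$end)) {
    bad <- which(annotations$start > annotations$end)[1L]
    stop("annotation start > end (", annotations$seqid[bad], ":",
         annotations$start[bad], "-", annotations$end[bad], ")",
         call. = FALSE)
  }
  if (any(annotations$start < 1L)) {
    stop("annotation start < 1", call. = FALSE)
  }
  a <- annotations[order(annotations$seqid, annotations$start,
                         annotations$end), , drop = FALSE]
  n <- nrow(a)
  col_or <- function(name, default) {
    if (name %in% names(a)) as.character(a[[name]]) else rep(default, n)
  }
  attrs <- if ("attributes" %in% names(a)) {
    if (is.list(a$attributes)) {
      vapply(seq_len(n), function(i) {
        kv <- a$attributes[[i]]
        if (is.null(kv) || length(kv) == 0L) return(".")
        paste0(gff3_escape(names(kv)), "=",
               gff3_escape(as.character(unlist(kv))), collapse = ";")
      }, character(1))
    } else {
      as.character(a$attributes)
    }
  } else {
    paste0("ID=", gff3_escape(a$seqid), ":", col_or("type", "region"), ":",
           seq_len(n))
  }
  lines <- paste(gff3_escape(a$seqid),
                 col_or("source", "myxocol"),
                 a$type,
                 as.integer(a$start),
                 as.integer(a$end),
                 col_or("score", "."),
                 col_or("strand", "."),
                 col_or("phase", "."),
                 attrs,
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Minimal GFF3 reader for the annotation tables this package writes and
#' consumes (domain annotations, gene loci). Attribute values are
#' percent-unescaped and returned as a named-list column.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns \code{seqid}, \code{source}, \code{type},
#'   \code{start}, \code{end}, \code{score}, \code{strand}, \code{phase},
#'   \code{attributes} (list column of named character vectors).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(),
                      end = integer(), score = character(),
                      strand = character(), phase = character(),
                      attributes = I(list()), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    bad <- which(lengths(fields) != 9L)[1L]
    stop("GFF3 feature line ", bad, " does not have 9 columns (", path, ")",
         call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  attrs <- lapply(m[, 9L], function(s) {
    if (s == ".") return(character())
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(gff3_unescape(vapply(kv, function(p) {
      if (length(p) >= 2L) paste(p[-1L], collapse = "=") else ""
    }, character(1))),
    gff3_unescape(vapply(kv, `[`, character(1), 1L)))
  })
  data.frame(seqid = gff3_unescape(m[, 1L]), source = m[, 2L],
             type = m[, 3L], start = as.integer(m[, 4L]),
             end = as.integer(m[, 5L]), score = m[, 6L], strand = m[, 7L],
             phase = m[, 8L], attributes = I(attrs),
             stringsAsFactors = FALSE)
}

# 1-based inclusive [start, end]  ->  0-based half-open [start0, end0)
to_half_open <- function(start, end) {
  stopifnot(all(start >= 1L), all(start <= end))
  list(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}

# 0-based half-open [start0, end0)  ->  1-based inclusive [start, end]
to_one_based <- function(start0, end0) {
  stopifnot(all(start0 >= 0L), all(start0 < end0))
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}
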