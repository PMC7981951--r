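#' Gene locus table constructor / reader
#'
#' Loci are rows of (scaffold, start, end, strand, name) with 1-based
#' inclusive coordinates. [read_loci()] accepts either a headered 5-column
#' TSV (scaffold, start, end, strand, name) or a GFF3 file of gene rows
#' (the \code{Name} or \code{ID} attribute becomes the gene name).
#'
#' @param scaffold,start,end,strand,name Vectors of equal length.
#' @return Data frame of class \code{gene_loci}.
#' @export
gene_loci <- function(scaffold, start, end, strand, name) {
  stopifnot(all(start >= 1L), all(start <= end),
            all(strand %in% c("+", "-")))
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   name = as.character(name), stringsAsFactors = FALSE)
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' @rdname gene_loci
#' @param path Path to a loci TSV or GFF3 file.
#' @export
read_loci <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff-version")) {
    g <- read_gff3(path)
    g <- g[g$type %in% c("gene", "mRNA"), , drop = FALSE]
    nm <- vapply(seq_len(nrow(g)), function(i) {
      a <- g$attributes[[i]]
      if ("Name" %in% names(a)) a[["Name"]]
      else if ("ID" %in% names(a)) a[["ID"]]
      else paste0("gene", i)
    }, character(1))
    return(gene_loci(g$seqid, g$start, g$end, g$strand, nm))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "start", "end", "strand", "name")
  if (!all(need %in% names(df))) {
    stop("loci TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gene_loci(df$scaffold, df$start, df$end, df$strand, df$name)
}

#' Intergenic region length between two loci
#'
#' Bases strictly between two genes on the same scaffold (1-based
#' inclusive gene bounds): after coordinate sorting,
#' \code{start2 - end1 - 1}, clamped to 0 for adjacent or overlapping
#' genes. Symmetric in its arguments.
#'
#' @param a,b Single-row gene locus data frames (or 1-row slices of a
#'   [gene_loci()] table).
#' @return Non-negative integer IGR length.
#' @examples
#' x <- gene_loci("s", c(100, 700), c(400, 1000), c("+", "+"),
#'                c("Ncol-1", "Ncol-4"))
#' igr_length(x[1, ], x[2, ])  # 299
#' @export
igr_length <- function(a, b) {
  if (a$scaffold != b$scaffold) {
    stop("not co-localized: loci on different scaffolds (",
         a$scaffold, " vs ", b$scaffold, ")", call. = FALSE)
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  max(0L, as.integer(b$start) - as.integer(a$end) - 1L)
}

#' Orientation class of a gene pair
#'
#' After sorting by coordinate: equal strands give co-directional; (-,+)
#' is head-to-head (divergent: the two 5' ends flank the IGR); (+,-) is
#' tail-to-tail (convergent: the two 3' ends flank the IGR).
#'
#' @inheritParams igr_length
#' @return One of \code{"co_directional"}, \code{"head_to_head"},
#'   \code{"tail_to_tail"}.
#' @export
orientation <- function(a, b) {
  if (a$scaffold != b$scaffold) {
    stop("not co-localized: loci on different scaffolds", call. = FALSE)
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (a$strand == b$strand) {
    "co_directional"
  } else if (a$strand == "-") {
    "head_to_head"
  } else {
    "tail_to_tail"
  }
}

#' Scan a locus table for gene clusters
#'
#' Reports every same-scaffold gene pair whose IGR length is at most
#' \code{max_igr}; pairs on different scaffolds are never reported.
#'
#' @param loci A [gene_loci()] data frame.
#' @param max_igr Maximum IGR length (bp) for a pair to count as
#'   clustered.
#' @return Data frame with columns \code{scaffold}, \code{gene1},
#'   \code{gene2} (in coordinate order), \code{igr_len},
#'   \code{orientation}, ordered by scaffold then coordinate.
#' @export
cluster_scan <- function(loci, max_igr = 100000L) {
  rows <- list()
  for (sc in unique(loci$scaffold)) {
    sub <- loci[loci$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        igr <- igr_length(sub[i, ], sub[j, ])
        if (igr <= max_igr) {
          rows[[length(rows) + 1L]] <- data.frame(
            scaffold = sc, gene1 = sub$name[i], gene2 = sub$name[j],
            igr_len = igr, orientation = orientation(sub[i, ], sub[j, ]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(scaffold = character(), gene1 = character(),
                      gene2 = character(), igr_len = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
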