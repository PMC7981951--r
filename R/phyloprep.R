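#' Excise residue intervals from a protein
#'
#' Removes the given 1-based inclusive intervals (typically polyproline
#' linkers) and returns the concatenation of the retained spans together
#' with a coordinate map from trimmed positions back to original
#' positions, so alignment columns can be traced to the full-length
#' sequence.
#'
#' @param protein Amino-acid string.
#' @param intervals Data frame or matrix with columns \code{start},
#'   \code{end} (1-based inclusive), or a list of \code{c(start, end)}
#'   pairs. May be empty (identity).
#' @return List with \code{trimmed} (string) and \code{map} (integer
#'   vector: \code{map[i]} is the original position of trimmed residue
#'   \code{i}).
#' @examples
#' excise_regions(strrep("A", 100),
#'                data.frame(start = c(1, 91), end = c(10, 100)))$map[1]
#' @export
excise_regions <- function(protein, intervals) {
  protein <- as_single_seq(protein, "protein")
  n <- nchar(protein)
  iv <- normalize_intervals(intervals, n)
  if (nrow(iv) == 0L) {
    return(list(trimmed = protein, map = seq_len(n)))
  }
  drop <- logical(n)
  for (i in seq_len(nrow(iv))) {
    span <- iv$start[i]:iv$end[i]
    if (any(drop[span])) {
      stop("overlapping excision intervals for this sequence", call. = FALSE)
    }
    drop[span] <- TRUE
  }
  keep <- which(!drop)
  list(trimmed = paste(strsplit(protein, "", fixed = TRUE)[[1L]][keep],
                       collapse = ""),
       map = keep)
}

normalize_intervals <- function(intervals, n) {
  if (is.null(intervals) || length(intervals) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(p) {
      data.frame(start = p[1L], end = p[2L])
    }))
  }
  if (is.matrix(intervals)) {
    intervals <- data.frame(start = intervals[, 1L], end = intervals[, 2L])
  }
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  stopifnot(all(c("start", "end") %in% names(intervals)))
  iv <- data.frame(start = as.integer(intervals$start),
                   end = as.integer(intervals$end))
  if (any(iv$start < 1L) || any(iv$end > n) || any(iv$start > iv$end)) {
    stop("excision interval out of bounds or inverted", call. = FALSE)
  }
  iv[order(iv$start), , drop = FALSE]
}

#' Re-insert excised spans (inverse of excision)
#'
#' Reconstructs the original sequence from a trimmed sequence, its
#' coordinate map, and the excised text. Exists chiefly so the round-trip
#' property can be asserted.
#'
#' @param trimmed Trimmed string from [excise_regions()].
#' @param map Coordinate map from [excise_regions()].
#' @param original_len Length of the original sequence.
#' @param excised_chars Character vector (or string) of the removed
#'   residues, in original order.
#' @return The reconstructed original string.
#' @export
reinsert_regions <- function(trimmed, map, original_len, excised_chars) {
  if (length(excised_chars) == 1L && nchar(excised_chars[1L]) > 1L) {
    excised_chars <- strsplit(excised_chars, "", fixed = TRUE)[[1L]]
  }
  out <- character(original_len)
  out[map] <- strsplit(trimmed, "", fixed = TRUE)[[1L]]
  out[setdiff(seq_len(original_len), map)] <- excised_chars
  paste(out, collapse = "")
}

#' Build an alignment-ready sequence set with polyproline regions excised
#'
#' For each protein, linker annotations of class polyP (from scanner
#' architectures or a GFF3 annotation table) are excised; records without
#' polyP annotations pass through unchanged. The result is ready for an
#' external aligner.
#'
#' @param proteins [read_fasta()] data frame.
#' @param annotations Either the result of [scan_proteins()], a list of
#'   \code{ncol_architecture} objects, or a GFF3-style annotation data
#'   frame whose linker rows carry a \code{class} attribute.
#' @param excise_classes Linker classes to excise (default \code{"polyP"};
#'   set to \code{c("polyP", "SG_rich", "other")} to excise all linkers).
#' @return List with \code{records} (trimmed [read_fasta()]-style data
#'   frame) and \code{provenance} (per-record data frame: id,
#'   original_len, trimmed_len, n_excised_intervals).
#' @export
build_alignment_set <- function(proteins, annotations,
                                excise_classes = "polyP") {
  ann <- linker_intervals(annotations, excise_classes)
  missing_prot <- setdiff(unique(ann$seqid), proteins$id)
  if (length(missing_prot)) {
    stop("annotation(s) reference missing protein(s): ",
         paste(missing_prot, collapse = ", "), call. = FALSE)
  }
  trimmed <- character(nrow(proteins))
  n_iv <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    iv <- ann[ann$seqid == proteins$id[i], c("start", "end"), drop = FALSE]
    res <- excise_regions(proteins$seq[i], iv)
    trimmed[i] <- res$trimmed
    n_iv[i] <- nrow(iv)
  }
  desc <- if (nrow(proteins)) paste0(proteins$id, " polyP-excised")
  else character()
  records <- data.frame(id = proteins$id, description = desc,
                        seq = trimmed, stringsAsFactors = FALSE)
  provenance <- data.frame(id = proteins$id,
                           original_len = nchar(proteins$seq),
                           trimmed_len = nchar(trimmed),
                           n_excised_intervals = n_iv,
                           stringsAsFactors = FALSE)
  list(records = records, provenance = provenance)
}

linker_intervals <- function(annotations, classes) {
  if (!is.null(annotations$architectures)) {
    annotations <- annotations$architectures
  }
  if (is.list(annotations) && !is.data.frame(annotations) &&
      all(vapply(annotations, inherits, logical(1), "ncol_architecture"))) {
    annotations <- architecture_annotations(annotations)
  }
  stopifnot(is.data.frame(annotations))
  link <- annotations[annotations$type == "linker", , drop = FALSE]
  if (nrow(link) == 0L) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cls <- if ("attributes" %in% names(link) && is.list(link$attributes)) {
    vapply(link$attributes, function(a) {
      if ("class" %in% names(a)) as.character(a[["class"]]) else "other"
    }, character(1))
  } else if ("class" %in% names(link)) {
    as.character(link$class)
  } else {
    rep("other", nrow(link))
  }
  link <- link[cls %in% classes, , drop = FALSE]
  data.frame(seqid = link$seqid, start = link$start, end = link$end,
             stringsAsFactors = FALSE)
}
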