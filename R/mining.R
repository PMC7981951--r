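#' Extract CRD query subsequences from annotated proteins
#'
#' Builds the query set used to mine minicollagen orthologs: one query per
#' annotated cysteine-rich domain (N- or C-terminal), cut out of its source
#' protein. Query ids encode the source id, the group label and the region,
#' e.g. \code{"prot1|Ncol-5|N_CRD"}.
#'
#' @param proteins [read_fasta()] data frame of protein sequences.
#' @param annotations Annotation data frame with columns \code{seqid},
#'   \code{type} (rows with type \code{N_CRD} or \code{C_CRD} are used),
#'   \code{start}, \code{end}; optionally a \code{group} column (or a
#'   \code{group} key in a GFF3 \code{attributes} list column) carrying the
#'   Ncol group label.
#' @return A data frame (the query set) with columns \code{query_id},
#'   \code{source_id}, \code{group}, \code{region}, \code{seq}. Proteins
#'   with no CRD annotation are skipped with a warning.
#' @export
extract_crd_queries <- function(proteins, annotations) {
  stopifnot(is.data.frame(proteins), is.data.frame(annotations))
  crd <- annotations[annotations$type %in% c("N_CRD", "C_CRD"), ,
                     drop = FALSE]
  no_crd <- setdiff(proteins$id, crd$seqid)
  if (length(no_crd)) {
    warning("protein(s) without CRD annotation skipped: ",
            paste(no_crd, collapse = ", "), call. = FALSE)
  }
  if (nrow(crd) == 0L) {
    return(data.frame(query_id = character(), source_id = character(),
                      group = character(), region = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  group <- if ("group" %in% names(crd)) {
    as.character(crd$group)
  } else if ("attributes" %in% names(crd)) {
    vapply(crd$attributes, function(a) {
      if ("group" %in% names(a)) a[["group"]] else "NA"
    }, character(1))
  } else {
    rep("NA", nrow(crd))
  }
  m <- match(crd$seqid, proteins$id)
  if (anyNA(m)) {
    stop("annotation references unknown protein(s): ",
         paste(unique(crd$seqid[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  plen <- nchar(proteins$seq[m])
  if (any(crd$end > plen)) {
    stop("CRD annotation extends beyond its protein: ",
         crd$seqid[which(crd$end > plen)[1L]], call. = FALSE)
  }
  data.frame(query_id = paste(crd$seqid, group, crd$type, sep = "|"),
             source_id = crd$seqid, group = group, region = crd$type,
             seq = substr(proteins$seq[m], crd$start, crd$end),
             stringsAsFactors = FALSE)
}

#' E-value gate for BLAST hits
#'
#' Retains hits with E-value at or below the cutoff (inclusive boundary),
#' preserving input order. The mining default cutoff is 1e-5.
#'
#' @param hits HSP data frame.
#' @param cutoff Positive E-value cutoff.
#' @return The retained subset of \code{hits}.
#' @export
filter_hits_evalue <- function(hits, cutoff = 1e-5) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  hits[hits$evalue <= cutoff, , drop = FALSE]
}

#' Subthreshold hits, for manual inspection
#'
#' Complement of [filter_hits_evalue()]: the hits an automatic gate drops,
#' dumped so low-scoring candidates can be mined by eye.
#'
#' @inheritParams filter_hits_evalue
#' @return The dropped subset of \code{hits}.
#' @export
subthreshold_hits <- function(hits, cutoff = 1e-5) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  hits[hits$evalue > cutoff, , drop = FALSE]
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) {
    return(stats::setNames(character(), character()))
  }
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Reciprocal best-hit confirmation
#'
#' A pair (q, s) is confirmed iff s is the best forward subject of q and q
#' is the best reverse subject of s. "Best" ranks by bitscore (descending),
#' then E-value (ascending), then subject id (lexicographic) — a fully
#' deterministic tie-break.
#'
#' @param forward_hits HSPs of queries vs the target database.
#' @param reverse_hits HSPs of target sequences vs the query database.
#' @return Data frame with columns \code{query_id}, \code{subject_id}, one
#'   row per confirmed reciprocal pair, ordered by \code{query_id}.
#' @export
reciprocal_check <- function(forward_hits, reverse_hits) {
  fwd <- best_hit_per_query(forward_hits)
  rev <- best_hit_per_query(reverse_hits)
  confirmed <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  out <- data.frame(query_id = confirmed,
                    subject_id = unname(fwd[confirmed]),
                    stringsAsFactors = FALSE)
  out[order(out$query_id), , drop = FALSE]
}
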