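#' Identity-weighted hit-coverage profile for one contig
#'
#' Merges all HSPs of one contig into disjoint coverage segments. Every
#' contig base covered by at least one HSP is assigned the maximum percent
#' identity (as a fraction) among the HSPs covering it; uncovered bases
#' contribute zero. The scalar similarity score is
#' \deqn{s = \sum_{seg} |seg| \cdot id_{seg} / L}
#' where L is the contig length taken from the assembly, never from the
#' hits. HSPs are pooled across all subjects; subject strand is ignored.
#'
#' @param hsps HSP data frame (see [parse_blast_tab()]) for a single contig;
#'   may have zero rows.
#' @param contig_len Contig length in bases (positive integer).
#' @param contig_id Contig id; required when \code{hsps} is empty, otherwise
#'   taken from the hits and checked for consistency.
#' @return An object of class \code{coverage_profile}: a list with
#'   \code{contig_id}, \code{contig_len}, \code{segments} (data frame with
#'   0-based half-open \code{start0}, \code{end0} and \code{best_identity}
#'   in [0,1], disjoint and sorted) and \code{similarity_score} in [0,1].
#' @examples
#' h <- data.frame(query_id = "c", subject_id = c("s1", "s2"),
#'                 pct_identity = c(95, 85), aln_len = c(100, 100),
#'                 mismatches = 0L, gap_opens = 0L,
#'                 q_start = c(1L, 51L), q_end = c(100L, 150L),
#'                 s_start = 1L, s_end = 100L, evalue = 0, bitscore = 180)
#' merge_hsps(h, contig_len = 200L)$similarity_score  # 0.6875
#' @export
merge_hsps <- function(hsps, contig_len, contig_id = NULL) {
  stopifnot(is.numeric(contig_len), length(contig_len) == 1L,
            contig_len >= 1)
  contig_len <- as.integer(contig_len)
  if (nrow(hsps) == 0L) {
    if (is.null(contig_id)) {
      stop("contig_id required when no HSPs are given", call. = FALSE)
    }
    return(new_coverage_profile(contig_id, contig_len,
                                empty_segments(), 0))
  }
  ids <- unique(hsps$query_id)
  if (length(ids) != 1L) {
    stop("merge_hsps() received HSPs from multiple contigs: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (!is.null(contig_id) && contig_id != ids) {
    stop("contig_id '", contig_id, "' does not match HSP query_id '",
         ids, "'", call. = FALSE)
  }
  over <- which(hsps$q_end > contig_len)
  if (length(over)) {
    stop("HSP ", ids, ":", hsps$q_start[over[1L]], "-", hsps$q_end[over[1L]],
         " extends beyond contig length ", contig_len, call. = FALSE)
  }

  # Greedy sweep from highest identity: each HSP claims only bases not yet
  # claimed by a better HSP, so each base carries its per-base max identity.
  ord <- order(-hsps$pct_identity, hsps$q_start, hsps$q_end)
  covered <- IRanges::IRanges()
  seg_start <- integer(); seg_end <- integer(); seg_id <- numeric()
  for (i in ord) {
    r <- IRanges::IRanges(start = hsps$q_start[i], end = hsps$q_end[i])
    new <- IRanges::setdiff(r, covered)
    if (length(new)) {
      seg_start <- c(seg_start, IRanges::start(new))
      seg_end <- c(seg_end, IRanges::end(new))
      seg_id <- c(seg_id, rep(hsps$pct_identity[i] / 100, length(new)))
      covered <- IRanges::reduce(IRanges::union(covered, r))
    }
  }
  o <- order(seg_start)
  segments <- data.frame(start0 = seg_start[o] - 1L, end0 = seg_end[o],
                         best_identity = seg_id[o])
  # Merge touching segments that ended up with identical identity.
  segments <- coalesce_segments(segments)
  score <- sum((segments$end0 - segments$start0) * segments$best_identity) /
    contig_len
  new_coverage_profile(ids, contig_len, segments, score)
}

empty_segments <- function() {
  data.frame(start0 = integer(), end0 = integer(), best_identity = numeric())
}

coalesce_segments <- function(segments) {
  n <- nrow(segments)
  if (n <= 1L) return(segments)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && !keep[j]) j <- j + 1L
    if (j <= n && segments$end0[i] == segments$start0[j] &&
        segments$best_identity[i] == segments$best_identity[j]) {
      segments$start0[j] <- segments$start0[i]
      keep[i] <- FALSE
    }
  }
  segments[keep, , drop = FALSE]
}

new_coverage_profile <- function(contig_id, contig_len, segments, score) {
  structure(list(contig_id = contig_id, contig_len = contig_len,
                 segments = segments, similarity_score = score),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s (%d bp): %d segment(s), score %.4f\n",
              x$contig_id, x$contig_len, nrow(x$segments),
              x$similarity_score))
  invisible(x)
}

contig_lengths <- function(contigs) {
  if (is.data.frame(contigs)) {
    stopifnot(all(c("id", "seq") %in% names(contigs)))
    stats::setNames(nchar(contigs$seq), contigs$id)
  } else if (is.numeric(contigs) && !is.null(names(contigs))) {
    contigs
  } else {
    stop("contigs must be a read_fasta() data frame or a named length vector",
         call. = FALSE)
  }
}

score_one <- function(hsps, len, id, mode, coverage_floor) {
  if (nrow(hsps) == 0L) return(0)
  prof <- merge_hsps(hsps, len, id)
  if (mode == "weighted") {
    prof$similarity_score
  } else {
    keep <- prof$segments$best_identity >= coverage_floor
    sum(prof$segments$end0[keep] - prof$segments$start0[keep]) / len
  }
}

#' Filter contigs by hit-coverage similarity or by any-hit presence
#'
#' Applies one removal policy to a whole assembly. Under
#' \code{similarity_threshold}, a contig is removed iff its similarity
#' score strictly exceeds \code{threshold} ("more than 90\% similar";
#' boundary equality keeps the contig). Under \code{any_hit}, a contig is
#' removed iff it has at least one hit, regardless of identity.
#'
#' @param contigs Assembly: a [read_fasta()] data frame or a named vector
#'   of contig lengths.
#' @param hits HSP data frame; every \code{query_id} must name a contig.
#' @param policy \code{"similarity_threshold"} or \code{"any_hit"}.
#' @param threshold Removal threshold in [0,1] (similarity policy only).
#' @param mode Scoring mode: \code{"weighted"} (identity-weighted coverage,
#'   the default) or \code{"coverage_only"} (fraction of bases covered by
#'   segments with identity >= \code{coverage_floor}).
#' @param coverage_floor Identity floor for \code{coverage_only} mode.
#' @param max_evalue Optional E-value gate applied to hits before scoring;
#'   default \code{NULL} (no gate — "any hit" means any hit).
#' @return A list with \code{kept} and \code{removed} (character vectors of
#'   contig ids, together a partition of the input) and \code{decisions}, a
#'   data frame with one row per contig: \code{contig_id}, \code{length},
#'   \code{n_hits}, \code{score}, \code{policy}, \code{threshold},
#'   \code{removed}.
#' @export
filter_contigs <- function(contigs, hits,
                           policy = c("similarity_threshold", "any_hit"),
                           threshold = 0.90,
                           mode = c("weighted", "coverage_only"),
                           coverage_floor = 0.90,
                           max_evalue = NULL) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  lens <- contig_lengths(contigs)
  if (!is.null(max_evalue)) {
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  }
  unknown <- setdiff(unique(hits$query_id), names(lens))
  if (length(unknown)) {
    stop("hits reference contig id(s) absent from the assembly: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  split_hits <- split(seq_len(nrow(hits)), hits$query_id)
  ids <- names(lens)
  n_hits <- integer(length(ids))
  score <- numeric(length(ids))
  for (k in seq_along(ids)) {
    idx <- split_hits[[ids[k]]]
    if (is.null(idx)) next
    n_hits[k] <- length(idx)
    score[k] <- score_one(hits[idx, , drop = FALSE], lens[[k]], ids[k],
                          mode, coverage_floor)
  }
  removed_flag <- if (policy == "similarity_threshold") {
    score > threshold
  } else {
    n_hits > 0L
  }
  decisions <- data.frame(contig_id = ids, length = unname(lens),
                          n_hits = n_hits, score = score,
                          policy = policy, threshold = threshold,
                          removed = removed_flag, stringsAsFactors = FALSE)
  list(kept = ids[!removed_flag], removed = ids[removed_flag],
       decisions = decisions)
}

#' Two-stage decontamination: host any-hit, then contaminant similarity
#'
#' The post-assembly cleaning workflow for a doubly contaminated assembly:
#' first every contig with any hit against the host genome is removed, then
#' the survivors are scored against the co-infecting species' transcriptome
#' and contigs with similarity above \code{threshold} are removed. A contig
#' hit by both references is counted once, as host-removed.
#'
#' @inheritParams filter_contigs
#' @param host_hits HSPs of contigs vs host genome.
#' @param contam_hits HSPs of contigs vs the contaminant transcriptome.
#' @return An object of class \code{clean_report}: list with \code{kept},
#'   \code{removed_host}, \code{removed_contaminant} (id vectors),
#'   \code{counts} (named integer vector: input, kept, host_removed,
#'   contaminant_removed) and \code{decisions} (per-contig table with a
#'   \code{stage} column).
#' @export
two_stage_clean <- function(contigs, host_hits, contam_hits,
                            threshold = 0.90,
                            mode = c("weighted", "coverage_only"),
                            coverage_floor = 0.90,
                            max_evalue = NULL) {
  mode <- match.arg(mode)
  lens <- contig_lengths(contigs)
  stage1 <- filter_contigs(lens, host_hits, policy = "any_hit",
                           max_evalue = max_evalue)
  survivors <- lens[stage1$kept]
  contam_hits2 <- contam_hits[contam_hits$query_id %in% names(survivors), ,
                              drop = FALSE]
  unknown <- setdiff(unique(contam_hits$query_id), names(lens))
  if (length(unknown)) {
    stop("contaminant hits reference unknown contig id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  stage2 <- filter_contigs(survivors, contam_hits2,
                           policy = "similarity_threshold",
                           threshold = threshold, mode = mode,
                           coverage_floor = coverage_floor,
                           max_evalue = max_evalue)
  d1 <- stage1$decisions
  d1$stage <- ifelse(d1$removed, "host", NA_character_)
  d1$contam_score <- NA_real_
  d2 <- stage2$decisions
  m <- match(d2$contig_id, d1$contig_id)
  d1$contam_score[m] <- d2$score
  d1$stage[m[d2$removed]] <- "contaminant"
  d1$stage[is.na(d1$stage)] <- "kept"
  decisions <- data.frame(contig_id = d1$contig_id, length = d1$length,
                          n_host_hits = d1$n_hits,
                          contam_score = d1$contam_score,
                          stage = d1$stage, stringsAsFactors = FALSE)
  counts <- c(input = length(lens), kept = length(stage2$kept),
              host_removed = length(stage1$removed),
              contaminant_removed = length(stage2$removed))
  stopifnot(counts[["input"]] == counts[["kept"]] +
              counts[["host_removed"]] + counts[["contaminant_removed"]])
  structure(list(kept = stage2$kept, removed_host = stage1$removed,
                 removed_contaminant = stage2$removed, counts = counts,
                 decisions = decisions),
            class = "clean_report")
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf(paste0("<clean_report> %d contigs in: %d kept, ",
                     "%d host-removed, %d contaminant-removed\n"),
              x$counts[["input"]], x$counts[["kept"]],
              x$counts[["host_removed"]], x$counts[["contaminant_removed"]]))
  invisible(x)
}
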