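#' CRD cysteine-spacing motifs
#'
#' A cysteine-rich domain (CRD) motif is six cysteines C1..C6 with
#' constrained residue counts in the five inter-cysteine gaps. The
#' canonical minicollagen CRD has three residues in every internal gap and
#' a terminal adjacent "CC" pair; the noncanonical C-terminal CRD found in
#' myxozoan Ncol-4/Ncol-5 widens the C2-C3 gap to 9-10 residues.
#'
#' @param gap_ranges List of 5 integer vectors \code{c(min, max)}: allowed
#'   residue counts between consecutive cysteines.
#' @param label Motif label, e.g. \code{"canonical"} or
#'   \code{"noncanonical_C"}.
#' @return An object of class \code{crd_motif}.
#' @export
crd_motif <- function(gap_ranges, label) {
  if (length(gap_ranges) < 5L) {
    stop("a CRD motif needs 5 gap ranges (6 cysteines)", call. = FALSE)
  }
  gap_ranges <- lapply(gap_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    stopifnot(length(r) == 2L, r[1L] <= r[2L], r[1L] >= 0L)
    r
  })
  structure(list(gap_ranges = gap_ranges, label = label),
            class = "crd_motif")
}

#' @rdname crd_motif
#' @export
canonical_crd <- function() {
  crd_motif(list(c(3, 3), c(3, 3), c(3, 3), c(3, 3), c(0, 0)), "canonical")
}

#' @rdname crd_motif
#' @export
noncanonical_c_crd <- function() {
  crd_motif(list(c(3, 3), c(9, 10), c(3, 3), c(3, 3), c(0, 0)),
            "noncanonical_C")
}

widen_ranges <- function(motif, tolerance) {
  lapply(motif$gap_ranges,
         function(r) c(max(0L, r[1L] - tolerance), r[2L] + tolerance))
}

cys_positions <- function(protein) {
  which(strsplit(protein, "", fixed = TRUE)[[1L]] == "C")
}

#' Find CRD motif matches in a protein
#'
#' Scans every window of six consecutive cysteine occurrences and reports
#' those whose five inter-cysteine gaps all fall within the motif's gap
#' ranges, each widened by \code{tolerance} on both sides (floored at 0).
#' Residues inside gaps are unconstrained apart from not being cysteine
#' (which would split the window). Matches are reported left to right and
#' may overlap.
#'
#' @param protein Uppercase amino-acid string.
#' @param motif A [crd_motif()].
#' @param tolerance Non-negative integer widening applied to every gap
#'   range.
#' @return Data frame with columns \code{start}, \code{end} (1-based
#'   inclusive span C1..C6) and \code{gaps} (list column of the five
#'   observed gap lengths).
#' @examples
#' find_crd("CAAACAAACAAACAAACC", canonical_crd(), tolerance = 0)
#' @export
find_crd <- function(protein, motif, tolerance = 1L) {
  stopifnot(inherits(motif, "crd_motif"), tolerance >= 0L)
  ranges <- widen_ranges(motif, as.integer(tolerance))
  cys <- cys_positions(protein)
  out_start <- integer(); out_end <- integer(); out_gaps <- list()
  if (length(cys) >= 6L) {
    for (i in seq_len(length(cys) - 5L)) {
      win <- cys[i:(i + 5L)]
      gaps <- diff(win) - 1L
      ok <- all(vapply(seq_len(5L), function(k) {
        gaps[k] >= ranges[[k]][1L] && gaps[k] <= ranges[[k]][2L]
      }, logical(1)))
      if (ok) {
        out_start <- c(out_start, win[1L])
        out_end <- c(out_end, win[6L])
        out_gaps <- c(out_gaps, list(gaps))
      }
    }
  }
  data.frame(start = out_start, end = out_end, gaps = I(out_gaps),
             stringsAsFactors = FALSE)
}

# CRD windows where exactly one gap is oversized relative to the motif and
# the oversized gap is proline-rich: the "C-CRD interrupted by a
# polyproline stretch" signature of Ncol-4.
find_crd_interrupted <- function(protein, motif, tolerance = 1L,
                                 min_insert = 3L, max_insert = 60L,
                                 min_pro_frac = 0.5) {
  ranges <- widen_ranges(motif, as.integer(tolerance))
  cys <- cys_positions(protein)
  out <- data.frame(start = integer(), end = integer(),
                    gaps = I(list()), interrupted_gap = integer(),
                    stringsAsFactors = FALSE)
  if (length(cys) < 6L) return(out)
  for (i in seq_len(length(cys) - 5L)) {
    win <- cys[i:(i + 5L)]
    gaps <- diff(win) - 1L
    within <- vapply(seq_len(5L), function(k) {
      gaps[k] >= ranges[[k]][1L] && gaps[k] <= ranges[[k]][2L]
    }, logical(1))
    over <- which(!within & gaps > vapply(ranges, `[`, integer(1), 2L))
    if (sum(!within) == 1L && length(over) == 1L) {
      k <- over
      insert_len <- gaps[k] - ranges[[k]][2L]
      if (insert_len < min_insert || insert_len > max_insert) next
      gap_seq <- substr(protein, win[k] + 1L, win[k + 1L] - 1L)
      pro_frac <- lengths(regmatches(gap_seq, gregexpr("P", gap_seq))) /
        nchar(gap_seq)
      if (pro_frac >= min_pro_frac) {
        out <- rbind(out, data.frame(start = win[1L], end = win[6L],
                                     gaps = I(list(gaps)),
                                     interrupted_gap = k,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Longest run of collagen Gly-X-Y triplets
#'
#' Finds the longest run of consecutive triplets each beginning with
#' glycine. The count is the number of complete triplets; a trailing
#' partial triplet never counts. With \code{max_gaps > 0}, up to that many
#' broken (non-G-led) triplets are tolerated inside a run without counting
#' toward it; the run must still begin and end on a G-led triplet.
#' Ties go to the leftmost run.
#'
#' @param protein Amino-acid string.
#' @param region Optional \code{c(start, end)} 1-based inclusive window to
#'   restrict the search; returned coordinates stay on the full protein.
#' @param max_gaps Broken triplets tolerated per run (default 0).
#' @return List with \code{count} (integer, 0 if no G-led triplet),
#'   \code{start} and \code{end} (1-based span of the run, \code{NA} when
#'   count is 0).
#' @examples
#' count_gxy("GPPGPQGAPGQA")  # 4 repeats, span 1-12
#' @export
count_gxy <- function(protein, region = NULL, max_gaps = 0L) {
  s <- protein
  offset <- 0L
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L,
              region[2L] <= nchar(protein))
    s <- substr(protein, region[1L], region[2L])
    offset <- region[1L] - 1L
  }
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  best <- 0L; best_start <- NA_integer_; best_end <- NA_integer_
  i <- 1L
  while (i + 2L <= n) {
    if (chars[i] == "G") {
      j <- i; k <- 0L; gaps_used <- 0L; end_good <- i - 1L
      while (j + 2L <= n) {
        if (chars[j] == "G") {
          k <- k + 1L
          end_good <- j + 2L
          j <- j + 3L
        } else if (gaps_used < max_gaps && j + 5L <= n &&
                   chars[j + 3L] == "G") {
          gaps_used <- gaps_used + 1L
          j <- j + 3L
        } else {
          break
        }
      }
      if (k > best) {
        best <- k; best_start <- i; best_end <- end_good
      }
    }
    i <- i + 1L
  }
  if (best == 0L) {
    list(count = 0L, start = NA_integer_, end = NA_integer_)
  } else {
    list(count = best, start = best_start + offset, end = best_end + offset)
  }
}

#' Classify a linker segment by residue composition
#'
#' Minicollagen linkers flanking the collagen domain are classified as
#' polyproline (\code{polyP}: proline fraction at least \code{theta_p}),
#' serine/glycine-rich (\code{SG_rich}: combined Ser+Gly fraction at least
#' \code{theta_sg}) or \code{other}. polyP takes precedence.
#'
#' @param segment Amino-acid string of length >= 1.
#' @param theta_p Proline-fraction threshold (default 0.30).
#' @param theta_sg Ser+Gly fraction threshold (default 0.50).
#' @return List with \code{class} and \code{composition} (named residue
#'   fraction vector over the segment).
#' @export
classify_linker <- function(segment, theta_p = 0.30, theta_sg = 0.50) {
  if (!nzchar(segment)) {
    stop("cannot classify an empty linker segment", call. = FALSE)
  }
  chars <- strsplit(segment, "", fixed = TRUE)[[1L]]
  comp <- table(chars) / length(chars)
  composition <- stats::setNames(as.numeric(comp), names(comp))
  frac <- function(a) sum(composition[names(composition) %in% a])
  cls <- if (frac("P") >= theta_p) {
    "polyP"
  } else if (frac(c("S", "G")) >= theta_sg) {
    "SG_rich"
  } else {
    "other"
  }
  list(class = cls, composition = composition)
}

#' Detect the propeptide KR cleavage dipeptide
#'
#' Canonical minicollagen propeptides end in a lysine-arginine ("KR")
#' cleavage motif; myxozoan Ncol-5 lacks it. By default the motif must sit
#' at the segment's terminal two residues; \code{where = "anywhere"}
#' accepts any internal occurrence.
#'
#' @param segment Propeptide amino-acid string.
#' @param where \code{"terminal"} (default) or \code{"anywhere"}.
#' @return Logical; segments shorter than 2 residues return \code{FALSE}
#'   with a warning.
#' @export
detect_kr <- function(segment, where = c("terminal", "anywhere")) {
  where <- match.arg(where)
  if (nchar(segment) < 2L) {
    warning("propeptide segment shorter than 2 residues; KR undetectable",
            call. = FALSE)
    return(FALSE)
  }
  if (where == "terminal") {
    substr(segment, nchar(segment) - 1L, nchar(segment)) == "KR"
  } else {
    grepl("KR", segment, fixed = TRUE)
  }
}

#' Scanner configuration
#'
#' Bundles the tunable parameters of the minicollagen scanner: the two CRD
#' motifs, the gap tolerance, linker composition thresholds, KR position
#' convention, broken-triplet allowance and the classification call
#' threshold.
#'
#' @param canonical,noncanonical_c CRD motifs (see [crd_motif()]).
#' @param tolerance Gap-range widening for CRD matching.
#' @param theta_p,theta_sg Linker composition thresholds.
#' @param kr_where KR detection convention (\code{"terminal"} or
#'   \code{"anywhere"}).
#' @param max_gxy_gaps Broken triplets tolerated per Gly-X-Y run.
#' @param call_threshold Minimum rule confidence for an Ncol call.
#' @return A list of class \code{ncolscan_config}.
#' @export
ncolscan_config <- function(canonical = canonical_crd(),
                            noncanonical_c = noncanonical_c_crd(),
                            tolerance = 1L,
                            theta_p = 0.30, theta_sg = 0.50,
                            kr_where = "terminal",
                            max_gxy_gaps = 0L,
                            call_threshold = 0.8) {
  structure(list(canonical = canonical, noncanonical_c = noncanonical_c,
                 tolerance = as.integer(tolerance), theta_p = theta_p,
                 theta_sg = theta_sg, kr_where = kr_where,
                 max_gxy_gaps = as.integer(max_gxy_gaps),
                 call_threshold = call_threshold),
            class = "ncolscan_config")
}

pick_crd_after <- function(pos, plain_noncanon, plain_canon, interrupted) {
  # Candidate C-CRDs downstream of `pos`; smallest start wins, plain
  # matches before interrupted ones at equal start.
  cand <- list()
  add <- function(df, label, inter, prio) {
    df <- df[df$start > pos, , drop = FALSE]
    if (nrow(df)) {
      cand[[length(cand) + 1L]] <<- data.frame(
        start = df$start[1L], end = df$end[1L], label = label,
        interrupted = inter, prio = prio, stringsAsFactors = FALSE)
    }
  }
  add(plain_noncanon, "noncanonical", FALSE, 1L)
  add(plain_canon, "canonical", FALSE, 2L)
  add(interrupted, "noncanonical", TRUE, 3L)
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand[order(cand$start, cand$prio), , drop = FALSE][1L, , drop = FALSE]
}

#' Build the domain architecture of a candidate minicollagen
#'
#' Locates, in order, an optional signal peptide and propeptide (from
#' external annotations or by convention), the N-terminal CRD, the central
#' Gly-X-Y collagen domain, the C-terminal CRD, and the linkers between
#' them; derives repeat count, KR presence and linker classes; and runs the
#' Ncol classification rules.
#'
#' Without annotations, the propeptide is taken as the span from residue 1
#' to the residue before the N-CRD (signal-peptide prediction is out of
#' scope), and the KR check uses its last two residues.
#'
#' @param protein Amino-acid string (length >= 30).
#' @param config An [ncolscan_config()].
#' @param seq_id Sequence id carried into the result.
#' @param annotations Optional data frame (GFF3-style: \code{seqid},
#'   \code{type}, \code{start}, \code{end}) supplying \code{signal} and/or
#'   \code{propeptide} spans for this protein.
#' @return An object of class \code{ncol_architecture}: list with
#'   \code{seq_id}, \code{length}, \code{domains} (ordered data frame of
#'   \code{dtype}, \code{start}, \code{end}), \code{gxy_repeat_count},
#'   \code{kr_present}, \code{linker_classes},
#'   \code{linker_after_gxy}, \code{n_crd}, \code{c_crd},
#'   \code{c_crd_interrupted}, \code{ncol_call}, \code{confidence},
#'   \code{rule_hits}.
#' @export
build_architecture <- function(protein, config = ncolscan_config(),
                               seq_id = "protein",
                               annotations = NULL) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) < 30L) {
    stop("protein shorter than 30 residues: ", seq_id, call. = FALSE)
  }
  n <- nchar(protein)
  tol <- config$tolerance
  gxy <- count_gxy(protein, max_gaps = config$max_gxy_gaps)
  canon <- find_crd(protein, config$canonical, tol)
  noncanon <- find_crd(protein, config$noncanonical_c, tol)
  inter_n <- find_crd_interrupted(protein, config$noncanonical_c, tol)
  inter_c <- find_crd_interrupted(protein, config$canonical, tol)
  interrupted <- rbind(inter_n, inter_c)
  if (nrow(interrupted) > 1L) {
    interrupted <- interrupted[order(interrupted$start), , drop = FALSE]
    interrupted <- interrupted[!duplicated(interrupted$start), , drop = FALSE]
  }

  dom <- list()
  add_dom <- function(dtype, start, end, attrs = list()) {
    dom[[length(dom) + 1L]] <<- list(dtype = dtype, start = start,
                                     end = end, attrs = attrs)
  }

  n_crd_label <- NA_character_
  c_crd_label <- NA_character_
  c_crd_interrupted <- FALSE
  ncrd <- NULL; ccrd <- NULL

  if (gxy$count > 0L) {
    before <- canon[canon$end < gxy$start, , drop = FALSE]
    if (nrow(before)) {
      ncrd <- before[nrow(before), , drop = FALSE]  # nearest upstream
      n_crd_label <- "canonical"
    }
    ccrd <- pick_crd_after(gxy$end, noncanon, canon, interrupted)
  } else {
    if (nrow(canon)) {
      ncrd <- canon[1L, , drop = FALSE]
      n_crd_label <- "canonical"
    }
    after_pos <- if (!is.null(ncrd)) ncrd$end else 0L
    ccrd <- pick_crd_after(after_pos, noncanon, canon, interrupted)
  }
  if (!is.null(ccrd)) {
    c_crd_label <- ccrd$label
    c_crd_interrupted <- isTRUE(ccrd$interrupted)
  }

  if (is.null(ncrd) && is.null(ccrd) && gxy$count == 0L) {
    arch <- new_ncol_architecture(seq_id, n, domains = empty_domains(),
                                  gxy_count = 0L, kr_present = FALSE,
                                  linker_classes = character(),
                                  linker_after_gxy = NA_character_,
                                  n_crd = NA_character_,
                                  c_crd = NA_character_,
                                  c_crd_interrupted = FALSE)
    return(classify_ncol(arch, call_threshold = config$call_threshold))
  }

  # Signal / propeptide: external annotations win; otherwise everything
  # upstream of the N-CRD is treated as propeptide.
  ann <- annotations
  if (!is.null(ann)) ann <- ann[ann$seqid == seq_id, , drop = FALSE]
  sig <- if (!is.null(ann)) ann[ann$type == "signal", , drop = FALSE]
  pro <- if (!is.null(ann)) ann[ann$type == "propeptide", , drop = FALSE]
  propep_span <- NULL
  if (!is.null(ann) && nrow(sig)) {
    add_dom("signal", sig$start[1L], sig$end[1L])
  }
  if (!is.null(ann) && nrow(pro)) {
    propep_span <- c(pro$start[1L], pro$end[1L])
  } else if (!is.null(ncrd)) {
    pstart <- if (!is.null(ann) && nrow(sig)) sig$end[1L] + 1L else 1L
    if (pstart <= ncrd$start - 1L) {
      propep_span <- c(pstart, ncrd$start - 1L)
    }
  }
  kr_present <- FALSE
  if (!is.null(propep_span)) {
    add_dom("propeptide", propep_span[1L], propep_span[2L])
    kr_present <- suppressWarnings(
      detect_kr(substr(protein, propep_span[1L], propep_span[2L]),
                where = config$kr_where))
  }

  linker_classes <- character()
  linker_after_gxy <- NA_character_
  if (!is.null(ncrd)) {
    add_dom("N_CRD", ncrd$start, ncrd$end,
            list(motif = n_crd_label,
                 gaps = paste(ncrd$gaps[[1L]], collapse = ",")))
  }
  if (gxy$count > 0L) {
    if (!is.null(ncrd) && ncrd$end + 1L <= gxy$start - 1L) {
      seg <- substr(protein, ncrd$end + 1L, gxy$start - 1L)
      cls <- classify_linker(seg, config$theta_p, config$theta_sg)$class
      linker_classes <- c(linker_classes, cls)
      add_dom("linker", ncrd$end + 1L, gxy$start - 1L, list(class = cls))
    }
    add_dom("GXY", gxy$start, gxy$end, list(repeat_count = gxy$count))
    if (!is.null(ccrd) && gxy$end + 1L <= ccrd$start - 1L) {
      seg <- substr(protein, gxy$end + 1L, ccrd$start - 1L)
      cls <- classify_linker(seg, config$theta_p, config$theta_sg)$class
      linker_classes <- c(linker_classes, cls)
      linker_after_gxy <- cls
      add_dom("linker", gxy$end + 1L, ccrd$start - 1L, list(class = cls))
    }
  }
  if (!is.null(ccrd)) {
    add_dom("C_CRD", ccrd$start, ccrd$end,
            list(motif = c_crd_label, interrupted = c_crd_interrupted))
  }

  domains <- do.call(rbind, lapply(dom, function(d) {
    data.frame(dtype = d$dtype, start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  }))
  domains$attributes <- I(lapply(dom, `[[`, "attrs"))
  domains <- domains[order(domains$start), , drop = FALSE]
  rownames(domains) <- NULL

  arch <- new_ncol_architecture(seq_id, n, domains,
                                gxy_count = gxy$count,
                                kr_present = kr_present,
                                linker_classes = linker_classes,
                                linker_after_gxy = linker_after_gxy,
                                n_crd = n_crd_label, c_crd = c_crd_label,
                                c_crd_interrupted = c_crd_interrupted)
  classify_ncol(arch, call_threshold = config$call_threshold)
}

empty_domains <- function() {
  d <- data.frame(dtype = character(), start = integer(), end = integer(),
                  stringsAsFactors = FALSE)
  d$attributes <- I(list())
  d
}

new_ncol_architecture <- function(seq_id, length, domains, gxy_count,
                                  kr_present, linker_classes,
                                  linker_after_gxy, n_crd, c_crd,
                                  c_crd_interrupted) {
  structure(list(seq_id = seq_id, length = length, domains = domains,
                 gxy_repeat_count = gxy_count, kr_present = kr_present,
                 linker_classes = linker_classes,
                 linker_after_gxy = linker_after_gxy,
                 n_crd = n_crd, c_crd = c_crd,
                 c_crd_interrupted = c_crd_interrupted,
                 ncol_call = "unclassified", confidence = 0,
                 rule_hits = character()),
            class = "ncol_architecture")
}

#' @export
print.ncol_architecture <- function(x, ...) {
  cat(sprintf(
    "<ncol_architecture> %s (%d aa): %s (conf %.2f), %d GXY repeats\n",
    x$seq_id, x$length, x$ncol_call, x$confidence, x$gxy_repeat_count))
  if (nrow(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      cat(sprintf("  %-10s %4d-%4d\n", x$domains$dtype[i],
                  x$domains$start[i], x$domains$end[i]))
    }
  }
  invisible(x)
}

#' Default Ncol classification rule table
#'
#' One named rule set per class; each rule is a predicate on an
#' architecture. Confidence for a class is the fraction of its rules
#' satisfied. Ncol-1, -2 and -3 are not separated (that distinction is
#' phylogenetic, not architectural) and are reported as one group.
#'
#' @return Named list of rule sets, each a named list of predicate
#'   functions.
#' @export
default_ncol_rules <- function() {
  list(
    "Ncol-5" = list(
      n_crd_canonical = function(a) isTRUE(a$n_crd == "canonical"),
      c_crd_noncanonical = function(a)
        isTRUE(a$c_crd == "noncanonical") && !a$c_crd_interrupted,
      gxy_16_24 = function(a)
        a$gxy_repeat_count >= 16L && a$gxy_repeat_count <= 24L,
      sg_rich_linker = function(a) "SG_rich" %in% a$linker_classes,
      kr_absent = function(a) !a$kr_present
    ),
    "Ncol-4" = list(
      gxy_4_7 = function(a)
        a$gxy_repeat_count >= 4L && a$gxy_repeat_count <= 7L,
      no_polyp_after_gxy = function(a)
        is.na(a$linker_after_gxy) || a$linker_after_gxy != "polyP",
      c_crd_interrupted_by_polyproline = function(a) a$c_crd_interrupted
    ),
    "Ncol-1/2/3-group" = list(
      n_crd_canonical = function(a) isTRUE(a$n_crd == "canonical"),
      c_crd_canonical = function(a)
        isTRUE(a$c_crd == "canonical") && !a$c_crd_interrupted,
      gxy_12_16 = function(a)
        a$gxy_repeat_count >= 12L && a$gxy_repeat_count <= 16L,
      polyp_linker = function(a) "polyP" %in% a$linker_classes
    )
  )
}

#' Heuristic Ncol typing of an architecture
#'
#' Evaluates each class's rules; the call is the class with the highest
#' confidence, provided it reaches \code{call_threshold}, else
#' \code{unclassified}. Ties break in rule-table order.
#'
#' @param arch An \code{ncol_architecture}.
#' @param rules Rule table (see [default_ncol_rules()]).
#' @param call_threshold Minimum confidence for a call (default 0.8).
#' @return The architecture with \code{ncol_call}, \code{confidence} and
#'   \code{rule_hits} filled in.
#' @export
classify_ncol <- function(arch, rules = default_ncol_rules(),
                          call_threshold = 0.8) {
  stopifnot(inherits(arch, "ncol_architecture"))
  conf <- numeric(length(rules))
  hits <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    sat <- vapply(rules[[i]], function(f) isTRUE(f(arch)), logical(1))
    conf[i] <- mean(sat)
    hits[[i]] <- names(rules[[i]])[sat]
  }
  best <- which.max(conf)  # first maximum: rule-table order breaks ties
  if (conf[best] >= call_threshold) {
    arch$ncol_call <- names(rules)[best]
    arch$confidence <- conf[best]
    arch$rule_hits <- hits[[best]]
  } else {
    arch$ncol_call <- "unclassified"
    arch$confidence <- conf[best]
    arch$rule_hits <- character()
  }
  arch
}

#' Scan a set of proteins for minicollagen architectures
#'
#' Runs [build_architecture()] on every record and returns both the
#' per-protein architectures and a summary table.
#'
#' @param proteins [read_fasta()] data frame of protein sequences.
#' @param config An [ncolscan_config()].
#' @param annotations Optional external signal/propeptide annotations
#'   (GFF3-style data frame).
#' @return List with \code{architectures} (named list) and \code{table}
#'   (data frame: seq_id, length, ncol_call, confidence, gxy_repeats,
#'   n_crd, c_crd, kr, linker_classes).
#' @export
scan_proteins <- function(proteins, config = ncolscan_config(),
                          annotations = NULL) {
  archs <- lapply(seq_len(nrow(proteins)), function(i) {
    build_architecture(proteins$seq[i], config = config,
                       seq_id = proteins$id[i], annotations = annotations)
  })
  names(archs) <- proteins$id
  tab <- do.call(rbind, lapply(archs, function(a) {
    data.frame(seq_id = a$seq_id, length = a$length,
               ncol_call = a$ncol_call,
               confidence = round(a$confidence, 3),
               gxy_repeats = a$gxy_repeat_count,
               n_crd = a$n_crd, c_crd = a$c_crd,
               kr = a$kr_present,
               linker_classes = paste(a$linker_classes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(architectures = archs, table = tab)
}

#' Serialize architectures' domains to a GFF3-ready annotation table
#'
#' @param architectures List of \code{ncol_architecture} objects (or the
#'   result of [scan_proteins()]).
#' @return Annotation data frame suitable for [write_gff3()].
#' @export
architecture_annotations <- function(architectures) {
  if (!is.null(architectures$architectures)) {
    architectures <- architectures$architectures
  }
  rows <- lapply(architectures, function(a) {
    if (nrow(a$domains) == 0L) return(NULL)
    data.frame(seqid = a$seq_id, type = a$domains$dtype,
               start = a$domains$start, end = a$domains$end,
               strand = "+", attributes = I(a$domains$attributes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    out$attributes <- I(list())
  }
  rownames(out) <- NULL
  out
}
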