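# Deterministic, seeded fixture generators. Every public generator takes a
# seed, pins the RNG kind explicitly, and restores the caller's RNG state,
# so identical (seed, spec) pairs give byte-identical outputs everywhere.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Synthetic co-infection transcriptome specification
#'
#' States the simulated world: a target transcriptome, contaminant contigs
#' derived from a related sequence pool by substitution-only mutation at a
#' controlled per-base divergence, and host-derived contigs. Defaults
#' mirror the co-infection scenario the filter is built for: ~31\% GC
#' myxozoan-like contigs, 2\% contaminant divergence (a closely related
#' congener), and target noise hits at 15\% divergence.
#'
#' @param seed Integer RNG seed.
#' @param n_target,n_contaminant,n_host Contig counts per class.
#' @param length_range Contig length range (uniform), bp.
#' @param gc GC fraction of generated sequences.
#' @param divergence Per-base substitution rate of contaminant contigs
#'   relative to their source pool sequences.
#' @param noise_identity Identity of optional spurious hits on target
#'   contigs (1 - target divergence).
#' @param noise_coverage Fraction of a target contig covered by its
#'   spurious hit.
#' @return A list of class \code{synth_spec}.
#' @export
synth_spec <- function(seed = 1L, n_target = 10L, n_contaminant = 5L,
                       n_host = 3L, length_range = c(300L, 3000L),
                       gc = 0.31, divergence = 0.02,
                       noise_identity = 0.85, noise_coverage = 1.0) {
  stopifnot(divergence >= 0, divergence <= 1, gc >= 0, gc <= 1,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L],
            noise_identity >= 0, noise_identity <= 1)
  structure(list(seed = as.integer(seed), n_target = as.integer(n_target),
                 n_contaminant = as.integer(n_contaminant),
                 n_host = as.integer(n_host),
                 length_range = as.integer(length_range), gc = gc,
                 divergence = divergence, noise_identity = noise_identity,
                 noise_coverage = noise_coverage),
            class = "synth_spec")
}

random_dna <- function(len, gc) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(prob), len, replace = TRUE, prob = prob),
        collapse = "")
}

mutate_substitutions <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic transcriptome
#'
#' Produces target, contaminant and host contigs plus a truth table. Each
#' contaminant contig is a substitution-only mutant of a source sequence
#' from the target-like pool; the truth table records the exact planted
#' substitution count, so \code{true_identity = 1 - n_subs/length} holds
#' exactly.
#'
#' @param spec A [synth_spec()].
#' @return List with \code{records} (FASTA-ready data frame; headers carry
#'   class and seed) and \code{truth} (data frame: contig_id, class,
#'   source_id, length, n_subs, true_identity).
#' @export
make_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  total <- spec$n_target + spec$n_contaminant + spec$n_host
  if (total == 0L) {
    return(list(records = empty_fasta(),
                truth = data.frame(contig_id = character(),
                                   class = character(),
                                   source_id = character(),
                                   length = integer(), n_subs = integer(),
                                   true_identity = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(spec$seed, {
    rlen <- function(n) {
      sample(seq(spec$length_range[1L], spec$length_range[2L]), n,
             replace = TRUE)
    }
    ids <- character(); seqs <- character(); cls <- character()
    src <- character(); nsub <- integer()

    t_len <- rlen(spec$n_target)
    t_seq <- vapply(t_len, random_dna, character(1), gc = spec$gc)
    if (spec$n_target > 0L) {
      ids <- c(ids, sprintf("target_%03d", seq_len(spec$n_target)))
      seqs <- c(seqs, t_seq)
      cls <- c(cls, rep("target", spec$n_target))
      src <- c(src, rep(NA_character_, spec$n_target))
      nsub <- c(nsub, rep(0L, spec$n_target))
    }
    if (spec$n_contaminant > 0L) {
      # Source pool: fresh sequences statistically like the targets; the
      # contaminant reference the hit table points at.
      s_len <- rlen(spec$n_contaminant)
      for (i in seq_len(spec$n_contaminant)) {
        source_seq <- random_dna(s_len[i], spec$gc)
        ns <- stats::rbinom(1L, s_len[i], spec$divergence)
        ids <- c(ids, sprintf("contam_%03d", i))
        seqs <- c(seqs, mutate_substitutions(source_seq, ns))
        cls <- c(cls, "contaminant")
        src <- c(src, sprintf("contam_ref_%03d", i))
        nsub <- c(nsub, ns)
      }
    }
    if (spec$n_host > 0L) {
      h_len <- rlen(spec$n_host)
      ids <- c(ids, sprintf("host_%03d", seq_len(spec$n_host)))
      seqs <- c(seqs, vapply(h_len, random_dna, character(1), gc = 0.41))
      cls <- c(cls, rep("host", spec$n_host))
      src <- c(src, sprintf("host_scaffold_%03d", seq_len(spec$n_host)))
      nsub <- c(nsub, rep(0L, spec$n_host))
    }
    lens <- nchar(seqs)
    truth <- data.frame(contig_id = ids, class = cls, source_id = src,
                        length = lens, n_subs = nsub,
                        true_identity = 1 - nsub / lens,
                        stringsAsFactors = FALSE)
    records <- data.frame(
      id = ids,
      description = sprintf("%s class=%s seed=%d", ids, cls, spec$seed),
      seq = seqs, stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Emit BLAST-tabular hit tables from a synthetic truth table
#'
#' Stands in for an external BLAST run so the filter is testable offline.
#' Contaminant-derived contigs get one full-length HSP against their
#' source with percent identity equal to the recorded true identity; host
#' contigs get one hit in the host table; target contigs get no hits, or
#' (with \code{target_noise = TRUE}) one partial/noisy HSP at the spec's
#' noise identity and coverage.
#'
#' @param truth Truth table from [make_transcriptome()].
#' @param spec The generating [synth_spec()] (for noise parameters).
#' @param target_noise Add noisy HSPs on target contigs to the
#'   contaminant table.
#' @return List with \code{host} and \code{contaminant} HSP data frames
#'   (12-column BLAST dialect, see [parse_blast_tab()]).
#' @export
emit_hsps <- function(truth, spec = synth_spec(), target_noise = FALSE) {
  mk <- function(qid, sid, pid, qs, qe) {
    alen <- qe - qs + 1L
    data.frame(query_id = qid, subject_id = sid,
               pct_identity = round(pid, 4), aln_len = alen,
               mismatches = as.integer(round((1 - pid / 100) * alen)),
               gap_opens = 0L, q_start = qs, q_end = qe,
               s_start = 1L, s_end = alen, evalue = 0,
               bitscore = round(2 * alen * pid / 100, 1),
               stringsAsFactors = FALSE)
  }
  contam_rows <- list(); host_rows <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$class == "contaminant") {
      contam_rows[[length(contam_rows) + 1L]] <-
        mk(row$contig_id, row$source_id, row$true_identity * 100,
           1L, row$length)
    } else if (row$class == "host") {
      host_rows[[length(host_rows) + 1L]] <-
        mk(row$contig_id, row$source_id, 99.0, 1L,
           min(row$length, 150L))
    } else if (target_noise) {
      qe <- max(1L, as.integer(round(row$length * spec$noise_coverage)))
      contam_rows[[length(contam_rows) + 1L]] <-
        mk(row$contig_id, "noise_ref", spec$noise_identity * 100, 1L, qe)
    }
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else
    empty_hsps()
  list(host = bind(host_rows), contaminant = bind(contam_rows))
}

# ---- minicollagen architecture generator --------------------------------

NEUTRAL_AA <- c("A", "L", "V", "T", "E", "D", "Q", "N", "F", "Y", "H",
                "I", "W")  # no C/G/P/S/K/R/M: keeps planted motifs unique

#' Planted minicollagen parameters
#'
#' One point of the architecture grid: Gly-X-Y repeat count, linker class,
#' KR flag, C-CRD type and optional explicit CRD gap choices.
#'
#' @param gxy Planted Gly-X-Y repeat count (0 = no collagen domain).
#' @param linker_class \code{"SG_rich"}, \code{"polyP"} or \code{"other"}.
#' @param kr Plant a terminal KR dipeptide in the propeptide?
#' @param c_crd \code{"noncanonical"}, \code{"canonical"} or
#'   \code{"interrupted"} (noncanonical split by a polyproline insert).
#' @param n_crd_gaps,c_crd_gaps Optional explicit 5-gap vectors.
#' @param expected_call The Ncol class this parameter set should be typed
#'   as (ground truth for recovery tests).
#' @param name Record id.
#' @return List of class \code{ncol_params}.
#' @export
ncol_params <- function(gxy = 20L, linker_class = "SG_rich", kr = FALSE,
                        c_crd = "noncanonical", n_crd_gaps = NULL,
                        c_crd_gaps = NULL, expected_call = NA_character_,
                        name = "synthetic_ncol") {
  stopifnot(gxy >= 0L,
            linker_class %in% c("SG_rich", "polyP", "other"),
            c_crd %in% c("noncanonical", "canonical", "interrupted"))
  structure(list(gxy = as.integer(gxy), linker_class = linker_class,
                 kr = isTRUE(kr), c_crd = c_crd,
                 n_crd_gaps = n_crd_gaps, c_crd_gaps = c_crd_gaps,
                 expected_call = expected_call, name = name),
            class = "ncol_params")
}

sample_neutral <- function(n) {
  if (n <= 0L) return(character())
  sample(NEUTRAL_AA, n, replace = TRUE)
}

# Serine/glycine linker whose glycines can never seed a Gly-X-Y triplet
# run longer than one triplet, nor extend the planted run across a
# boundary: no two glycines three apart, no G in the final three residues,
# none in the first residue.
sample_sg_linker <- function(n, allow_g = TRUE) {
  chars <- rep("S", n)
  if (allow_g && n > 4L) {
    candidates <- setdiff(2L:(n - 3L), integer(0))
    g_pos <- candidates[stats::runif(length(candidates)) < 0.25]
    if (length(g_pos) > 1L) {
      keep <- g_pos[1L]
      for (p in g_pos[-1L]) {
        if (all(abs(keep - p) != 3L)) keep <- c(keep, p)
      }
      g_pos <- keep
    }
    chars[g_pos] <- "G"
  }
  chars
}

sample_polyp_linker <- function(n) {
  n_p <- max(ceiling(0.5 * n), 1L)
  chars <- c(rep("P", n_p), sample(c("A", "Q", "V"), n - n_p,
                                   replace = TRUE))
  sample(chars)  # shuffle
}

sample_linker <- function(n, class, allow_g = TRUE) {
  switch(class,
         SG_rich = sample_sg_linker(n, allow_g),
         polyP = sample_polyp_linker(n),
         other = sample_neutral(n))
}

crd_from_gaps <- function(gaps) {
  stopifnot(length(gaps) == 5L)
  out <- "C"
  for (g in gaps) {
    out <- c(out, sample_neutral(g), "C")
  }
  out
}

# Independent triplet-run checker used only to *assert* generator truth
# (regex-based, distinct from the scanner's counting loop).
max_gxy_run_regex <- function(seq) {
  best <- 0L
  for (off in 0:2) {
    s <- substr(seq, off + 1L, nchar(seq))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    if (!nzchar(s)) next
    triplets <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    runs <- rle(substr(triplets, 1L, 1L) == "G")
    hit <- runs$lengths[runs$values]
    if (length(hit)) best <- max(best, max(hit))
  }
  best
}

#' Generate one minicollagen protein with a planted architecture
#'
#' Assembles signal + propeptide (with or without terminal KR) + N-CRD +
#' linker + Gly-X-Y domain + linker + C-CRD from residue alphabets chosen
#' so every planted feature is the unique occurrence of its motif, and
#' records every domain span in a truth annotation table.
#'
#' @param params An [ncol_params()].
#' @param seed Integer seed.
#' @return List with \code{record} (1-row FASTA data frame), \code{truth}
#'   (annotation data frame: seqid, type, start, end, attributes) and
#'   \code{params}.
#' @export
make_minicollagen <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ncol_params"))
  with_seed(seed, {
    n_gaps <- params$n_crd_gaps
    if (is.null(n_gaps)) n_gaps <- c(3L, 3L, 3L, 3L, 0L)
    c_gaps <- params$c_crd_gaps
    if (is.null(c_gaps)) {
      c_gaps <- switch(params$c_crd,
                       canonical = c(3L, 3L, 3L, 3L, 0L),
                       c(3L, sample(9:10, 1L), 3L, 3L, 0L))
    }
    pieces <- list(); spans <- list()
    pos <- 0L
    push <- function(type, chars, attrs = list()) {
      if (!length(chars)) return(invisible(NULL))
      pieces[[length(pieces) + 1L]] <<- chars
      spans[[length(spans) + 1L]] <<-
        list(type = type, start = pos + 1L, end = pos + length(chars),
             attrs = attrs)
      pos <<- pos + length(chars)
      invisible(NULL)
    }

    push("signal", c("M", sample(c("L", "V", "A", "F", "I", "W", "T"),
                                 sample(14:19, 1L), replace = TRUE)))
    prop_len <- sample(6:12, 1L)
    prop <- sample_neutral(prop_len)
    if (params$kr) prop[(prop_len - 1L):prop_len] <- c("K", "R")
    push("propeptide", prop, list(kr = params$kr))
    push("N_CRD", crd_from_gaps(n_gaps),
         list(motif = "canonical", gaps = paste(n_gaps, collapse = ",")))

    allow_g <- params$gxy > 0L
    if (params$gxy > 0L) {
      push("linker", sample_linker(sample(8:15, 1L), params$linker_class,
                                   allow_g),
           list(class = params$linker_class))
      xy <- c("P", "A", "Q", "E", "K", "S")
      gxy_chars <- as.vector(vapply(seq_len(params$gxy), function(i) {
        c("G", sample(xy, 2L, replace = TRUE))
      }, character(3)))
      push("GXY", gxy_chars, list(repeat_count = params$gxy))
      push("linker", sample_linker(sample(8:15, 1L), params$linker_class,
                                   allow_g),
           list(class = params$linker_class))
    } else {
      # keep the two CRDs apart so no bridging cysteine window can form
      push("spacer", sample_neutral(8L))
    }

    if (params$c_crd == "interrupted") {
      # noncanonical gaps with a polyproline insert inside the C4-C5 gap
      insert_len <- sample(7:10, 1L)
      gaps_seq <- list()
      for (k in seq_len(5L)) {
        g <- sample_neutral(c_gaps[k])
        if (k == 4L) {
          g <- c(g[seq_len(min(2L, length(g)))], rep("P", insert_len),
                 g[-seq_len(min(2L, length(g)))])
        }
        gaps_seq[[k]] <- g
      }
      chars <- "C"
      for (k in seq_len(5L)) chars <- c(chars, gaps_seq[[k]], "C")
      push("C_CRD", chars,
           list(motif = "noncanonical", interrupted = TRUE,
                gaps = paste(c_gaps, collapse = ",")))
    } else {
      push("C_CRD", crd_from_gaps(c_gaps),
           list(motif = if (params$c_crd == "canonical") "canonical"
                else "noncanonical",
                interrupted = FALSE,
                gaps = paste(c_gaps, collapse = ",")))
    }
    push("tail", sample_neutral(sample(0:3, 1L)))

    seq <- paste(unlist(pieces), collapse = "")
    gxy_span <- Filter(function(s) s$type == "GXY", spans)
    run <- max_gxy_run_regex(seq)
    if (params$gxy > 0L && run != params$gxy) {
      stop("generator invariant violated: planted ", params$gxy,
           " Gly-X-Y repeats but longest run is ", run, call. = FALSE)
    }
    if (params$gxy == 0L && run != 0L) {
      stop("generator invariant violated: stray Gly-X-Y triplet",
           call. = FALSE)
    }

    keep <- Filter(function(s) !s$type %in% c("tail", "spacer"), spans)
    truth <- do.call(rbind, lapply(keep, function(s) {
      data.frame(seqid = params$name, type = s$type, start = s$start,
                 end = s$end, stringsAsFactors = FALSE)
    }))
    truth$attributes <- I(lapply(keep, `[[`, "attrs"))
    record <- data.frame(
      id = params$name,
      description = sprintf("%s planted=%s gxy=%d seed=%d", params$name,
                            params$c_crd, params$gxy, seed),
      seq = seq, stringsAsFactors = FALSE)
    list(record = record, truth = truth, params = params)
  })
}

#' Default planted architecture grid
#'
#' A factorial grid across the four target classes: Ncol-5-like (16-24
#' repeats, SG-rich linkers, noncanonical C-CRD, no KR), Ncol-4-like (4-7
#' repeats, interrupted C-CRD), canonical Ncol-1/2/3-group-like (12-16
#' repeats, polyproline linkers, KR), and out-of-rule architectures (8-11
#' repeats) expected to stay unclassified. Gap variants stay within the
#' scanner's default +-1 tolerance.
#'
#' @param n_replicates Replicates of the base grid (distinct seeds).
#' @return List of [ncol_params()] objects, >= 200 at the default.
#' @export
default_architecture_grid <- function(n_replicates = 3L) {
  variant_gaps <- list(c(3L, 3L, 3L, 3L, 0L),
                       c(2L, 3L, 4L, 3L, 0L),
                       c(4L, 3L, 2L, 4L, 0L))
  grid <- list()
  add <- function(p) grid[[length(grid) + 1L]] <<- p
  for (rep_i in seq_len(n_replicates)) {
    for (v in seq_along(variant_gaps)) {
      for (g in 16:24) {
        add(ncol_params(gxy = g, linker_class = "SG_rich", kr = FALSE,
                        c_crd = "noncanonical",
                        n_crd_gaps = variant_gaps[[v]],
                        expected_call = "Ncol-5",
                        name = sprintf("ncol5_g%02d_v%d_r%d", g, v, rep_i)))
      }
      for (g in 4:7) {
        for (kr in c(FALSE, TRUE)) {
          add(ncol_params(gxy = g, linker_class = "SG_rich", kr = kr,
                          c_crd = "interrupted",
                          n_crd_gaps = variant_gaps[[v]],
                          expected_call = "Ncol-4",
                          name = sprintf("ncol4_g%02d_kr%d_v%d_r%d", g, kr,
                                         v, rep_i)))
        }
      }
      for (g in 12:16) {
        add(ncol_params(gxy = g, linker_class = "polyP", kr = TRUE,
                        c_crd = "canonical",
                        n_crd_gaps = variant_gaps[[v]],
                        expected_call = "Ncol-1/2/3-group",
                        name = sprintf("ncol123_g%02d_v%d_r%d", g, v,
                                       rep_i)))
      }
      for (g in 8:11) {
        add(ncol_params(gxy = g, linker_class = "polyP", kr = TRUE,
                        c_crd = "canonical",
                        n_crd_gaps = variant_gaps[[v]],
                        expected_call = "unclassified",
                        name = sprintf("offgrid_g%02d_v%d_r%d", g, v,
                                       rep_i)))
      }
    }
  }
  grid
}

#' Generate a set of planted minicollagens
#'
#' @param params_list List of [ncol_params()] (e.g.
#'   [default_architecture_grid()]).
#' @param seed Base seed; record i uses \code{seed + i}.
#' @return List with \code{records} (FASTA data frame), \code{truth}
#'   (stacked annotation data frame) and \code{params_list}.
#' @export
make_minicollagen_set <- function(params_list, seed = 1L) {
  out <- lapply(seq_along(params_list), function(i) {
    make_minicollagen(params_list[[i]], seed = seed + i)
  })
  records <- do.call(rbind, lapply(out, `[[`, "record"))
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(records) <- rownames(truth) <- NULL
  list(records = records, truth = truth, params_list = params_list)
}

#' Generate a genomic/transcript pair with planted introns, plus loci
#'
#' The genomic sequence is the transcript with intron blocks inserted
#' after stated transcript positions; each block is
#' \code{GT + random + AG} (or the stated donor/acceptor). Also emits a
#' two-gene locus table at a planted intergenic distance and strand pair,
#' serving the cluster-geometry module.
#'
#' @param transcript_len Transcript length, bp.
#' @param introns Data frame (or list of lists) with \code{after}
#'   (transcript position after which the block inserts) and \code{length}
#'   (>= 4); may be empty.
#' @param igr Planted intergenic distance between the two loci, bp.
#' @param strands Length-2 strand vector for the loci.
#' @param donor_acceptor 4-character splice boundary, default "GTAG".
#' @param gc GC fraction of the transcript.
#' @param seed Integer seed.
#' @return List with \code{transcript}, \code{genomic} (1-row FASTA data
#'   frames), \code{introns_truth} (after, length, genomic_start,
#'   genomic_end) and \code{loci} ([gene_loci()] table).
#' @export
make_gene_fixture <- function(transcript_len = 400L,
                              introns = data.frame(after = c(120L, 260L),
                                                   length = c(32L, 40L)),
                              igr = 250L, strands = c("+", "-"),
                              donor_acceptor = "GTAG", gc = 0.31,
                              seed = 1L) {
  if (is.list(introns) && !is.data.frame(introns)) {
    introns <- do.call(rbind, lapply(introns, as.data.frame))
  }
  stopifnot(nchar(donor_acceptor) == 4L)
  if (nrow(introns)) {
    stopifnot(all(introns$length >= 4L),
              all(introns$after >= 0L),
              all(introns$after <= transcript_len),
              !anyDuplicated(introns$after))
    introns <- introns[order(introns$after), , drop = FALSE]
  }
  with_seed(seed, {
    transcript <- random_dna(transcript_len, gc)
    genomic <- transcript
    shift <- 0L
    g_start <- integer(nrow(introns)); g_end <- integer(nrow(introns))
    for (i in seq_len(nrow(introns))) {
      block <- paste0(substr(donor_acceptor, 1L, 2L),
                      random_dna(introns$length[i] - 4L, gc),
                      substr(donor_acceptor, 3L, 4L))
      at <- introns$after[i] + shift
      genomic <- paste0(substr(genomic, 1L, at), block,
                        substr(genomic, at + 1L, nchar(genomic)))
      g_start[i] <- at + 1L
      g_end[i] <- at + introns$length[i]
      shift <- shift + introns$length[i]
    }
    gene1_len <- sample(600:1500, 1L)
    gene2_len <- sample(600:1500, 1L)
    g1_start <- 101L
    g1_end <- g1_start + gene1_len - 1L
    g2_start <- g1_end + igr + 1L
    loci <- gene_loci(scaffold = c("scaffold_1", "scaffold_1"),
                      start = c(g1_start, g2_start),
                      end = c(g1_end, g2_start + gene2_len - 1L),
                      strand = strands, name = c("Ncol-1", "Ncol-4"))
    list(transcript = data.frame(id = "transcript_1",
                                 description = sprintf(
                                   "transcript_1 seed=%d", seed),
                                 seq = transcript,
                                 stringsAsFactors = FALSE),
         genomic = data.frame(id = "genomic_1",
                              description = sprintf("genomic_1 seed=%d",
                                                    seed),
                              seq = genomic, stringsAsFactors = FALSE),
         introns_truth = data.frame(after = introns$after,
                                    length = introns$length,
                                    genomic_start = g_start,
                                    genomic_end = g_end,
                                    stringsAsFactors = FALSE),
         loci = loci)
  })
}
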