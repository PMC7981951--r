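test_that("make_transcriptome: labels, exact truth identities, determinism", {
  sp <- synth_spec(seed = 1, n_target = 10L, n_contaminant = 5L,
                   n_host = 2L, divergence = 0.02)
  tr <- make_transcriptome(sp)
  expect_equal(nrow(tr$records), 17L)
  expect_equal(sum(tr$truth$class == "contaminant"), 5L)
  expect_equal(tr$truth$true_identity,
               1 - tr$truth$n_subs / tr$truth$length)
  contam <- tr$truth[tr$truth$class == "contaminant", ]
  expect_true(all(abs(contam$true_identity - 0.98) < 0.05))

  # byte-identical reruns under the same seed
  tr2 <- make_transcriptome(sp)
  expect_identical(tr, tr2)
  f1 <- tmpfile(".fa"); f2 <- tmpfile(".fa")
  write_fasta(tr$records, f1); write_fasta(tr2$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  # divergence 0 means identical to source
  tr0 <- make_transcriptome(synth_spec(seed = 3, n_contaminant = 4L,
                                       divergence = 0))
  expect_true(all(tr0$truth$true_identity[
    tr0$truth$class == "contaminant"] == 1))

  # empty spec
  e <- make_transcriptome(synth_spec(n_target = 0L, n_contaminant = 0L,
                                     n_host = 0L))
  expect_equal(nrow(e$records), 0L)
})

test_that("emit_hsps mirrors the truth table", {
  sp <- synth_spec(seed = 4, n_target = 6L, n_contaminant = 4L, n_host = 3L)
  tr <- make_transcriptome(sp)
  hits <- emit_hsps(tr$truth, sp)
  expect_equal(nrow(hits$contaminant), 4L)
  expect_equal(nrow(hits$host), 3L)
  contam <- tr$truth[tr$truth$class == "contaminant", ]
  m <- match(contam$contig_id, hits$contaminant$query_id)
  expect_equal(hits$contaminant$pct_identity[m],
               round(contam$true_identity * 100, 4))
  expect_equal(hits$contaminant$q_start[m], rep(1L, 4L))
  expect_equal(hits$contaminant$q_end[m], contam$length)
  # target contigs get no hits unless noise is requested
  expect_false(any(grepl("^target", hits$contaminant$query_id)))
  noisy <- emit_hsps(tr$truth, sp, target_noise = TRUE)
  expect_equal(sum(grepl("^target", noisy$contaminant$query_id)), 6L)
  # noise spec example: 50 bp at 80% on a 1000 bp contig scores 0.04
  truth1 <- data.frame(contig_id = "t1", class = "target",
                       source_id = NA, length = 1000L, n_subs = 0L,
                       true_identity = 1, stringsAsFactors = FALSE)
  sp_noise <- synth_spec(noise_identity = 0.80, noise_coverage = 0.05)
  h <- emit_hsps(truth1, sp_noise, target_noise = TRUE)$contaminant
  prof <- merge_hsps(h, 1000L)
  expect_equal(prof$similarity_score, 0.04)
})

test_that("minicollagen generator honours planted parameters", {
  # gxy = 0: no GXY domain in truth, scanner counts zero
  m0 <- make_minicollagen(ncol_params(gxy = 0L, name = "flat"), seed = 6)
  expect_false("GXY" %in% m0$truth$type)
  expect_equal(count_gxy(m0$record$seq)$count, 0L)

  m <- make_minicollagen(ncol_params(gxy = 17L, kr = TRUE, name = "k"),
                         seed = 7)
  pro <- m$truth[m$truth$type == "propeptide", ]
  expect_equal(substr(m$record$seq, pro$end - 1L, pro$end), "KR")
  expect_identical(make_minicollagen(ncol_params(gxy = 17L, kr = TRUE,
                                                 name = "k"), seed = 7),
                   m)

  # truth spans tile the sequence without overlap
  expect_true(all(m$truth$start <= m$truth$end))
  o <- order(m$truth$start)
  expect_true(all(diff(m$truth$start[o]) > 0))
})

test_that("gene fixture plants introns and locus geometry exactly", {
  gf <- make_gene_fixture(transcript_len = 300L,
                          introns = data.frame(after = 100L, length = 32L),
                          igr = 250L, strands = c("+", "-"), seed = 10)
  expect_equal(nchar(gf$genomic$seq), 332L)
  it <- gf$introns_truth
  expect_equal(substr(gf$genomic$seq, it$genomic_start,
                      it$genomic_start + 1L), "GT")
  expect_equal(substr(gf$genomic$seq, it$genomic_end - 1L,
                      it$genomic_end), "AG")
  expect_equal(igr_length(gf$loci[1, ], gf$loci[2, ]), 250L)
  expect_equal(orientation(gf$loci[1, ], gf$loci[2, ]), "tail_to_tail")

  # no introns -> genomic == transcript, empty truth
  gf0 <- make_gene_fixture(introns = data.frame(after = integer(),
                                                length = integer()),
                           seed = 11)
  expect_identical(gf0$genomic$seq, gf0$transcript$seq)
  expect_equal(nrow(gf0$introns_truth), 0L)
})

test_that("generator rejects impossible plantings", {
  expect_error(make_gene_fixture(introns = data.frame(after = 10L,
                                                      length = 3L)))
  expect_error(ncol_params(linker_class = "weird"))
})
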