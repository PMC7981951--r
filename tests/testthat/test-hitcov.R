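mk_hsp <- function(qid, qs, qe, pid, sid = "s1") {
  data.frame(query_id = qid, subject_id = sid, pct_identity = pid,
             aln_len = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
             q_start = qs, q_end = qe, s_start = 1L, s_end = qe - qs + 1L,
             evalue = 1e-50, bitscore = 100, stringsAsFactors = FALSE)
}

test_that("merge_hsps: empty, full and overlapping cases", {
  p0 <- merge_hsps(empty_hsps_df(), 200L, contig_id = "c0")
  expect_equal(p0$similarity_score, 0)
  expect_equal(nrow(p0$segments), 0L)

  p1 <- merge_hsps(mk_hsp("c1", 1L, 200L, 100), 200L)
  expect_equal(p1$similarity_score, 1.0)

  h <- rbind(mk_hsp("c2", 1L, 100L, 95.0), mk_hsp("c2", 51L, 150L, 85.0))
  p2 <- merge_hsps(h, 200L)
  expect_equal(p2$similarity_score, 0.6875)
  # per-base max: bases 1-100 at 0.95, 101-150 at 0.85
  expect_equal(p2$segments$start0, c(0L, 100L))
  expect_equal(p2$segments$end0, c(100L, 150L))
  expect_equal(p2$segments$best_identity, c(0.95, 0.85))
})

test_that("merge_hsps error contract", {
  h <- rbind(mk_hsp("a", 1L, 10L, 90), mk_hsp("b", 1L, 10L, 90))
  expect_error(merge_hsps(h, 100L), "multiple contigs")
  expect_error(merge_hsps(mk_hsp("a", 1L, 300L, 90), 200L),
               "beyond contig length")
})

test_that("merged profile equals brute-force per-base oracle (property)", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(50:2000, 1L)
    h <- random_hsps("c", len, sample(0:20, 1L))
    h <- h[h$q_end <= len, , drop = FALSE]
    prof <- merge_hsps(h, len, contig_id = "c")
    expect_equal(prof$similarity_score, oracle_similarity_score(h, len),
                 tolerance = 1e-12)
    # segments disjoint, sorted, in range
    if (nrow(prof$segments) > 1L) {
      expect_true(all(diff(prof$segments$start0) > 0))
      expect_true(all(prof$segments$start0[-1L] >=
                        prof$segments$end0[-nrow(prof$segments)]))
    }
    expect_true(all(prof$segments$end0 <= len))
  }
})

test_that("merging is order-independent and idempotent", {
  set.seed(11)
  for (rep in 1:25) {
    len <- 1000L
    h <- random_hsps("c", len, 12L)
    h <- h[h$q_end <= len, , drop = FALSE]
    p1 <- merge_hsps(h, len, contig_id = "c")
    p2 <- merge_hsps(h[sample.int(nrow(h)), , drop = FALSE], len,
                     contig_id = "c")
    expect_equal(p1$segments, p2$segments, ignore_attr = TRUE)
    expect_equal(p1$similarity_score, p2$similarity_score)
  }
})

test_that("filter_contigs policies and threshold boundary", {
  lens <- c(a = 100L, b = 100L, c = 100L)
  # a scores 0.92, b exactly 0.90, c no hits
  hits <- rbind(mk_hsp("a", 1L, 100L, 92), mk_hsp("b", 1L, 100L, 90))
  res <- filter_contigs(lens, hits, policy = "similarity_threshold",
                        threshold = 0.90)
  expect_setequal(res$removed, "a")
  expect_setequal(res$kept, c("b", "c"))
  expect_equal(nrow(res$decisions), 3L)
  expect_equal(res$decisions$score[res$decisions$contig_id == "c"], 0)

  # any_hit: identity is irrelevant
  low <- mk_hsp("a", 1L, 10L, 40)
  res2 <- filter_contigs(lens, low, policy = "any_hit")
  expect_setequal(res2$removed, "a")
  expect_setequal(res2$kept, c("b", "c"))

  expect_error(filter_contigs(lens, mk_hsp("zz", 1L, 10L, 90), "any_hit"),
               "zz")
})

test_that("coverage_only mode counts covered bases above the floor", {
  lens <- c(a = 200L)
  hits <- rbind(mk_hsp("a", 1L, 100L, 95), mk_hsp("a", 101L, 160L, 50))
  res <- filter_contigs(lens, hits, policy = "similarity_threshold",
                        threshold = 0.4, mode = "coverage_only",
                        coverage_floor = 0.90)
  expect_equal(res$decisions$score, 100 / 200)
})

test_that("threshold monotonicity and kept/removed partition (property)", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(5:25, 1L)
    lens <- stats::setNames(sample(100:500, n, replace = TRUE),
                            sprintf("c%02d", seq_len(n)))
    hits <- do.call(rbind, lapply(names(lens), function(id) {
      k <- sample(0:5, 1L)
      if (k == 0L) return(NULL)
      h <- random_hsps(id, lens[[id]], k)
      h[h$q_end <= lens[[id]], , drop = FALSE]
    }))
    if (is.null(hits)) hits <- empty_hsps_df()
    th <- sort(stats::runif(2))
    r1 <- filter_contigs(lens, hits, "similarity_threshold", th[1L])
    r2 <- filter_contigs(lens, hits, "similarity_threshold", th[2L])
    expect_true(all(r2$removed %in% r1$removed))
    expect_setequal(c(r1$kept, r1$removed), names(lens))
    expect_length(intersect(r1$kept, r1$removed), 0L)
  }
})

test_that("two_stage_clean applies host precedence and partitions counts", {
  lens <- stats::setNames(rep(100L, 10L), sprintf("c%02d", 1:10))
  host_hits <- rbind(mk_hsp("c01", 1L, 50L, 99), mk_hsp("c02", 1L, 50L, 80))
  contam_hits <- rbind(mk_hsp("c03", 1L, 100L, 95),
                       mk_hsp("c04", 1L, 100L, 91),
                       mk_hsp("c05", 1L, 100L, 50),
                       mk_hsp("c01", 1L, 100L, 99))  # host wins
  rep <- two_stage_clean(lens, host_hits, contam_hits, threshold = 0.90)
  expect_setequal(rep$removed_host, c("c01", "c02"))
  expect_setequal(rep$removed_contaminant, c("c03", "c04"))
  expect_equal(rep$counts[["kept"]], 6L)
  expect_equal(sum(rep$counts[c("kept", "host_removed",
                                "contaminant_removed")]),
               rep$counts[["input"]])
  expect_equal(rep$decisions$stage[rep$decisions$contig_id == "c01"],
               "host")

  # empty hit tables keep everything
  rep0 <- two_stage_clean(lens, empty_hsps_df(), empty_hsps_df())
  expect_length(rep0$kept, 10L)
})
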