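test_that("extract_crd_queries cuts annotated spans and skips bare proteins", {
  proteins <- data.frame(id = c("p1", "p2"),
                         description = c("p1", "p2"),
                         seq = c(strrep("A", 120), strrep("L", 80)),
                         stringsAsFactors = FALSE)
  ann <- data.frame(seqid = "p1", type = c("N_CRD", "C_CRD"),
                    start = c(5L, 80L), end = c(22L, 100L),
                    group = "Ncol-5", stringsAsFactors = FALSE)
  expect_warning(qs <- extract_crd_queries(proteins, ann), "p2")
  expect_equal(nrow(qs), 2L)
  expect_equal(nchar(qs$seq), c(18L, 21L))
  expect_equal(qs$query_id, c("p1|Ncol-5|N_CRD", "p1|Ncol-5|C_CRD"))
  expect_false(anyDuplicated(qs$query_id) > 0)
})

test_that("query ids stay unique across many proteins", {
  proteins <- data.frame(id = sprintf("p%d", 1:3),
                         description = sprintf("p%d", 1:3),
                         seq = rep(strrep("A", 150), 3L),
                         stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(seqid = sprintf("p%d", i), type = c("N_CRD", "C_CRD"),
               start = c(10L, 100L), end = c(30L, 130L), group = "Ncol-4",
               stringsAsFactors = FALSE)
  }))
  qs <- extract_crd_queries(proteins, ann)
  expect_equal(nrow(qs), 6L)
  expect_equal(anyDuplicated(qs$query_id), 0L)
})

test_that("filter_hits_evalue: boundary inclusive, subset, idempotent", {
  h <- random_hsps("q", 500L, 10L)
  h$evalue <- c(1e-6, 1e-4, 1e-5, 1, 1e-10, 1e-3, 1e-7, 1e-20, 0.5, 1e-5)
  kept <- filter_hits_evalue(h, cutoff = 1e-5)
  expect_true(all(kept$evalue <= 1e-5))
  expect_equal(nrow(kept), 6L)  # 1e-6, 1e-5, 1e-10, 1e-7, 1e-20, 1e-5
  expect_identical(filter_hits_evalue(kept, 1e-5), kept)
  expect_true(all(rownames(kept) %in% rownames(h)))
  # complement
  expect_equal(nrow(subthreshold_hits(h, 1e-5)) + nrow(kept), nrow(h))
})

test_that("reciprocal_check confirms symmetric best pairs only", {
  mk <- function(q, s, bits, ev = 1e-20) {
    data.frame(query_id = q, subject_id = s, pct_identity = 90,
               aln_len = 100L, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
               evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
  }
  fwd <- rbind(mk("q1", "s1", 200), mk("q1", "s2", 150),
               mk("q2", "s2", 180))
  rev <- rbind(mk("s1", "q1", 210), mk("s2", "q2", 170),
               mk("s2", "q1", 100))
  conf <- reciprocal_check(fwd, rev)
  expect_equal(conf$query_id, c("q1", "q2"))
  expect_equal(conf$subject_id, c("s1", "s2"))

  # asymmetry: q1's best is s1 but s1's best is q2
  rev2 <- mk("s1", "q2", 300)
  conf2 <- reciprocal_check(mk("q1", "s1", 200), rev2)
  expect_equal(nrow(conf2), 0L)

  # empty forward table
  expect_equal(nrow(reciprocal_check(fwd[0, ], rev)), 0L)
})

test_that("reciprocal confirmation is symmetric under table swap", {
  set.seed(404)
  ids_a <- sprintf("a%d", 1:6); ids_b <- sprintf("b%d", 1:6)
  mk_tab <- function(from, to) {
    do.call(rbind, lapply(from, function(q) {
      n <- sample(1:4, 1L)
      data.frame(query_id = q, subject_id = sample(to, n),
                 pct_identity = 90, aln_len = 100L, mismatches = 0L,
                 gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
                 s_end = 100L, evalue = 10^-sample(5:40, n, replace = TRUE),
                 bitscore = sample(50:400, n), stringsAsFactors = FALSE)
    }))
  }
  for (rep in 1:20) {
    fwd <- mk_tab(ids_a, ids_b); rev <- mk_tab(ids_b, ids_a)
    c1 <- reciprocal_check(fwd, rev)
    c2 <- reciprocal_check(rev, fwd)
    expect_setequal(paste(c1$query_id, c1$subject_id),
                    paste(c2$subject_id, c2$query_id))
  }
})

test_that("tie-breaking is deterministic: bitscore, evalue, subject id", {
  mk <- function(q, s, bits, ev) {
    data.frame(query_id = q, subject_id = s, pct_identity = 90,
               aln_len = 100L, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
               evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
  }
  fwd <- rbind(mk("q", "sB", 100, 1e-10), mk("q", "sA", 100, 1e-10),
               mk("q", "sC", 100, 1e-12))
  rev <- rbind(mk("sC", "q", 50, 1e-5))
  # sC wins on evalue despite equal bitscore
  conf <- reciprocal_check(fwd, rev)
  expect_equal(conf$subject_id, "sC")
})
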