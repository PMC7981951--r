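test_that("find_crd matches constructed canonical and noncanonical CRDs", {
  m <- find_crd("CAAACAAACAAACAAACC", canonical_crd(), tolerance = 0)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 18L)
  expect_equal(m$gaps[[1L]], c(3L, 3L, 3L, 3L, 0L))

  # 9-residue C2-C3 spacing of the noncanonical C-terminal CRD
  seq9 <- paste0("CAAAC", strrep("A", 9), "CAAACAAACC")
  m2 <- find_crd(seq9, noncanonical_c_crd(), tolerance = 0)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$gaps[[1L]][2L], 9L)

  # five cysteines cannot match
  expect_equal(nrow(find_crd("CAAACAAACAAACC", canonical_crd(), 0)), 0L)
  expect_error(find_crd("CC", crd_motif(list(c(1, 2)), "x")), "5 gap")
})

test_that("find_crd equals the regex enumeration oracle (property)", {
  set.seed(505)
  motifs <- list(canonical_crd(), noncanonical_c_crd())
  for (rep in 1:150) {
    # C-enriched alphabet so 6-cysteine windows actually occur
    prot <- random_protein(sample(40:300, 1L),
                           alphabet = c("A", "C", "C", "G", "P", "S", "L"))
    motif <- motifs[[sample(2L, 1L)]]
    tol <- sample(0:2, 1L)
    got <- find_crd(prot, motif, tolerance = tol)
    want <- oracle_find_crd_starts(prot, motif$gap_ranges, tol)
    expect_identical(got$start, want,
                     label = paste("seq", prot, "tol", tol, motif$label))
  }
})

test_that("count_gxy worked examples and brute-force equivalence", {
  r <- count_gxy("GPPGPQGAPGQA")
  expect_equal(r$count, 4L)
  expect_equal(c(r$start, r$end), c(1L, 12L))
  expect_equal(count_gxy("AAAA")$count, 0L)
  expect_equal(count_gxy("GPPAPPGPP")$count, 1L)
  # trailing partial triplet not counted
  expect_equal(count_gxy("GPPGP")$count, 1L)

  set.seed(606)
  for (rep in 1:300) {
    prot <- random_protein(sample(3:120, 1L),
                           alphabet = c("G", "P", "A", "S", "G"))
    expect_identical(count_gxy(prot)$count, oracle_count_gxy(prot),
                     label = prot)
  }
})

test_that("count_gxy with one tolerated broken triplet", {
  # G.. G.. X.. G.. G..  -> strict: 2; max_gaps = 1: 4 counted G-triplets
  s <- "GPPGPPAPPGPPGPP"
  expect_equal(count_gxy(s)$count, 2L)
  expect_equal(count_gxy(s, max_gaps = 1L)$count, 4L)
})

test_that("classify_linker thresholds", {
  expect_equal(classify_linker("PPQPPAPPSP")$class, "polyP")
  expect_equal(classify_linker("SGSGSGGSSG")$class, "SG_rich")
  expect_equal(classify_linker("ALKVMNDE")$class, "other")
  # polyP precedence at exactly the default thresholds
  expect_equal(classify_linker("PPPSSSSSGG")$class, "polyP")  # P=0.3
  expect_equal(classify_linker("SSSSSAAAAA")$class, "SG_rich")  # SG=0.5
  expect_error(classify_linker(""), "empty")
  comp <- classify_linker("PPAA")$composition
  expect_equal(unname(comp[c("A", "P")]), c(0.5, 0.5))
})

test_that("detect_kr is positional by default", {
  expect_true(detect_kr("MASFVKR"))
  expect_false(detect_kr("MASFVKA"))
  expect_false(detect_kr("KRAAAA"))
  expect_true(detect_kr("KRAAAA", where = "anywhere"))
  expect_warning(expect_false(detect_kr("K")), "shorter")
})

test_that("build_architecture recovers a planted Ncol-5 exactly", {
  params <- ncol_params(gxy = 20L, linker_class = "SG_rich", kr = FALSE,
                        c_crd = "noncanonical", name = "n5")
  m <- make_minicollagen(params, seed = 99)
  arch <- build_architecture(m$record$seq, seq_id = "n5")
  truth <- m$truth
  expect_equal(arch$ncol_call, "Ncol-5")
  expect_equal(arch$gxy_repeat_count, 20L)
  expect_false(arch$kr_present)
  for (ty in c("N_CRD", "GXY", "C_CRD")) {
    got <- arch$domains[arch$domains$dtype == ty, ]
    want <- truth[truth$type == ty, ]
    expect_equal(got$start, want$start, label = ty)
    expect_equal(got$end, want$end, label = ty)
  }
  # linkers recovered at planted spans too
  expect_equal(arch$domains$start[arch$domains$dtype == "linker"],
               truth$start[truth$type == "linker"])
  expect_equal(arch$linker_classes, c("SG_rich", "SG_rich"))
})

test_that("degenerate inputs are unclassified or rejected", {
  expect_error(build_architecture(strrep("A", 10)), "shorter than 30")
  arch <- build_architecture(random_protein(200, alphabet = c("A", "L",
                                                              "V", "T")),
                             seq_id = "rand")
  expect_equal(arch$ncol_call, "unclassified")
  expect_equal(nrow(arch$domains), 0L)
  expect_lt(arch$confidence, 0.8)
})

test_that("interrupted C-CRD is flagged and drives the Ncol-4 rule", {
  params <- ncol_params(gxy = 4L, linker_class = "SG_rich", kr = FALSE,
                        c_crd = "interrupted", name = "n4")
  m <- make_minicollagen(params, seed = 17)
  arch <- build_architecture(m$record$seq, seq_id = "n4")
  expect_equal(arch$gxy_repeat_count, 4L)
  expect_true(arch$c_crd_interrupted)
  expect_equal(arch$ncol_call, "Ncol-4")
  expect_true("c_crd_interrupted_by_polyproline" %in% arch$rule_hits)
})

test_that("classification rules place each planted class correctly", {
  cases <- list(
    list(p = ncol_params(gxy = 16L, c_crd = "noncanonical",
                         linker_class = "SG_rich", kr = FALSE,
                         name = "a"), want = "Ncol-5"),
    list(p = ncol_params(gxy = 24L, c_crd = "noncanonical",
                         linker_class = "SG_rich", kr = FALSE,
                         name = "b"), want = "Ncol-5"),
    list(p = ncol_params(gxy = 5L, c_crd = "interrupted",
                         linker_class = "SG_rich", kr = FALSE,
                         name = "c"), want = "Ncol-4"),
    list(p = ncol_params(gxy = 14L, c_crd = "canonical",
                         linker_class = "polyP", kr = TRUE,
                         name = "d"), want = "Ncol-1/2/3-group"),
    list(p = ncol_params(gxy = 9L, c_crd = "canonical",
                         linker_class = "polyP", kr = TRUE,
                         name = "e"), want = "unclassified"))
  for (i in seq_along(cases)) {
    m <- make_minicollagen(cases[[i]]$p, seed = 1000L + i)
    arch <- build_architecture(m$record$seq, seq_id = cases[[i]]$p$name)
    expect_equal(arch$ncol_call, cases[[i]]$want,
                 label = cases[[i]]$p$name)
  }
})

test_that("scanning is position-stable under a non-matching prefix", {
  params <- ncol_params(gxy = 18L, name = "shift")
  m <- make_minicollagen(params, seed = 55)
  prefix <- strrep("L", 37)
  shifted <- paste0(prefix, m$record$seq)
  a1 <- build_architecture(m$record$seq, seq_id = "shift")
  a2 <- build_architecture(shifted, seq_id = "shift")
  d1 <- a1$domains[a1$domains$dtype %in% c("N_CRD", "GXY", "C_CRD"), ]
  d2 <- a2$domains[a2$domains$dtype %in% c("N_CRD", "GXY", "C_CRD"), ]
  expect_equal(d2$start, d1$start + 37L)
  expect_equal(d2$end, d1$end + 37L)
  expect_equal(a2$ncol_call, a1$ncol_call)
})

test_that("signal/propeptide annotations reshape the propeptide span", {
  params <- ncol_params(gxy = 20L, kr = TRUE, c_crd = "noncanonical",
                        name = "annotated")
  m <- make_minicollagen(params, seed = 77)
  sig <- m$truth[m$truth$type == "signal", ]
  ann <- data.frame(seqid = "annotated", type = "signal",
                    start = sig$start, end = sig$end,
                    stringsAsFactors = FALSE)
  arch <- build_architecture(m$record$seq, seq_id = "annotated",
                             annotations = ann)
  pro <- arch$domains[arch$domains$dtype == "propeptide", ]
  expect_equal(pro$start, sig$end + 1L)
  expect_true(arch$kr_present)
})
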