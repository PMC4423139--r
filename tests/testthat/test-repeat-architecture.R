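test_that("find_cores locates exact and near-exact cores", {
  res <- find_cores("CCDPCQKPCCDPCQQSV", max_mismatch = 0)
  expect_equal(res$start, c(0L, 8L))
  expect_equal(res$mismatches, c(0L, 0L))

  res1 <- find_cores("CCDPCEKP", max_mismatch = 1)
  expect_equal(res1$start, 0L)
  expect_equal(res1$mismatches, 1L)

  # CC anchor is exact: a mismatch inside the anchor is never tolerated
  expect_equal(nrow(find_cores("CADPCQKP", max_mismatch = 2,
                               exact_prefix_len = 2)), 0L)
  # X never matches a motif position
  expect_equal(find_cores("CCDPCX")$mismatches, 1L)
  expect_equal(nrow(find_cores("CCXPCX")), 0L)
})

test_that("find_cores equals the brute-force window oracle on random input", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_protein(200)
    got <- find_cores(s)
    want <- oracle_find_cores(s)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("raising max_mismatch never loses cores", {
  set.seed(202)
  for (i in 1:30) {
    s <- random_protein(150)
    counts <- vapply(0:3, function(mm) nrow(find_cores(s, max_mismatch = mm)),
                     integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("segment_units reproduces the worked segmentations", {
  s <- "CCDPCQKPCCDPCQQSV"
  arch <- segment_units(s, find_cores(s, max_mismatch = 0))
  expect_equal(arch$nterm, "")
  expect_equal(arch$cterm, "")
  expect_equal(arch$units$start, c(0L, 8L))
  expect_equal(arch$units$end, c(8L, 17L))
  expect_equal(arch$units$tail, c("KP", "QSV"))

  s2 <- "MWYCCDPCQTCCDPCQS"
  arch2 <- decompose(s2)
  expect_equal(arch2$nterm, "MWY")
  expect_equal(arch2$units$tail, c("T", "S"))
  expect_equal(arch2$cterm, "")
})

test_that("segment_units truncates oversized gaps into linkers", {
  # gap of 14 between core starts: unit capped at core+max_tail, 4 left over
  s <- paste0("CCDPCQKTVGGGGG", "CCDPCQKP")
  arch <- segment_units(s, find_cores(s, max_mismatch = 0))
  expect_equal(arch$units$end[1], 10L)
  expect_equal(nrow(arch$linkers), 1L)
  expect_equal(arch$linkers$start, 10L)
  expect_equal(arch$linkers$end, 14L)
  expect_equal(arch$linkers$seq, "GGGG")
  expect_equal(edcrp:::reconstruct_architecture(arch), s)
})

test_that("segment_units rejects overlapping or invalid cores", {
  expect_error(
    segment_units("CCDPCQKP", tibble::tibble(start = c(0L, 3L),
                                             mismatches = c(0L, 0L))),
    "non-overlapping")
  expect_error(
    segment_units("CCDPCQ", tibble::tibble(start = 3L, mismatches = 0L)),
    "past end")
})

test_that("empty core list puts the whole sequence in the N-terminus", {
  arch <- decompose("MKLVNNWYSTRA")
  expect_equal(arch$nterm, "MKLVNNWYSTRA")
  expect_equal(arch$n_repeats, 0L)
  expect_equal(arch$cterm, "")
})

test_that("classify_tail implements the default inventory", {
  expect_equal(classify_tail("KP"), "KP")
  expect_equal(classify_tail(c("KTV", "KSV")), rep("K(T/S)V", 2))
  expect_equal(classify_tail(c("T", "S")), rep("(T/S)", 2))
  expect_equal(classify_tail(c("QSV", "QS")), rep("QS(V)", 2))
  expect_equal(classify_tail(""), "CORE_ONLY")
  expect_equal(classify_tail("QW"), "OTHER")
  expect_error(classify_tail("KPKPV"), "longer than 4")
})

test_that("every tail maps to exactly one label (first rule wins)", {
  tails <- c("", "K", "P", "T", "S", "V", "KP", "KT", "KS", "KV", "QS",
             "QSV", "KTV", "KSV", "QQS", "KPV", "X", "XX")
  labels <- classify_tail(tails)
  expect_equal(length(labels), length(tails))
  expect_true(all(nchar(labels) > 0))
})

test_that("alternation_stats matches worked examples", {
  alt <- alternation_stats(c("A", "B", "A", "B", "A", "B"))
  expect_equal(alt$pair_labels[[1]], c("A", "B"))
  expect_equal(alt$run_length, 6L)
  expect_equal(alt$n_pairs, 3L)

  deg <- alternation_stats(c("A", "A", "A"))
  expect_equal(deg$run_length, 1L)
  expect_equal(deg$n_pairs, 0L)
  expect_null(deg$pair_labels[[1]])

  single <- alternation_stats("A")
  expect_equal(single$n_pairs, 0L)
  expect_null(single$pair_labels[[1]])

  empty <- alternation_stats(character(0))
  expect_equal(empty$run_length, 0L)
})

test_that("alternation_stats equals the exhaustive substring oracle", {
  set.seed(303)
  for (i in 1:200) {
    labels <- sample(LETTERS[1:sample(2:4, 1)], sample(1:12, 1),
                     replace = TRUE)
    got <- alternation_stats(labels)
    want <- oracle_alternation(labels)
    expect_equal(got$run_length, want$run_length)
    expect_equal(got$n_pairs, want$n_pairs)
    expect_equal(got$run_start_unit, want$run_start)
  }
})

test_that("decompose segments the four main repeat units", {
  arch <- decompose(paste(main_repeat_units(), collapse = ""))
  expect_equal(arch$n_repeats, 4L)
  expect_equal(sort(unique(arch$units$type_label)),
               sort(c("KP", "K(T/S)V", "(T/S)", "QS(V)")))
  expect_equal(sort(arch$units$end - arch$units$start), c(7L, 8L, 9L, 9L))
})

test_that("reconstruction invariant holds on random sequences", {
  set.seed(404)
  for (i in 1:100) {
    s <- random_protein(sample(50:300, 1))
    arch <- decompose(s)
    expect_equal(edcrp:::reconstruct_architecture(arch), s)
    lens <- arch$units$end - arch$units$start
    expect_true(all(lens >= 6 & lens <= 10))
  }
})

test_that("greedy unit count equals the exhaustive DP on short sequences", {
  set.seed(505)
  for (i in 1:50) {
    s <- random_protein(sample(20:60, 1), cys_weight = 6)
    expect_equal(decompose(s)$n_cores, oracle_max_units(s))
  }
})

test_that("tidy and glance summarize architectures", {
  arch <- decompose(paste0("MWY", paste(main_repeat_units(), collapse = ""),
                           "GGLKV"))
  td <- tidy(arch)
  expect_equal(nrow(td), 4L)
  expect_equal(td$length, td$end - td$start)
  segs <- tidy(arch, segments = TRUE)
  expect_equal(segs$segment[1], "nterm")
  expect_equal(segs$segment[nrow(segs)], "cterm")
  expect_equal(sum(segs$length), nchar(arch$seq))
  gl <- glance(arch)
  expect_equal(gl$n_repeats, 4L)
  expect_equal(gl$nterm_len, 3L)
  expect_equal(gl$cterm_len, 5L)
})

test_that("scan_proteins returns one summary row per record", {
  recs <- tibble::tibble(
    id = c("r1", "r2"),
    seq = c(paste(main_repeat_units(), collapse = ""), "MKLVNN"))
  out <- scan_proteins(recs)
  expect_equal(out$n_repeats, c(4L, 0L))
  expect_s3_class(out$architecture[[1]], "repeat_architecture")
})
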