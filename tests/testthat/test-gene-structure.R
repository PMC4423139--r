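edcrp_style <- function(id = "g1", neighbors = c("EDWM", "LOR")) {
  gene_model(id, exons = rbind(c(0L, 100L), c(500L, 1800L)),
             coding_exon_indices = 1L, locus_label = "EDC",
             neighbors = neighbors)
}
krtap_style <- function(id = "g2") {
  gene_model(id, exons = rbind(c(0L, 500L)), coding_exon_indices = 0L,
             locus_label = "type1_keratin_cluster",
             neighbors = c("KRT31-like", "KRTAP-cluster-genes"))
}

test_that("structure_signature reads exon architecture", {
  expect_equal(structure_signature(edcrp_style()),
               tibble::tibble(n_exons = 2L, n_coding_exons = 1L,
                              has_noncoding_first_exon = TRUE))
  expect_equal(structure_signature(krtap_style()),
               tibble::tibble(n_exons = 1L, n_coding_exons = 1L,
                              has_noncoding_first_exon = FALSE))
  g3 <- gene_model("g3", exons = rbind(c(0L, 10L), c(20L, 30L), c(40L, 50L)),
                   coding_exon_indices = 0:2)
  expect_equal(structure_signature(g3),
               tibble::tibble(n_exons = 3L, n_coding_exons = 3L,
                              has_noncoding_first_exon = FALSE))
})

test_that("gene_model validates its invariants", {
  expect_error(gene_model("bad", exons = rbind(c(0L, 100L), c(50L, 150L))),
               "non-overlapping")
  expect_error(gene_model("bad", exons = rbind(c(0L, 100L)),
                          coding_exon_indices = 2L), "out of range")
})

test_that("synteny_jaccard matches worked examples and is bounded", {
  expect_equal(synteny_jaccard(edcrp_style("a"), edcrp_style("b")), 1)
  expect_equal(synteny_jaccard(edcrp_style(), krtap_style()), 0)
  expect_equal(synteny_jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  # case-insensitive exact name match
  expect_equal(synteny_jaccard(c("edwm", "lor"), c("EDWM", "LOR")), 1)
  # sided neighbor lists honor k_neighbors per side
  g1 <- gene_model("s1", exons = rbind(c(0L, 10L)),
                   neighbors = list(upstream = c("A", "B", "C", "D"),
                                    downstream = c("E", "F")))
  g2 <- gene_model("s2", exons = rbind(c(0L, 10L)),
                   neighbors = list(upstream = c("A", "B"),
                                    downstream = c("E", "F")))
  expect_equal(synteny_jaccard(g1, g2, k_neighbors = 2L), 1)
  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(LETTERS, sample(1:6, 1))
    n2 <- sample(LETTERS, sample(1:6, 1))
    sj <- synteny_jaccard(n1, n2)
    expect_gte(sj, 0)
    expect_lte(sj, 1)
    expect_equal(synteny_jaccard(n1, n1), 1)
  }
})

test_that("motif_similarity matches direct k-mer enumeration", {
  s <- "CCDPCQKPCCDPCQQSV"
  expect_equal(motif_similarity(s, s), 1)
  expect_equal(motif_similarity(strrep("CCDPCQKP", 4), strrep("G", 50)), 0)

  set1 <- c("CCDPCQKPCCDPCQT", "CCKQCCDP")
  set2 <- c("CCDPCQSSCCQP", "KQCCDPCQ")
  want <- {
    k1 <- oracle_kmers(set1, 5)
    k2 <- oracle_kmers(set2, 5)
    length(intersect(k1, k2)) / length(union(k1, k2))
  }
  expect_equal(motif_similarity(set1, set2), want)
})

test_that("motif_similarity skips short sequences with a warning", {
  expect_warning(ms <- motif_similarity(c("CCDPCQKP", "CC"), "CCDPCQKP"),
                 "skipped")
  expect_equal(ms, 1)
  expect_error(suppressWarnings(motif_similarity("CC", "CCDPCQKP")),
               "shorter than k")
})

test_that("convergence_verdict applies the decision rule", {
  sig_e <- structure_signature(edcrp_style())
  sig_k <- structure_signature(krtap_style())

  conv <- convergence_verdict(0.2, sig_e, sig_k, 0)
  expect_equal(conv$verdict, "supports_convergence")
  expect_false(conv$structure_concordant)
  expect_match(conv$rationale, "discordant")

  hom <- convergence_verdict(0.5, sig_e, sig_e, 1)
  expect_equal(hom$verdict, "supports_homology")

  expect_equal(convergence_verdict(0.01, sig_e, sig_k, 0)$verdict,
               "indeterminate")
  # concordant structure but lost synteny: the unresolved loss-vs-convergence
  # alternative stays indeterminate
  expect_equal(convergence_verdict(0.5, sig_e, sig_e, 0)$verdict,
               "indeterminate")
})

test_that("the verdict is symmetric in its gene arguments", {
  fx <- synthetic_gene_fixtures()
  v12 <- compare_gene_families(fx$models$avian_EDCRP, fx$models$human_KRTAP,
                               fx$proteins$avian, fx$proteins$krtap)
  v21 <- compare_gene_families(fx$models$human_KRTAP, fx$models$avian_EDCRP,
                               fx$proteins$krtap, fx$proteins$avian)
  expect_equal(v12$verdict, v21$verdict)
  expect_equal(v12$motif_similarity, v21$motif_similarity)
  expect_equal(v12$synteny_jaccard, v21$synteny_jaccard)
})

test_that("gene models round-trip through JSON", {
  fx <- synthetic_gene_fixtures()
  tf <- tempfile(fileext = ".json")
  write_gene_models(fx$models, tf)
  back <- read_gene_models(tf)
  expect_equal(names(back), names(fx$models))
  expect_equal(back$avian_EDCRP$exons, fx$models$avian_EDCRP$exons)
  expect_equal(back$avian_EDCRP$neighbors, fx$models$avian_EDCRP$neighbors)
  expect_equal(structure_signature(back$human_KRTAP),
               structure_signature(fx$models$human_KRTAP))
})

test_that("the GFF3 reader builds gene models with derived neighbors", {
  skip_if_not_installed("rtracklayer")
  gff <- system.file("extdata", "toy_locus_synthetic.gff3", package = "edcrp")
  models <- read_gff_gene_models(gff)
  expect_setequal(names(models),
                  c("PGLYRP3", "EDWM", "EDCRP", "LOR1", "LOR2"))
  sig <- structure_signature(models$EDCRP)
  expect_equal(sig$n_exons, 2L)
  expect_true(sig$has_noncoding_first_exon)
  expect_equal(models$EDCRP$neighbors$upstream, c("EDWM", "PGLYRP3"))
  expect_equal(models$EDCRP$neighbors$downstream, c("LOR1", "LOR2"))
})
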