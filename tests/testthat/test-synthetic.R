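falcon_plan <- function() {
  repeat_plan(main_repeat_units()[c("KP", "QS(V)")],
              arrangement = "alternating", n_pairs = 14)
}

test_that("repeat_plan validates unit strings and ranges", {
  expect_error(repeat_plan(c(x = "CDPCQKP"), n_units = 6), "CCDPCQ")
  expect_error(repeat_plan(c(x = "CCDPCQKPKPKPK"), n_units = 6), "7-10")
  expect_error(repeat_plan(main_repeat_units(), n_units = 5), "\\[6, 56\\]")
  expect_error(repeat_plan(main_repeat_units(), n_units = 57), "\\[6, 56\\]")
  expect_error(repeat_plan(main_repeat_units()[1:2],
                           arrangement = "alternating"), "n_pairs")
  p <- falcon_plan()
  expect_equal(p$n_units, 28L)
})

test_that("generation is deterministic in the seed", {
  p <- falcon_plan()
  a <- generate_edcrp_like(5, p)
  b <- generate_edcrp_like(5, p)
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$truth$architecture$units, b$truth$architecture$units)
  c <- generate_edcrp_like(6, p)
  expect_false(identical(a$record$seq, c$record$seq))
})

test_that("the falcon-style plan yields 28 cores alternating 14 times", {
  gen <- generate_edcrp_like(1, falcon_plan())
  arch <- decompose(gen$record)
  expect_equal(arch$n_cores, 28L)
  expect_equal(arch$alternation$n_pairs, 14L)
  expect_setequal(arch$alternation$pair_labels[[1]], c("KP", "QS(V)"))
})

test_that("zero-noise decomposition recovers the truth across the grid", {
  for (n_units in c(6L, 20L, 56L)) {
    for (nterm_len in c(8L, 20L)) {
      for (cterm_len in c(52L, 75L)) {
        plan <- repeat_plan(main_repeat_units(), arrangement = "random",
                            n_units = n_units)
        gen <- suppressWarnings(
          generate_edcrp_like(n_units * 1000L + nterm_len + cterm_len,
                              plan, nterm_len = nterm_len,
                              cterm_len = cterm_len))
        truth <- gen$truth$architecture
        est <- decompose(gen$record)
        expect_identical(est$units, truth$units)
        expect_identical(nchar(est$nterm), nterm_len)
        expect_identical(nchar(est$cterm), cterm_len)
        expect_equal(edcrp:::reconstruct_architecture(truth),
                     gen$truth$pre_noise_seq)
      }
    }
  }
})

test_that("truth round-trips exactly for seeds 1-20 on a mixed plan", {
  plan <- repeat_plan(main_repeat_units(), arrangement = "random",
                      n_units = 20)
  for (seed in 1:20) {
    gen <- generate_edcrp_like(seed, plan)
    expect_identical(decompose(gen$record)$units,
                     gen$truth$architecture$units)
  }
})

test_that("zero-noise main-type plans stay in the 29-38% cysteine band", {
  for (n_units in c(20L, 40L, 56L)) {
    plan <- repeat_plan(main_repeat_units(), arrangement = "random",
                        n_units = n_units)
    for (seed in 1:5) {
      gen <- generate_edcrp_like(seed, plan)
      pct <- residue_profile(gen$truth$pre_noise_seq)$cys_percent
      expect_gte(pct, 29)
      expect_lte(pct, 38)
    }
  }
})

test_that("the generator warns when a plan leaves the composition band", {
  low_cys <- repeat_plan(main_repeat_units(), arrangement = "random",
                         n_units = 6)
  expect_warning(
    generate_edcrp_like(1, low_cys, nterm_len = 20, cterm_len = 75,
                        terminal_cys_fraction = 0.02),
    "outside the 29-38% band")
})

test_that("parameter validation rejects out-of-range inputs", {
  p <- falcon_plan()
  expect_error(generate_edcrp_like(1, p, nterm_len = 7), "\\[8, 20\\]")
  expect_error(generate_edcrp_like(1, p, cterm_len = 80), "\\[52, 75\\]")
  expect_error(generate_edcrp_like(1, p, sub_rate = 0.5), "\\[0, 0.2\\]")
})

test_that("mutate_seq honors its rate contracts", {
  expect_equal(mutate_seq("CCDPCQ", 0, 0, seed = 1), "CCDPCQ")
  s <- strrep("A", 200)
  forced <- mutate_seq(s, 1, 0, seed = 2)
  expect_equal(nchar(forced), 200L)
  expect_false(grepl("A", forced, fixed = TRUE))

  # substitution count over 10,000 positions within 3 SD of binomial
  long <- random_protein(10000)
  mut <- mutate_seq(long, 0.05, 0, seed = 3)
  n_sub <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(n_sub - 500), 3 * sqrt(10000 * 0.05 * 0.95))

  # indels change length with expected magnitude ~ Binomial difference
  mut2 <- mutate_seq(long, 0, 0.04, seed = 4)
  expect_false(nchar(mut2) == 0)
  expect_lt(abs(nchar(mut2) - 10000), 3 * sqrt(2 * 10000 * 0.02 * 0.98) + 1)
})

test_that("generated promoters round-trip their planted truth", {
  for (el in c("none", "tata_like", "canonical_tata")) {
    for (seed in 1:10) {
      rec <- generate_promoter(seed, element = el, position = -40)
      ann <- scan_promoter(rec$seq, rec$tss_index)
      expect_equal(ann$element_class, el)
      if (el != "none") expect_equal(ann$position, -40L)
    }
  }
})

test_that("generate_promoter validates motif placement", {
  expect_error(generate_promoter(1, "tata_like", position = -10),
               "does not fit")
  expect_error(generate_promoter(1, "canonical_tata", motif = "AATAAAA"),
               "element class")
})

test_that("the synthetic panel respects the published parameter ranges", {
  panel <- generate_edcrp_panel(3, n = 8)
  scans <- scan_proteins(panel$records)
  expect_true(all(scans$n_repeats >= 6 & scans$n_repeats <= 56))
  expect_true(all(scans$nterm_len >= 8 & scans$nterm_len <= 20))
  expect_true(all(scans$cterm_len >= 52 & scans$cterm_len <= 75))
})
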