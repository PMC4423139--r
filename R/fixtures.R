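# Deterministic terminal segment with an exact cysteine count: CC pairs
# (plus one single C when the count is odd) dropped into a cysteine-free
# filler cycle at ~10-residue spacing, mimicking the CC pattern of real
# EDCRP termini without ever forming a spurious CCDPCQ-like core.
terminal_with_cys <- function(len, n_cys, spacing = 10L, offset = 2L) {
  stopifnot(n_cys <= len)
  filler <- c("K", "Q", "P", "S", "V", "G", "D", "L")
  chars <- rep_len(filler, len)
  placed <- 0L
  pos <- offset
  while (placed < n_cys && pos + 1L < len) {
    take <- min(2L, n_cys - placed)
    chars[(pos + 1L):(pos + take)] <- "C"
    placed <- placed + take
    pos <- pos + spacing
  }
  while (placed < n_cys) {  # dense fallback for cysteine-heavy termini
    free <- which(chars != "C")[1]
    chars[free] <- "C"
    placed <- placed + 1L
  }
  paste(chars, collapse = "")
}

#' Synthetic stand-in reference proteins
#'
#' Deterministic, fully synthetic sequences constructed to the published
#' summary constraints of three reference EDCRPs, for exercising the
#' pipeline when the real sequence panel is unavailable:
#'
#' * `chicken_like` — 385 residues of which exactly 140 are cysteines
#'   (36% rounded), with a typed-repeat central region.
#' * `falcon_like` — KP and QS(V) units alternating 14 times.
#' * `ostrich_like` — cysteine content inside the 29-31% band typical of
#'   Palaeognathae.
#'
#' These are not the real sequences; they only reproduce the printed
#' summary statistics, so they validate the measurement machinery, not the
#' underlying biology.
#'
#' @return Tibble with `id`, `species`, `seq`.
#' @export
synthetic_reference_proteins <- function() {
  # chicken-like: nterm 15 (5 C) + 11 KP units + 24 QS(V) units + cterm 66
  # (30 C) = 385 aa, 140 C
  chicken <- paste0(
    terminal_with_cys(15L, 5L),
    strrep("CCDPCQKP", 11L),
    strrep("CCDPCQQSV", 24L),
    terminal_with_cys(66L, 30L, spacing = 4L)
  )
  falcon <- paste0(
    terminal_with_cys(12L, 4L, spacing = 5L),
    strrep(paste0("CCDPCQKP", "CCDPCQQSV"), 14L),
    terminal_with_cys(60L, 20L, spacing = 5L)
  )
  # ostrich-like: 60 + 14 = 74 C over 245 aa = 30.2%
  ostrich <- paste0(
    terminal_with_cys(15L, 2L),
    strrep("CCDPCQKP", 20L),
    terminal_with_cys(70L, 12L)
  )
  tibble(
    id = c("chicken_like", "falcon_like", "ostrich_like"),
    species = c("synthetic (chicken-like)", "synthetic (falcon-like)",
                "synthetic (ostrich-like)"),
    seq = c(chicken, falcon, ostrich)
  )
}

#' Synthetic promoter panel mirroring the avian/lizard TATA survey
#'
#' Generates one promoter per species label with the element class
#' reported for that lineage: the TATA-like `AATAAAA` for every avian
#' species except the loon, and a canonical TATA box for the loon and the
#' green anole lizard. Entirely synthetic background sequence; only the
#' planted element class mirrors the survey.
#'
#' @param seed Integer seed.
#' @param position Planted element offset relative to the TSS.
#' @return Tibble with `id`, `species`, `seq`, `tss_index`, `element`
#'   (the planted truth).
#' @export
synthetic_promoter_panel <- function(seed = 1L, position = -30L) {
  avian <- c("chicken", "duck", "zebra_finch", "falcon", "ostrich",
             "tinamou", "pigeon", "egret", "mesite", "canary",
             "emperor_penguin", "adelie_penguin")
  species <- c(avian, "loon", "lizard")
  element <- c(rep("tata_like", length(avian)), "canonical_tata",
               "canonical_tata")
  purrr::map2_dfr(species, seq_along(species), function(sp, i) {
    rec <- generate_promoter(seed * 1000L + i, element = element[i],
                             position = position)
    tibble(id = sp, species = sp, seq = rec$seq,
           tss_index = rec$tss_index, element = element[i])
  })
}

#' Synthetic gene-model and protein fixtures for the convergence analysis
#'
#' Toy records mirroring the published locus descriptions: avian and
#' lizard EDCRP genes with a non-coding first exon and a coding second
#' exon, located between EDWM and the loricrin genes of the epidermal
#' differentiation complex; and a single-exon, TATA-box human KRTAP gene
#' inside a type 1 keratin cluster. Protein sets are synthetic
#' cysteine-rich sequences sharing the repeat vocabulary of their family.
#'
#' @return List with `models` (named list of [gene_model()]) and
#'   `proteins` (named list of record tibbles: `avian`, `lizard`,
#'   `krtap`).
#' @export
synthetic_gene_fixtures <- function() {
  edc_neighbors <- list(upstream = c("EDWM", "PGLYRP3"),
                        downstream = c("LOR1", "LOR2"))
  models <- list(
    avian_EDCRP = gene_model(
      "avian_EDCRP", species = "chicken",
      exons = rbind(c(0L, 150L), c(800L, 2200L)),
      coding_exon_indices = 1L, locus_label = "EDC",
      neighbors = edc_neighbors, strand = "+"),
    lizard_EDCRP = gene_model(
      "lizard_EDCRP", species = "green anole lizard",
      exons = rbind(c(0L, 120L), c(700L, 2100L)),
      coding_exon_indices = 1L, locus_label = "EDC",
      neighbors = edc_neighbors, strand = "+"),
    human_KRTAP = gene_model(
      "human_KRTAP", species = "human",
      exons = rbind(c(0L, 600L)),
      coding_exon_indices = 0L, locus_label = "type1_keratin_cluster",
      neighbors = list(upstream = c("KRT31", "KRT33A"),
                       downstream = c("KRTAP1-3", "KRT34")),
      strand = "+")
  )
  refs <- synthetic_reference_proteins()
  lizard <- tibble(
    id = "lizard_EDCRP_like", species = "synthetic (lizard-like)",
    seq = paste0(terminal_with_cys(14L, 4L),
                 strrep("CCDPCQKTVCCDPCQT", 8L),
                 terminal_with_cys(55L, 18L, spacing = 5L)))
  krtap <- tibble(
    id = c("KRTAP_like_1", "KRTAP_like_2"),
    species = "synthetic (KRTAP-like)",
    seq = c(paste0("MSC", strrep("CCDPCQSS", 10L), strrep("CCQPSCQS", 5L)),
            paste0("MAC", strrep("CCQPCCQSV", 8L), strrep("CCDPSCQT", 4L))))
  list(models = models,
       proteins = list(avian = refs[refs$id != "ostrich_like", ],
                       lizard = lizard, krtap = krtap))
}
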