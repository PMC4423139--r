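#' Default run configuration
#'
#' Central bundle of every tunable parameter, with defaults matching the
#' biology of EDCRP/KRTAP-class proteins: the `CCDPCQ` core with an exact
#' CC anchor and at most one mismatch elsewhere, 4-residue maximum tails,
#' the 8-11 residue CC spacing band, a (-100, -15) promoter scan window
#' with exact-match `TATAAA`/`TATAAAA` versus `AATAAAA` elements, and the
#' verdict thresholds of [convergence_verdict()].
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    core = "CCDPCQ",
    max_mismatch = 1L,
    exact_prefix_len = 2L,
    max_tail = 4L,
    inventory = default_inventory(),
    cc_band = c(8L, 11L),
    promoter_window = c(-100L, -15L),
    canonical_motifs = c("TATAAA", "TATAAAA"),
    tata_like_motif = "AATAAAA",
    k_neighbors = 3L,
    kmer_k = 5L,
    min_cys = 2L,
    ms_min = 0.05,
    sj_min = 0.34,
    seed = 1L
  )
}

#' Load a YAML configuration over the defaults
#'
#' Reads a YAML key-value file and merges it over [default_config()]
#' (or another base). A custom `inventory` is given as a list of
#' `{pattern, label}` mappings. Every field is validated on load.
#'
#' @param path YAML file path.
#' @param base Configuration list to merge into.
#' @return Validated configuration list.
#' @export
load_config <- function(path, base = default_config()) {
  raw <- yaml::read_yaml(path)
  inv <- raw$inventory
  raw$inventory <- NULL
  cfg <- modifyList(base, raw)
  if (!is.null(inv)) {
    cfg$inventory <- dplyr::bind_rows(lapply(inv, as_tibble))
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    nchar(cfg$core) > 0L,
    cfg$max_mismatch >= 0L,
    cfg$exact_prefix_len >= 0L, cfg$exact_prefix_len <= nchar(cfg$core),
    cfg$max_tail >= 0L,
    is.data.frame(cfg$inventory),
    all(c("pattern", "label") %in% names(cfg$inventory)),
    length(cfg$cc_band) == 2L, cfg$cc_band[1] <= cfg$cc_band[2],
    length(cfg$promoter_window) == 2L,
    cfg$promoter_window[1] < cfg$promoter_window[2],
    length(cfg$canonical_motifs) >= 1L,
    nchar(cfg$tata_like_motif) > 0L,
    cfg$k_neighbors >= 1L, cfg$kmer_k >= 3L,
    cfg$ms_min >= 0, cfg$ms_min <= 1, cfg$sj_min >= 0, cfg$sj_min <= 1
  )
  cfg
}

architecture_to_list <- function(arch, id = NULL) {
  n <- nchar(arch$seq)
  nterm_len <- nchar(arch$nterm)
  list(
    id = id %||% arch$id %||% NA_character_,
    length = n,
    nterm = list(start = 0L, end = nterm_len, seq = arch$nterm),
    cterm = list(start = n - nchar(arch$cterm), end = n, seq = arch$cterm),
    units = arch$units,
    linkers = arch$linkers,
    n_repeats = arch$n_repeats,
    n_cores = arch$n_cores,
    type_counts = as.list(arch$type_counts),
    alternation = list(
      pair_labels = arch$alternation$pair_labels[[1]],
      n_pairs = arch$alternation$n_pairs,
      run_start_unit = arch$alternation$run_start_unit,
      run_length = arch$alternation$run_length
    )
  )
}

#' Scan a protein FASTA: architectures, unit table, composition table
#'
#' Orchestrates the repeat-architecture and composition stages over a FASTA
#' file (gapped alignment FASTA is degapped on the fly) and writes three
#' files into `out_dir`: `architecture.json` (one object per record, 0-based
#' half-open coordinates), `units.tsv` (one row per repeat unit) and
#' `composition.tsv` (one row per record). Records without any repeat are
#' reported with a message. Re-running with identical inputs and
#' configuration produces byte-identical outputs.
#'
#' @param fasta Input protein FASTA path.
#' @param out_dir Output directory (created if missing).
#' @param config Configuration list; see [default_config()].
#' @return Named list of output paths, invisibly.
#' @export
cmd_scan <- function(fasta, out_dir, config = default_config()) {
  config <- validate_config(config)
  records <- read_fasta(fasta, "protein")
  if ("aligned_seq" %in% names(records)) records <- degap(records)
  scans <- scan_proteins(records, core = config$core,
                         max_mismatch = config$max_mismatch,
                         exact_prefix_len = config$exact_prefix_len,
                         max_tail = config$max_tail,
                         inventory = config$inventory)
  none <- scans$id[scans$n_repeats == 0L]
  for (id in none) message("record '", id, "' has no repeat units")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(architecture = file.path(out_dir, "architecture.json"),
                units = file.path(out_dir, "units.tsv"),
                composition = file.path(out_dir, "composition.tsv"))
  jsonlite::write_json(
    purrr::map2(scans$architecture, scans$id, architecture_to_list),
    paths$architecture, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  units <- purrr::map2_dfr(scans$architecture, scans$id, function(a, id) {
    if (nrow(a$units) == 0L) return(tibble())
    dplyr::bind_cols(tibble(id = id, unit_index = seq_len(nrow(a$units)) - 1L),
                     a$units)
  })
  readr::write_tsv(units, paths$units)
  readr::write_tsv(profile_composition(records, band = config$cc_band),
                   paths$composition)
  invisible(paths)
}

#' Classify promoters from FASTA plus TSS sidecar
#'
#' Reads a DNA FASTA and a TSS specification (a sidecar TSV with columns
#' `id`, `tss_index`, or one integer applied to all records), classifies
#' each promoter with [scan_promoters()] and writes the annotation TSV.
#'
#' @param fasta Promoter DNA FASTA path.
#' @param out_tsv Output TSV path.
#' @param tss Sidecar TSV path, tibble, or single integer TSS.
#' @param config Configuration list.
#' @return The annotation tibble, invisibly.
#' @export
cmd_promoter <- function(fasta, out_tsv, tss, config = default_config()) {
  config <- validate_config(config)
  records <- read_fasta(fasta, "dna")
  if (is.character(tss) && length(tss) == 1L && file.exists(tss)) {
    tss <- readr::read_tsv(tss, show_col_types = FALSE)
  }
  ann <- scan_promoters(records, tss = tss,
                        window = config$promoter_window,
                        canonical_motifs = config$canonical_motifs,
                        tata_like_motif = config$tata_like_motif)
  readr::write_tsv(ann, out_tsv)
  invisible(ann)
}

#' Compare two gene families and write the verdict JSON
#'
#' Loads two gene models from a JSON file (see [read_gene_models()]) and a
#' protein FASTA per family, runs [compare_gene_families()] and writes the
#' verdict with all three scores and the rationale.
#'
#' @param models_json Gene-model JSON path (at least the two named genes).
#' @param gene1,gene2 Gene identifiers to compare.
#' @param fasta1,fasta2 Protein FASTA paths for the two families.
#' @param out_json Output JSON path.
#' @param config Configuration list.
#' @return The verdict tibble, invisibly.
#' @export
cmd_compare <- function(models_json, gene1, gene2, fasta1, fasta2,
                        out_json, config = default_config()) {
  config <- validate_config(config)
  models <- read_gene_models(models_json)
  for (g in c(gene1, gene2)) {
    if (!g %in% names(models)) {
      stop("gene '", g, "' not found in ", models_json, call. = FALSE)
    }
  }
  verdict <- compare_gene_families(
    models[[gene1]], models[[gene2]],
    read_fasta(fasta1, "protein"), read_fasta(fasta2, "protein"),
    k_neighbors = config$k_neighbors, kmer_k = config$kmer_k,
    min_cys = config$min_cys, ms_min = config$ms_min,
    sj_min = config$sj_min)
  jsonlite::write_json(as.list(verdict), out_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(verdict)
}

#' Simulate an EDCRP-like panel to FASTA plus truth sidecar
#'
#' Wraps [generate_edcrp_panel()]: writes the records as FASTA and the
#' ground truth (plans, segment coordinates, unit labels) as a JSON
#' sidecar that [cmd_benchmark()] consumes.
#'
#' @param out_fasta,out_truth_json Output paths.
#' @param seed Integer seed.
#' @param n Number of records.
#' @param sub_rate,indel_rate Noise rates.
#' @return Invisible list of output paths.
#' @export
cmd_simulate <- function(out_fasta, out_truth_json, seed, n = 12L,
                         sub_rate = 0, indel_rate = 0) {
  panel <- generate_edcrp_panel(seed, n = n, sub_rate = sub_rate,
                                indel_rate = indel_rate)
  write_fasta(panel$records, out_fasta)
  truths <- purrr::map2(panel$truths, panel$records$id, function(tr, id) {
    list(id = id, seed = tr$seed, nterm_len = tr$nterm_len,
         cterm_len = tr$cterm_len, sub_rate = tr$sub_rate,
         indel_rate = tr$indel_rate,
         architecture = architecture_to_list(tr$architecture, id))
  })
  jsonlite::write_json(truths, out_truth_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(fasta = out_fasta, truth = out_truth_json))
}

# Fraction of true unit boundary coordinates (unit starts and ends)
# recovered by an estimated unit table.
boundary_recovery <- function(true_units, est_units) {
  truth <- sort(unique(c(true_units$start, true_units$end)))
  if (length(truth) == 0L) return(NA_real_)
  est <- unique(c(est_units$start, est_units$end))
  mean(truth %in% est)
}

#' Benchmark architecture recovery against simulation truth
#'
#' Re-analyzes a simulated FASTA with [scan_proteins()] and scores each
#' record against the truth sidecar: repeat-count agreement and the
#' fraction of true unit boundaries (starts and ends) recovered. Only
#' meaningful for substitution-only noise, where coordinates are
#' preserved.
#'
#' @param fasta Simulated FASTA path (from [cmd_simulate()]).
#' @param truth_json Truth sidecar path.
#' @param out_tsv Output report path.
#' @param config Configuration list.
#' @return The report tibble, invisibly.
#' @export
cmd_benchmark <- function(fasta, truth_json, out_tsv,
                          config = default_config()) {
  config <- validate_config(config)
  records <- read_fasta(fasta, "protein")
  truths <- jsonlite::read_json(truth_json, simplifyVector = FALSE)
  names(truths) <- vapply(truths, `[[`, character(1), "id")
  scans <- scan_proteins(records, core = config$core,
                         max_mismatch = config$max_mismatch,
                         exact_prefix_len = config$exact_prefix_len,
                         max_tail = config$max_tail,
                         inventory = config$inventory)
  report <- purrr::map_dfr(seq_len(nrow(scans)), function(i) {
    tr <- truths[[scans$id[i]]]
    tr_units <- dplyr::bind_rows(lapply(tr$architecture$units, as_tibble))
    est <- scans$architecture[[i]]$units
    tibble(
      id = scans$id[i],
      true_n_repeats = length(tr$architecture$units),
      est_n_repeats = nrow(est),
      boundary_recovery = boundary_recovery(tr_units, est)
    )
  })
  readr::write_tsv(report, out_tsv)
  invisible(report)
}
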