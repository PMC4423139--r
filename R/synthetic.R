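# Residues used alongside cysteine in sampled terminal segments: the
# residues that dominate real EDCRP termini and repeat tails.
TERMINAL_RESIDUES <- c("K", "Q", "P", "S", "V", "D", "G", "L")

#' Define a repeat plan for the synthetic generator
#'
#' A plan fixes the exact unit strings and their arrangement, which becomes
#' the recorded ground truth of [generate_edcrp_like()]. Unit strings must
#' start with the `CCDPCQ` core and be 7-10 residues long, matching the
#' repeat-length regime of real EDCRPs (7-9, exceptionally 10).
#'
#' @param unit_specs Named character vector of unit strings (names are type
#'   labels; unnamed specs are labelled from their tails via
#'   [classify_tail()]), or a tibble with columns `label`, `unit`.
#' @param arrangement `"as_listed"` (specs cycled to `n_units`),
#'   `"alternating"` (first two specs, `A,B,A,B,...`), or `"random"`
#'   (specs sampled uniformly, under the generator's seed).
#' @param n_units Total number of units, 6-56. For `"alternating"` supply
#'   `n_pairs` instead (`n_units = 2 * n_pairs`).
#' @param n_pairs Number of A/B pairs for the alternating arrangement.
#' @return A `repeat_plan` object.
#' @examples
#' repeat_plan(main_repeat_units()[c("KP", "QS(V)")],
#'             arrangement = "alternating", n_pairs = 14)
#' @export
repeat_plan <- function(unit_specs,
                        arrangement = c("as_listed", "alternating", "random"),
                        n_units = NULL, n_pairs = NULL) {
  arrangement <- match.arg(arrangement)
  if (is.data.frame(unit_specs)) {
    specs <- tibble(label = unit_specs$label, unit = unit_specs$unit)
  } else {
    units <- as.character(unit_specs)
    labels <- names(unit_specs)
    if (is.null(labels) || any(labels == "")) {
      labels <- classify_tail(substr(units, 7L, nchar(units)))
    }
    specs <- tibble(label = labels, unit = units)
  }
  if (!all(startsWith(specs$unit, "CCDPCQ"))) {
    stop("every unit string must start with the CCDPCQ core", call. = FALSE)
  }
  if (!all(nchar(specs$unit) >= 7L & nchar(specs$unit) <= 10L)) {
    stop("unit strings must be 7-10 residues long", call. = FALSE)
  }
  if (arrangement == "alternating") {
    if (is.null(n_pairs)) stop("alternating arrangement needs n_pairs",
                               call. = FALSE)
    if (nrow(specs) < 2L) stop("alternating arrangement needs 2 specs",
                               call. = FALSE)
    n_units <- 2L * as.integer(n_pairs)
  }
  if (is.null(n_units)) n_units <- nrow(specs)
  n_units <- as.integer(n_units)
  if (n_units < 6L || n_units > 56L) {
    stop("n_units must lie in [6, 56] (got ", n_units, ")", call. = FALSE)
  }
  structure(list(unit_specs = specs, arrangement = arrangement,
                 n_units = n_units,
                 n_pairs = if (arrangement == "alternating") {
                   as.integer(n_pairs)
                 } else {
                   NA_integer_
                 }),
            class = "repeat_plan")
}

# Materialize the ordered unit list of a plan. Random arrangement consumes
# the active RNG stream.
plan_units <- function(plan) {
  specs <- plan$unit_specs
  idx <- switch(plan$arrangement,
    as_listed = rep_len(seq_len(nrow(specs)), plan$n_units),
    alternating = rep_len(c(1L, 2L), plan$n_units),
    random = sample.int(nrow(specs), plan$n_units, replace = TRUE)
  )
  specs[idx, ]
}

sample_terminal <- function(len, cys_fraction) {
  paste(sample(c("C", TERMINAL_RESIDUES), len, replace = TRUE,
               prob = c(cys_fraction,
                        rep((1 - cys_fraction) / length(TERMINAL_RESIDUES),
                            length(TERMINAL_RESIDUES)))),
        collapse = "")
}

#' Generate an EDCRP-like protein with recorded ground truth
#'
#' Emits `N-terminus + repeat units per plan + C-terminus`. Terminal
#' segments are sampled with the given cysteine fraction (remainder drawn
#' uniformly from K,Q,P,S,V,D,G,L) and resampled, up to `max_retries`
#' times, until the assembled zero-noise sequence's core scan recovers
#' exactly the planned core grid — chance core look-alikes in
#' cysteine-rich random termini would otherwise corrupt the ground truth.
#' Substitution/indel noise is applied only after the truth architecture is
#' recorded. A single seeded RNG stream makes every call fully
#' reproducible. The generator warns when the zero-noise cysteine content
#' leaves the 29-38% band observed across real avian EDCRPs.
#'
#' @param seed Integer seed.
#' @param plan A [repeat_plan()].
#' @param nterm_len N-terminal segment length, 8-20 residues.
#' @param cterm_len C-terminal segment length, 52-75 residues.
#' @param terminal_cys_fraction Cysteine fraction of sampled termini
#'   (default 0.25).
#' @param sub_rate,indel_rate Post-hoc noise rates in `[0, 0.2]`; see
#'   [mutate_seq()].
#' @param id Record identifier.
#' @param max_retries Terminal resampling budget.
#' @return List with `record` (one-row tibble `id`, `species`, `seq`) and
#'   `truth` (list: `plan`, `nterm_len`, `cterm_len`, `sub_rate`,
#'   `indel_rate`, `seed`, `pre_noise_seq`, `architecture` — the true
#'   `repeat_architecture` of the pre-noise sequence).
#' @export
generate_edcrp_like <- function(seed, plan, nterm_len = 12L,
                                cterm_len = 60L,
                                terminal_cys_fraction = 0.25,
                                sub_rate = 0, indel_rate = 0,
                                id = paste0("synthetic_", seed),
                                max_retries = 200L) {
  stopifnot(inherits(plan, "repeat_plan"))
  if (nterm_len < 8L || nterm_len > 20L) {
    stop("nterm_len must lie in [8, 20]", call. = FALSE)
  }
  if (cterm_len < 52L || cterm_len > 75L) {
    stop("cterm_len must lie in [52, 75]", call. = FALSE)
  }
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2) {
    stop("noise rates must lie in [0, 0.2]", call. = FALSE)
  }
  withr::with_seed(seed, {
    units <- plan_units(plan)
    unit_lens <- nchar(units$unit)
    repeat_region <- paste(units$unit, collapse = "")
    planned_starts <- nterm_len + c(0L, cumsum(unit_lens))[seq_len(nrow(units))]
    seq <- NULL
    for (try in seq_len(max_retries)) {
      nterm <- sample_terminal(nterm_len, terminal_cys_fraction)
      cterm <- sample_terminal(cterm_len, terminal_cys_fraction)
      cand <- paste0(nterm, repeat_region, cterm)
      found <- find_cores(cand)
      if (identical(found$start, as.integer(planned_starts)) &&
          all(found$mismatches == 0L)) {
        seq <- cand
        break
      }
    }
    if (is.null(seq)) {
      stop("could not sample clean terminal segments in ", max_retries,
           " tries", call. = FALSE)
    }
    arch <- segment_units(seq, tibble(start = as.integer(planned_starts),
                                      mismatches = 0L))
    cys_pct <- residue_profile(seq)$cys_percent
    if (cys_pct < 29 || cys_pct > 38) {
      warning(sprintf(
        "zero-noise cysteine content %.1f%% outside the 29-38%% band", cys_pct),
        call. = FALSE)
    }
    noisy <- if (sub_rate > 0 || indel_rate > 0) {
      mutate_seq(seq, sub_rate, indel_rate)
    } else {
      seq
    }
    list(
      record = tibble(id = id, species = "synthetic", seq = noisy),
      truth = list(plan = plan, nterm_len = as.integer(nterm_len),
                   cterm_len = as.integer(cterm_len), sub_rate = sub_rate,
                   indel_rate = indel_rate, seed = as.integer(seed),
                   pre_noise_seq = seq, architecture = arch)
    )
  })
}

#' Apply substitution and indel noise to a sequence
#'
#' Per-position independent substitutions (to a uniformly chosen different
#' residue of the 20-letter alphabet) and single-residue indels (equal
#' chance of deletion or of inserting a random residue after the position).
#' Uses the active RNG stream unless `seed` is given.
#'
#' @param seq Protein sequence.
#' @param sub_rate Per-position substitution probability in `[0, 1]`
#'   (1 forces every position to change).
#' @param indel_rate Per-position indel probability in `[0, 0.5]`.
#' @param seed Optional integer seed.
#' @param alphabet Residue alphabet for substitutions/insertions.
#' @return Mutated sequence string.
#' @export
mutate_seq <- function(seq, sub_rate, indel_rate, seed = NULL,
                       alphabet = AA20) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0,
            indel_rate <= 0.5)
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n == 0L) return(seq)
    sub_hit <- runif(n) < sub_rate
    if (any(sub_hit)) {
      chars[sub_hit] <- vapply(chars[sub_hit], function(orig) {
        sample(setdiff(alphabet, orig), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    if (indel_rate > 0) {
      indel_hit <- runif(n) < indel_rate
      if (any(indel_hit)) {
        is_del <- runif(n) < 0.5
        out <- character(0)
        for (i in seq_len(n)) {
          if (indel_hit[i] && is_del[i]) next
          out <- c(out, chars[i])
          if (indel_hit[i] && !is_del[i]) {
            out <- c(out, sample(alphabet, 1L))
          }
        }
        chars <- out
      }
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a promoter sequence with a planted core element
#'
#' Samples a uniform A/C/G/T background, rejection-filters it so the scan
#' window contains no motif occurrence other than the planted one (planting
#' can create junction artifacts, so the filter re-checks the assembled
#' sequence), plants the requested element at `position` relative to the
#' TSS, and sets the TSS at `length - 50`.
#'
#' @param seed Integer seed.
#' @param element `"none"`, `"canonical_tata"` or `"tata_like"`.
#' @param position Motif start offset relative to the TSS (negative
#'   upstream); the motif must fit inside `window`.
#' @param length Sequence length (default 200).
#' @param window Scan window the guarantee applies to.
#' @param canonical_motifs,tata_like_motif Motif sets; the planted motif is
#'   `motif` (default: first canonical motif, or the TATA-like element).
#' @param motif Motif string to plant; must belong to the chosen class.
#' @param max_retries Rejection-sampling budget.
#' @return One-row tibble: `id`, `seq`, `tss_index`, `element`, `position`.
#' @export
generate_promoter <- function(seed,
                              element = c("none", "canonical_tata",
                                          "tata_like"),
                              position = -30L, length = 200L,
                              window = c(-100L, -15L),
                              canonical_motifs = c("TATAAA", "TATAAAA"),
                              tata_like_motif = "AATAAAA",
                              motif = NULL, max_retries = 200L) {
  element <- match.arg(element)
  length <- as.integer(length)
  tss <- length - 50L
  all_motifs <- c(canonical_motifs, tata_like_motif)
  if (element != "none") {
    if (is.null(motif)) {
      motif <- if (element == "canonical_tata") {
        canonical_motifs[1]
      } else {
        tata_like_motif
      }
    }
    ok_class <- if (element == "canonical_tata") {
      motif %in% canonical_motifs
    } else {
      identical(motif, tata_like_motif)
    }
    if (!ok_class) stop("motif does not belong to element class",
                        call. = FALSE)
    if (position < window[1] || position + nchar(motif) > window[2]) {
      stop("planted motif [", position, ", ", position + nchar(motif),
           ") does not fit inside window [", window[1], ", ", window[2],
           ")", call. = FALSE)
    }
  }
  w0 <- tss + as.integer(window[1])
  w1 <- tss + as.integer(window[2])
  stopifnot(w0 >= 0L, w1 <= length)
  withr::with_seed(seed, {
    for (try in seq_len(max_retries)) {
      chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      if (element != "none") {
        at <- tss + as.integer(position)
        chars[(at + 1L):(at + nchar(motif))] <-
          strsplit(motif, "", fixed = TRUE)[[1]]
      }
      seq <- paste(chars, collapse = "")
      region <- substr(seq, w0 + 1L, w1)
      occ <- purrr::map_dfr(unique(all_motifs), function(m) {
        p <- gregexpr(m, region, fixed = TRUE)[[1]]
        if (p[1] == -1L) return(tibble())
        tibble(motif = m, at = as.integer(p) - 1L + w0 - tss)
      })
      clean <- if (element == "none") {
        nrow(occ) == 0L
      } else {
        nrow(occ) == 1L && occ$motif[1] == motif &&
          occ$at[1] == as.integer(position)
      }
      if (clean) {
        return(tibble(id = paste0("promoter_", element, "_", seed),
                      seq = seq, tss_index = tss, element = element,
                      position = if (element == "none") {
                        NA_integer_
                      } else {
                        as.integer(position)
                      }))
      }
    }
    stop("rejection sampling failed after ", max_retries, " tries",
         call. = FALSE)
  })
}

#' Generate a synthetic EDCRP-like panel with ground truth
#'
#' Draws `n` proteins across the realistic parameter ranges: 6-56 units per
#' protein built from 2-4 of the main repeat types, N-termini of 8-20 and
#' C-termini of 52-75 residues, arrangements mixed between alternating and
#' random. Useful as a stand-in species panel when real sequence panels
#' are unavailable.
#'
#' @param seed Integer seed.
#' @param n Number of proteins.
#' @param sub_rate,indel_rate Noise rates forwarded to
#'   [generate_edcrp_like()].
#' @return List with `records` (tibble of `id`, `species`, `seq`) and
#'   `truths` (list of truth records).
#' @export
generate_edcrp_panel <- function(seed, n = 12L, sub_rate = 0,
                                 indel_rate = 0) {
  params <- withr::with_seed(seed, {
    tibble(
      sub_seed = sample.int(1e6, n),
      n_units = sample(6:56, n, replace = TRUE),
      nterm_len = sample(8:20, n, replace = TRUE),
      cterm_len = sample(52:75, n, replace = TRUE),
      n_types = sample(2:4, n, replace = TRUE),
      alternating = runif(n) < 0.5
    )
  })
  out <- purrr::map(seq_len(n), function(i) {
    p <- params[i, ]
    types <- withr::with_seed(p$sub_seed + 1L, {
      sample(main_repeat_units(), p$n_types)
    })
    plan <- if (p$alternating) {
      repeat_plan(types[1:2], arrangement = "alternating",
                  n_pairs = max(3L, p$n_units %/% 2L))
    } else {
      repeat_plan(types, arrangement = "random", n_units = p$n_units)
    }
    generate_edcrp_like(p$sub_seed, plan, nterm_len = p$nterm_len,
                        cterm_len = p$cterm_len, sub_rate = sub_rate,
                        indel_rate = indel_rate,
                        id = sprintf("panel_%02d", i))
  })
  list(records = purrr::map_dfr(out, "record"),
       truths = purrr::map(out, "truth"))
}
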