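round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Residue composition profile of a protein sequence
#'
#' Counts every residue (including `X`, unless `include_x = FALSE`) and
#' reports fractions plus the cysteine percentage on the 0-100 scale.
#' Disulfide cross-linking capacity scales with cysteine content, which in
#' avian EDCRPs reaches 29-38% — among the highest of any protein family —
#' so cysteine gets a dedicated, integer-rounded readout
#' (round-half-away-from-zero, making printed values like "36%" directly
#' comparable).
#'
#' @param seq Protein sequence (non-empty uppercase string).
#' @param include_x Count `X` (unknown) positions in the length and counts?
#'   Default `TRUE`.
#' @return A `composition_profile` object: list with `counts` (named
#'   integer over the observed alphabet), `fractions`, `length`,
#'   `cys_percent` and `cys_percent_rounded`.
#' @examples
#' residue_profile("CCDPCQ")$cys_percent
#' @export
residue_profile <- function(seq, include_x = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!include_x) chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop("sequence contains only 'X' positions", call. = FALSE)
  }
  tab <- table(chars)
  counts <- setNames(as.integer(tab), names(tab))
  len <- length(chars)
  cys <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  structure(
    list(counts = counts, fractions = counts / len, length = len,
         cys_percent = 100 * cys / len,
         cys_percent_rounded = as.integer(round_half_away(100 * cys / len))),
    class = "composition_profile"
  )
}

#' Cross-linking-relevant residue fractions
#'
#' Fractions of the five residues implicated in cornification chemistry:
#' cysteine (disulfide bonds), lysine and glutamine (transglutamination),
#' plus proline and serine, which dominate the repeat tails. A subset view
#' of [residue_profile()]; residues absent from the sequence report 0.
#'
#' @inheritParams residue_profile
#' @return Named numeric vector over `C, K, Q, P, S`.
#' @examples
#' crosslink_profile("CCDPCQKP")
#' @export
crosslink_profile <- function(seq, include_x = TRUE) {
  prof <- residue_profile(seq, include_x = include_x)
  res <- c("C", "K", "Q", "P", "S")
  out <- setNames(numeric(5), res)
  present <- intersect(res, names(prof$fractions))
  out[present] <- prof$fractions[present]
  out
}

#' CC-dipeptide sites and their periodicity
#'
#' Consecutive-cysteine (CC) dipeptides are the presumptive disulfide
#' cross-linking hot spots of EDCRP/KRTAP-class proteins and recur with a
#' spacing of about 8-11 residues. A site is the 0-based start of each
#' maximal run of two or more consecutive cysteines (a run `CCC...` counts
#' once, at its start, which keeps spacings well defined); spacings are
#' successive start-to-start distances; `in_band_fraction` is the share of
#' spacings inside the closed band (0 when there are fewer than two sites).
#'
#' @param seq Protein sequence.
#' @param band Closed spacing band, default `c(8, 11)`.
#' @return A `cc_periodicity` object: list with `sites`, `spacings`,
#'   `in_band_fraction`, `n_sites`, `median_spacing` and `band`.
#' @examples
#' cc_periodicity("CCDPCQKPCCDPCQQSVCC")
#' @export
cc_periodicity <- function(seq, band = c(8L, 11L)) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L,
            length(band) == 2L, band[1] <= band[2])
  m <- gregexpr("C{2,}", seq)[[1]]
  sites <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  spacings <- if (length(sites) >= 2L) diff(sites) else integer(0)
  structure(
    list(sites = sites, spacings = spacings,
         in_band_fraction = if (length(spacings)) {
           mean(spacings >= band[1] & spacings <= band[2])
         } else {
           0
         },
         n_sites = length(sites),
         median_spacing = if (length(spacings)) median(spacings) else NA_real_,
         band = as.integer(band)),
    class = "cc_periodicity"
  )
}

#' Composition and CC-periodicity table for a set of records
#'
#' One row per record: length, percentages of the cross-linking residues,
#' cysteine percent (exact and integer-rounded), CC site count, median CC
#' spacing and the in-band fraction. This is the table `cmd_scan()` writes
#' as `composition.tsv`.
#'
#' @param records Tibble with `id` and `seq` columns.
#' @param band CC spacing band, passed to [cc_periodicity()].
#' @param include_x Passed to [residue_profile()].
#' @return Tibble, one row per record.
#' @export
profile_composition <- function(records, band = c(8L, 11L),
                                include_x = TRUE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  purrr::map2_dfr(records$id, records$seq, function(id, seq) {
    prof <- residue_profile(seq, include_x = include_x)
    xl <- crosslink_profile(seq, include_x = include_x)
    cc <- cc_periodicity(seq, band = band)
    tibble(
      id = id, length = prof$length,
      pct_C = 100 * xl[["C"]], pct_K = 100 * xl[["K"]],
      pct_Q = 100 * xl[["Q"]], pct_P = 100 * xl[["P"]],
      pct_S = 100 * xl[["S"]],
      cys_percent = prof$cys_percent,
      cys_percent_rounded = prof$cys_percent_rounded,
      n_cc_sites = cc$n_sites,
      median_cc_spacing = cc$median_spacing,
      cc_in_band_fraction = cc$in_band_fraction
    )
  })
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile>", x$length, "aa, Cys",
      sprintf("%.1f%%", x$cys_percent),
      sprintf("(rounded %d%%)\n", x$cys_percent_rounded))
  invisible(x)
}

#' @export
print.cc_periodicity <- function(x, ...) {
  cat("<cc_periodicity>", x$n_sites, "CC sites;",
      length(x$spacings), "spacings, ",
      sprintf("%.0f%%", 100 * x$in_band_fraction),
      sprintf("in [%d,%d]\n", x$band[1], x$band[2]))
  invisible(x)
}
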