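#' Classify a proximal promoter by core TATA element
#'
#' Scans the given strand of a promoter sequence inside a window relative to
#' the transcription start site (TSS) for a canonical TATA box
#' (`TATAAA`/`TATAAAA` by default) or, failing that, the TATA-like element
#' `AATAAAA` that replaces the canonical box in most avian EDCRP promoters.
#' A canonical match anywhere in the window wins over a TATA-like match
#' (longest motif preferred, then most upstream). Matches must lie entirely
#' inside the window; sequence outside the window never affects the result,
#' and the reverse strand is never searched.
#'
#' When `tss_index` is `NULL` a fallback mode anchors the window at the
#' 3' end of the sequence and flags the annotation as approximate.
#'
#' @param seq Promoter DNA sequence (uppercase `A,C,G,T,N`).
#' @param tss_index 0-based TSS position within `seq`, or `NULL`.
#' @param window Scan window as offsets relative to the TSS, 0-based
#'   half-open; default `c(-100, -15)` generously brackets the typical
#'   core-promoter TATA position near -30.
#' @param canonical_motifs Exact-match canonical TATA motifs.
#' @param tata_like_motif Exact-match TATA-like element.
#' @return One-row tibble: `element_class` (`canonical_tata`, `tata_like`
#'   or `none`), `motif` (`NA` when none), `position` (motif start relative
#'   to the TSS, negative upstream), `window_start`, `window_end`,
#'   `approximate`.
#' @examples
#' p <- generate_promoter(seed = 1, element = "tata_like", position = -30)
#' scan_promoter(p$seq, p$tss_index)
#' @export
scan_promoter <- function(seq, tss_index, window = c(-100L, -15L),
                          canonical_motifs = c("TATAAA", "TATAAAA"),
                          tata_like_motif = "AATAAAA") {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L,
            length(window) == 2L, window[1] < window[2])
  if (missing(tss_index)) {
    stop("tss_index is required (pass NULL explicitly for the ",
         "3'-anchored fallback mode)", call. = FALSE)
  }
  approximate <- FALSE
  if (is.null(tss_index) || is.na(tss_index)) {
    tss_index <- nchar(seq)
    approximate <- TRUE
  }
  tss_index <- as.integer(tss_index)
  if (!approximate && (tss_index < 0L || tss_index >= nchar(seq))) {
    stop("tss_index ", tss_index, " outside sequence [0, ", nchar(seq), ")",
         call. = FALSE)
  }
  w0 <- tss_index + as.integer(window[1])
  w1 <- tss_index + as.integer(window[2])
  if (w0 < 0L || w1 > nchar(seq)) {
    stop("scan window [", w0, ", ", w1, ") outside sequence [0, ",
         nchar(seq), ")", call. = FALSE)
  }
  region <- substr(seq, w0 + 1L, w1)

  hit <- find_window_motif(region, canonical_motifs)
  cls <- "canonical_tata"
  if (is.null(hit)) {
    hit <- find_window_motif(region, tata_like_motif)
    cls <- "tata_like"
  }
  if (is.null(hit)) {
    return(tibble(element_class = "none", motif = NA_character_,
                  position = NA_integer_, window_start = window[1],
                  window_end = window[2], approximate = approximate))
  }
  tibble(element_class = cls, motif = hit$motif,
         position = as.integer(w0 + hit$offset - tss_index),
         window_start = as.integer(window[1]),
         window_end = as.integer(window[2]), approximate = approximate)
}

# All occurrences of the motifs fully inside `region`; longest motif
# preferred, then most upstream. NULL when absent.
find_window_motif <- function(region, motifs) {
  hits <- purrr::map_dfr(motifs, function(m) {
    p <- gregexpr(m, region, fixed = TRUE)[[1]]
    if (p[1] == -1L) return(tibble())
    tibble(motif = m, offset = as.integer(p) - 1L, len = nchar(m))
  })
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$len, hits$offset), ]
  list(motif = hits$motif[1], offset = hits$offset[1])
}

#' Classify a table of promoter records
#'
#' Row-wise [scan_promoter()]. The TSS comes from a `tss_index` column in
#' `records`, or from the `tss` argument (a single integer applied to all
#' records, or a tibble of `id`, `tss_index` to join — the "sidecar"
#' format written next to promoter FASTA files).
#'
#' @param records Tibble with `id`, `seq` and optionally `tss_index`.
#' @param tss Optional uniform TSS (integer) or sidecar tibble.
#' @inheritParams scan_promoter
#' @return Tibble with one annotation row per record, keyed by `id`.
#' @export
scan_promoters <- function(records, tss = NULL, window = c(-100L, -15L),
                           canonical_motifs = c("TATAAA", "TATAAAA"),
                           tata_like_motif = "AATAAAA") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (!is.null(tss)) {
    if (is.data.frame(tss)) {
      records <- dplyr::left_join(
        dplyr::select(records, -dplyr::any_of("tss_index")),
        dplyr::select(tss, "id", "tss_index"), by = "id")
    } else {
      records$tss_index <- as.integer(tss)
    }
  }
  if (!"tss_index" %in% names(records)) {
    stop("no TSS available: provide a 'tss_index' column or 'tss'",
         call. = FALSE)
  }
  purrr::map2_dfr(records$id, seq_len(nrow(records)), function(id, i) {
    ann <- scan_promoter(records$seq[i],
                         tss_index = records$tss_index[i],
                         window = window,
                         canonical_motifs = canonical_motifs,
                         tata_like_motif = tata_like_motif)
    dplyr::bind_cols(tibble(id = id), ann)
  })
}
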