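#' Read a protein or DNA FASTA file into a tibble
#'
#' Reads plain or multi-line FASTA (CRLF endings tolerated), normalizes
#' sequences to uppercase, and validates them against the requested alphabet.
#' The first whitespace-delimited token of each header becomes `id`; the
#' remainder, if any, becomes `species`. `'*'` stop symbols are stripped with
#' a warning. For protein input containing `'-'` gap characters the file is
#' treated as an alignment and returned with an `aligned_seq` column instead
#' of `seq`; pass the result through [degap()] to obtain ungapped records.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (20 amino acids plus `X`) or `"dna"`
#'   (`A,C,G,T,N`).
#' @return A tibble with columns `id`, `species` and `seq` (protein), `id`,
#'   `species`, `aligned_seq` (gapped protein alignment), or `id`, `seq`
#'   (DNA).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a Gallus gallus", "CCDPCQKP"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(gsub("[\r\n\t ]", "", as.character(set))))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop symbols from ",
            sum(grepl("*", seqs, fixed = TRUE)), " record(s)", call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (alphabet == "protein") {
    if (any(grepl("-", seqs, fixed = TRUE))) {
      check_alphabet(gsub("-", "", seqs, fixed = TRUE), id, PROTEIN_ALPHABET,
                     allow_empty = TRUE)
      return(tibble(id = id, species = species, aligned_seq = seqs))
    }
    check_alphabet(seqs, id, PROTEIN_ALPHABET)
    tibble(id = id, species = species, seq = seqs)
  } else {
    check_alphabet(seqs, id, DNA_ALPHABET)
    tibble(id = id, seq = seqs)
  }
}

check_alphabet <- function(seqs, ids, alphabet, allow_empty = FALSE) {
  for (i in seq_along(seqs)) {
    if (!allow_empty && nchar(seqs[i]) == 0L) {
      stop("record '", ids[i], "' has an empty sequence", call. = FALSE)
    }
    chars <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, alphabet)
    if (length(bad) > 0L) {
      stop("record '", ids[i], "' contains illegal character '", bad[1], "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Remove alignment gaps from aligned protein records
#'
#' Drops every `'-'` from `aligned_seq`, preserving `id` and `species`.
#' Residue order is untouched, so the result is always a subsequence of the
#' aligned input.
#'
#' @param records Tibble with columns `id`, `species`, `aligned_seq` (as
#'   returned by [read_fasta()] for a gapped file).
#' @return Tibble with columns `id`, `species`, `seq`.
#' @examples
#' degap(tibble::tibble(id = "a", species = "", aligned_seq = "C-C-D"))
#' @export
degap <- function(records) {
  stopifnot(is.data.frame(records), "aligned_seq" %in% names(records))
  seqs <- gsub("-", "", records$aligned_seq, fixed = TRUE)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("record '", records$id[which(empty)[1]],
         "' is empty after gap removal", call. = FALSE)
  }
  species <- if ("species" %in% names(records)) records$species else ""
  tibble(id = records$id, species = species, seq = seqs)
}

#' Write protein or DNA records to FASTA
#'
#' Headers are `id` followed, when non-empty, by a space and `species`.
#' Inverse of [read_fasta()] on valid record tibbles.
#'
#' @param records Tibble with `id`, optional `species`, and one of `seq` or
#'   `aligned_seq`.
#' @param path Output file path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records))
  seq_col <- intersect(c("seq", "aligned_seq"), names(records))[1]
  if (is.na(seq_col)) stop("no 'seq' or 'aligned_seq' column", call. = FALSE)
  species <- if ("species" %in% names(records)) {
    records$species
  } else {
    rep("", nrow(records))
  }
  headers <- ifelse(nchar(species) > 0L,
                    paste(records$id, species), records$id)
  set <- Biostrings::BStringSet(setNames(records[[seq_col]], headers))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
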