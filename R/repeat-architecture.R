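#' Default repeat-type inventory
#'
#' Repeat units are typed by the residues C-terminal of the `CCDPCQ` core
#' (the "tail"). The default inventory encodes the four main avian EDCRP
#' repeat types, with threonine/serine treated as equivalent at the T/S
#' position and an optional trailing valine folded into one label:
#' `KP`, `K(T/S)V`, `(T/S)`, and `QS(V)`. Classification is deterministic:
#' the first matching rule wins, an empty tail is `CORE_ONLY`, and anything
#' unmatched is `OTHER`.
#'
#' @return A tibble with columns `pattern` (anchored regular expression on
#'   the tail) and `label`.
#' @export
default_inventory <- function() {
  tibble(
    pattern = c("^KP$", "^K[TS]V$", "^[TS]$", "^QSV?$"),
    label   = c("KP", "K(T/S)V", "(T/S)", "QS(V)")
  )
}

#' The four main repeat-unit strings of avian EDCRP
#'
#' Full unit strings (core plus tail) for the four main repeat types:
#' `CCDPCQKP`, `CCDPCQKTV`, `CCDPCQT`, and `CCDPCQQSV` (the T/S position is
#' instantiated with T, the optional valine included).
#'
#' @return Named character vector; names are the type labels.
#' @export
main_repeat_units <- function() {
  c("KP"      = "CCDPCQKP",
    "K(T/S)V" = "CCDPCQKTV",
    "(T/S)"   = "CCDPCQT",
    "QS(V)"   = "CCDPCQQSV")
}

#' Locate CCDPCQ core matches in a protein sequence
#'
#' Greedy left-to-right scan for non-overlapping occurrences of the repeat
#' core. A window of `nchar(core)` residues matches when its first
#' `exact_prefix_len` residues equal the core prefix exactly (the conserved
#' CC anchor) and the total number of mismatches over the window is at most
#' `max_mismatch`. `X` (unknown residue) always counts as a mismatch. After
#' a match the scan resumes at the match end, so accepted cores never
#' overlap; ties are resolved leftmost-first and the scan is deterministic.
#'
#' @param seq Protein sequence (single uppercase string).
#' @param core Core motif, default `"CCDPCQ"`.
#' @param max_mismatch Maximum mismatches per accepted window.
#' @param exact_prefix_len Number of leading core positions that must match
#'   exactly (default 2, the CC anchor).
#' @return Tibble with 0-based `start` and `mismatches`, sorted by `start`.
#' @examples
#' find_cores("CCDPCQKPCCDPCQQSV", max_mismatch = 0)
#' @export
find_cores <- function(seq, core = "CCDPCQ", max_mismatch = 1L,
                       exact_prefix_len = 2L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(core) > 0L,
            max_mismatch >= 0L, exact_prefix_len >= 0L,
            exact_prefix_len <= nchar(core))
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- strsplit(core, "", fixed = TRUE)[[1]]
  L <- length(k)
  n <- length(s)
  starts <- integer(0)
  mms <- integer(0)
  i <- 1L
  while (i + L - 1L <= n) {
    w <- s[i:(i + L - 1L)]
    miss <- (w != k) | (w == "X")
    if (exact_prefix_len > 0L && any(miss[seq_len(exact_prefix_len)])) {
      i <- i + 1L
      next
    }
    m <- sum(miss)
    if (m <= max_mismatch) {
      starts <- c(starts, i - 1L)
      mms <- c(mms, m)
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  tibble(start = as.integer(starts), mismatches = as.integer(mms))
}

#' Classify a repeat-unit tail into a type label
#'
#' Applies the inventory rules in order; the first matching pattern wins.
#' Empty tails are labelled `CORE_ONLY`; tails matching no rule, `OTHER`.
#' Vectorized over `tail`.
#'
#' @param tail Character vector of tails (0-4 residues each).
#' @param inventory Tibble of `(pattern, label)` rules; see
#'   [default_inventory()].
#' @return Character vector of labels.
#' @examples
#' classify_tail(c("KP", "KSV", "QW", ""))
#' @export
classify_tail <- function(tail, inventory = default_inventory()) {
  stopifnot(is.character(tail))
  if (any(nchar(tail) > 4L)) {
    stop("tail longer than 4 residues: '", tail[nchar(tail) > 4L][1], "'",
         call. = FALSE)
  }
  vapply(tail, function(t) {
    if (nchar(t) == 0L) return("CORE_ONLY")
    for (r in seq_len(nrow(inventory))) {
      if (grepl(inventory$pattern[r], t)) return(inventory$label[r])
    }
    "OTHER"
  }, character(1), USE.NAMES = FALSE)
}

# substring with 0-based half-open coordinates
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

#' Segment a sequence into repeat units around located cores
#'
#' Builds the full architecture from a core list: the N-terminal segment is
#' everything before the first core; each unit starts at its core and, when
#' the gap to the next core is at most `core length + max_tail`, extends to
#' the next core start (the intervening residues are the unit's tail);
#' larger gaps truncate the unit at `core + max_tail` and record the surplus
#' as a linker, so irregular regions are flagged rather than silently
#' absorbed. The last unit's tail is the longest stretch of at most
#' `max_tail` residues after its core that matches an inventory rule; if
#' none does, the tail is empty and the residues fall to the C-terminal
#' segment. Concatenating N-terminus, units and linkers in coordinate
#' order, and C-terminus always reproduces the input exactly.
#'
#' @param seq Protein sequence.
#' @param cores Tibble from [find_cores()] (sorted, non-overlapping).
#' @param max_tail Maximum tail length in residues (default 4).
#' @param inventory Type inventory for tail classification.
#' @param core_length Core motif length (default 6).
#' @return A `repeat_architecture` object; see [decompose()].
#' @export
segment_units <- function(seq, cores, max_tail = 4L,
                          inventory = default_inventory(),
                          core_length = 6L) {
  n <- nchar(seq)
  empty_units <- tibble(start = integer(0), end = integer(0),
                        core_start = integer(0), tail = character(0),
                        type_label = character(0))
  empty_linkers <- tibble(start = integer(0), end = integer(0),
                          seq = character(0))
  if (nrow(cores) == 0L) {
    return(new_architecture(seq, nterm = seq, units = empty_units,
                            linkers = empty_linkers, cterm = "",
                            n_cores = 0L, inventory = inventory))
  }
  starts <- as.integer(cores$start)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(diff(starts) < core_length)) {
    stop("cores must be sorted and non-overlapping", call. = FALSE)
  }
  if (starts[length(starts)] + core_length > n) {
    stop("core extends past end of sequence", call. = FALSE)
  }
  m <- length(starts)
  unit_start <- integer(m)
  unit_end <- integer(m)
  linkers <- empty_linkers
  for (i in seq_len(m)) {
    unit_start[i] <- starts[i]
    if (i < m) {
      g <- starts[i + 1L] - starts[i]
      if (g <= core_length + max_tail) {
        unit_end[i] <- starts[i + 1L]
      } else {
        unit_end[i] <- starts[i] + core_length + max_tail
        linkers <- dplyr::bind_rows(linkers, tibble(
          start = unit_end[i], end = starts[i + 1L],
          seq = substr0(seq, unit_end[i], starts[i + 1L])))
      }
    } else {
      core_end <- starts[i] + core_length
      tail <- ""
      for (L in rev(seq_len(min(max_tail, n - core_end)))) {
        cand <- substr0(seq, core_end, core_end + L)
        if (classify_tail(cand, inventory) != "OTHER") {
          tail <- cand
          break
        }
      }
      unit_end[i] <- core_end + nchar(tail)
    }
  }
  units <- tibble(
    start = unit_start, end = unit_end, core_start = unit_start,
    tail = vapply(seq_len(m), function(i) {
      substr0(seq, unit_start[i] + core_length, unit_end[i])
    }, character(1))
  )
  units$type_label <- classify_tail(units$tail, inventory)
  new_architecture(seq, nterm = substr0(seq, 0L, starts[1]),
                   units = units, linkers = linkers,
                   cterm = substr0(seq, unit_end[m], n),
                   n_cores = m, inventory = inventory)
}

new_architecture <- function(seq, nterm, units, linkers, cterm, n_cores,
                             inventory) {
  type_counts <- if (nrow(units)) {
    tab <- table(units$type_label)
    setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(
    list(seq = seq, nterm = nterm, units = units, linkers = linkers,
         cterm = cterm, n_repeats = nrow(units), n_cores = n_cores,
         type_counts = type_counts,
         alternation = alternation_stats(units$type_label)),
    class = "repeat_architecture"
  )
}

#' Longest two-label alternation run in a label sequence
#'
#' Finds the longest contiguous stretch of unit labels that strictly
#' alternates between exactly two distinct labels (`A,B,A,B,...`), the
#' regular arrangement seen in some EDCRPs — e.g. the saker falcon, where
#' KP and QS(V) units alternate 14 times. `n_pairs` is
#' `floor(run_length / 2)`. Ties are broken by the earliest run start;
#' fewer than two units (or no two adjacent distinct labels) yield
#' `n_pairs = 0` with absent `pair_labels`.
#'
#' @param labels Character vector of unit type labels in order.
#' @return A one-row tibble with list-column `pair_labels` (length-2
#'   character vector or `NULL`), `n_pairs`, `run_start_unit` (0-based) and
#'   `run_length`.
#' @examples
#' alternation_stats(c("A", "B", "A", "B", "A", "B"))
#' @export
alternation_stats <- function(labels) {
  n <- length(labels)
  if (n == 0L) {
    return(tibble(pair_labels = list(NULL), n_pairs = 0L,
                  run_start_unit = 0L, run_length = 0L))
  }
  best_start <- 0L
  best_len <- 1L
  best_pair <- NULL
  for (st in seq_len(n)) {
    if (st < n && labels[st] != labels[st + 1L]) {
      a <- labels[st]
      b <- labels[st + 1L]
      j <- st + 1L
      while (j < n) {
        nxt <- if ((j + 1L - st) %% 2L == 0L) a else b
        if (labels[j + 1L] == nxt) j <- j + 1L else break
      }
      len <- j - st + 1L
      if (len > best_len) {
        best_len <- len
        best_start <- st - 1L
        best_pair <- c(a, b)
      }
    }
  }
  tibble(pair_labels = list(best_pair), n_pairs = best_len %/% 2L,
         run_start_unit = best_start, run_length = best_len)
}

#' Decompose a cysteine-rich protein into its repeat architecture
#'
#' End-to-end decomposition: locates `CCDPCQ` cores ([find_cores()]),
#' segments the sequence into N-terminus, typed repeat units, linkers and
#' C-terminus ([segment_units()]), classifies each unit's tail
#' ([classify_tail()]) and summarizes type counts and alternation
#' ([alternation_stats()]).
#'
#' @param x A protein sequence string, or a one-row tibble with a `seq`
#'   column (e.g. a row from [read_fasta()]).
#' @param core,max_mismatch,exact_prefix_len Passed to [find_cores()].
#' @param max_tail,inventory Passed to [segment_units()].
#' @return A `repeat_architecture` object: a list with elements `seq`,
#'   `nterm`, `units` (tibble with 0-based half-open `start`/`end`, `tail`,
#'   `type_label`), `linkers`, `cterm`, `n_repeats`, `n_cores`,
#'   `type_counts` and `alternation`. Use [tidy()][tidy.repeat_architecture]
#'   for the unit table and [glance()][glance.repeat_architecture] for a
#'   one-row summary.
#' @examples
#' arch <- decompose(paste(main_repeat_units(), collapse = ""))
#' arch$n_repeats
#' @export
decompose <- function(x, core = "CCDPCQ", max_mismatch = 1L,
                      exact_prefix_len = 2L, max_tail = 4L,
                      inventory = default_inventory()) {
  seq <- if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "seq" %in% names(x))
    x$seq
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    x
  }
  cores <- find_cores(seq, core = core, max_mismatch = max_mismatch,
                      exact_prefix_len = exact_prefix_len)
  arch <- segment_units(seq, cores, max_tail = max_tail,
                        inventory = inventory, core_length = nchar(core))
  if (is.data.frame(x) && "id" %in% names(x)) arch$id <- x$id
  arch
}

#' Decompose every protein in a record table
#'
#' Data-frame-first wrapper around [decompose()]: one row in, one row out,
#' with per-record architecture summaries and the full `repeat_architecture`
#' object in a list-column.
#'
#' @param records Tibble with columns `id` and `seq` (and optionally
#'   `species`), as returned by [read_fasta()].
#' @inheritParams decompose
#' @return Tibble with one row per record: `id`, `species`, `length`,
#'   `n_repeats`, `n_cores`, `n_types`, `nterm_len`, `cterm_len`,
#'   `alt_pairs`, `alt_run_length` and list-column `architecture`.
#' @export
scan_proteins <- function(records, core = "CCDPCQ", max_mismatch = 1L,
                          exact_prefix_len = 2L, max_tail = 4L,
                          inventory = default_inventory()) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  archs <- purrr::map(records$seq, decompose, core = core,
                      max_mismatch = max_mismatch,
                      exact_prefix_len = exact_prefix_len,
                      max_tail = max_tail, inventory = inventory)
  summaries <- purrr::map(archs, glance)
  out <- dplyr::bind_cols(
    tibble(id = records$id,
           species = if ("species" %in% names(records)) {
             records$species
           } else {
             ""
           }),
    dplyr::bind_rows(summaries)
  )
  out$architecture <- archs
  out
}

#' @export
print.repeat_architecture <- function(x, ...) {
  cat("<repeat_architecture>", nchar(x$seq), "aa\n")
  cat("  N-terminus:", nchar(x$nterm), "aa | repeats:", x$n_repeats,
      "| C-terminus:", nchar(x$cterm), "aa\n")
  if (length(x$type_counts)) {
    cat("  types:", paste(names(x$type_counts), x$type_counts,
                          sep = "=", collapse = ", "), "\n")
  }
  alt <- x$alternation
  if (alt$n_pairs[1] > 0L) {
    cat("  alternation:", paste(alt$pair_labels[[1]], collapse = "/"),
        "x", alt$n_pairs[1], "pairs\n")
  }
  invisible(x)
}

# Reconstruction check used by tests and cmd_benchmark: concatenating the
# segments in coordinate order must reproduce the input.
reconstruct_architecture <- function(arch) {
  pieces <- dplyr::bind_rows(
    tibble(start = arch$units$start,
           seq = vapply(seq_len(nrow(arch$units)), function(i) {
             substr0(arch$seq, arch$units$start[i], arch$units$end[i])
           }, character(1))),
    tibble(start = arch$linkers$start, seq = arch$linkers$seq)
  )
  pieces <- pieces[order(pieces$start), ]
  paste0(arch$nterm, paste(pieces$seq, collapse = ""), arch$cterm)
}
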