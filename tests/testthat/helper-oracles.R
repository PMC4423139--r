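# Independent brute-force oracles and random-sequence helpers shared by the
# unit and acceptance tests. These deliberately use naive enumeration,
# separate from the package's scanning code paths.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, cys_weight = 4) {
  prob <- rep(1, length(AA))
  prob[AA == "C"] <- cys_weight
  paste(sample(AA, n, replace = TRUE, prob = prob), collapse = "")
}

# Window predicate: exact anchor prefix, total mismatches <= max_mismatch,
# X always a mismatch.
window_valid <- function(chars, i, core_chars, max_mismatch,
                         exact_prefix_len) {
  L <- length(core_chars)
  if (i + L - 1L > length(chars)) return(NA_integer_)
  w <- chars[i:(i + L - 1L)]
  mm <- sum(w != core_chars | w == "X")
  if (exact_prefix_len > 0L &&
      any((w != core_chars | w == "X")[seq_len(exact_prefix_len)])) {
    return(NA_integer_)
  }
  if (mm <= max_mismatch) mm else NA_integer_
}

# Greedy scan re-done with per-window substring tests (no vectorized reuse
# of package internals).
oracle_find_cores <- function(seq, core = "CCDPCQ", max_mismatch = 1L,
                              exact_prefix_len = 2L) {
  chars <- strsplit(seq, "")[[1]]
  core_chars <- strsplit(core, "")[[1]]
  L <- length(core_chars)
  starts <- integer(0)
  mms <- integer(0)
  i <- 1L
  while (i + L - 1L <= length(chars)) {
    mm <- window_valid(chars, i, core_chars, max_mismatch, exact_prefix_len)
    if (!is.na(mm)) {
      starts <- c(starts, i - 1L)
      mms <- c(mms, mm)
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  list(start = starts, mismatches = mms)
}

# Backward dynamic program: maximum number of non-overlapping valid core
# windows in the sequence.
oracle_max_units <- function(seq, core = "CCDPCQ", max_mismatch = 1L,
                             exact_prefix_len = 2L) {
  chars <- strsplit(seq, "")[[1]]
  core_chars <- strsplit(core, "")[[1]]
  L <- length(core_chars)
  n <- length(chars)
  f <- integer(n + 1L)  # f[i] = best count using positions >= i (1-based)
  for (i in seq(n, 1L)) {
    best <- f[i + 1L]
    mm <- window_valid(chars, i, core_chars, max_mismatch, exact_prefix_len)
    if (!is.na(mm) && i + L <= n + 1L) {
      best <- max(best, 1L + if (i + L <= n) f[i + L] else 0L)
    }
    f[i] <- best
  }
  f[1]
}

# Exhaustive two-label alternation search over all substrings.
oracle_alternation <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(list(run_start = 0L, run_length = 0L, n_pairs = 0L))
  best_start <- 0L
  best_len <- 1L
  for (st in seq_len(n)) {
    for (en in st:n) {
      sub <- labels[st:en]
      len <- en - st + 1L
      if (len < 2L) next
      if (length(unique(sub)) != 2L) next
      if (any(sub[-1] == sub[-len])) next
      if (len > best_len) {
        best_len <- len
        best_start <- st - 1L
      }
    }
  }
  list(run_start = best_start, run_length = best_len,
       n_pairs = best_len %/% 2L)
}

# Maximal runs of >= 2 consecutive 'C' by explicit character walking.
oracle_cc_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sites <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "C") {
      j <- i
      while (j < length(chars) && chars[j + 1L] == "C") j <- j + 1L
      if (j - i + 1L >= 2L) sites <- c(sites, i - 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  sites
}

# Direct k-mer set builder for motif_similarity cross-checks.
oracle_kmers <- function(seqs, k, min_cys = 2L) {
  out <- character(0)
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (lengths(regmatches(km, gregexpr("C", km))) >= min_cys) {
        out <- c(out, km)
      }
    }
  }
  unique(out)
}
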