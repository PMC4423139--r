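#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeat architecture into its unit table
#'
#' @param x A `repeat_architecture` from [decompose()].
#' @param segments If `TRUE`, return every segment (N-terminus, units,
#'   linkers, C-terminus) as rows instead of units only.
#' @param ... Unused.
#' @return A tibble with 0-based half-open `start`/`end` coordinates.
#' @export
tidy.repeat_architecture <- function(x, segments = FALSE, ...) {
  units <- dplyr::bind_cols(
    tibble(segment = rep("unit", nrow(x$units))), x$units,
    tibble(length = x$units$end - x$units$start)
  )
  if (!segments) return(units)
  n <- nchar(x$seq)
  rows <- dplyr::bind_rows(
    if (nchar(x$nterm)) {
      tibble(segment = "nterm", start = 0L, end = nchar(x$nterm))
    },
    dplyr::select(units, "segment", "start", "end", "tail", "type_label"),
    if (nrow(x$linkers)) {
      tibble(segment = "linker", start = x$linkers$start,
             end = x$linkers$end)
    },
    if (nchar(x$cterm)) {
      tibble(segment = "cterm", start = n - nchar(x$cterm), end = n)
    }
  )
  rows$length <- rows$end - rows$start
  dplyr::arrange(rows, .data$start)
}

#' One-row summary of a repeat architecture
#'
#' @param x A `repeat_architecture`.
#' @param ... Unused.
#' @return Tibble with `length`, `n_repeats`, `n_cores`, `n_types`,
#'   `nterm_len`, `cterm_len`, `alt_pairs`, `alt_run_length`.
#' @export
glance.repeat_architecture <- function(x, ...) {
  tibble(
    length = nchar(x$seq),
    n_repeats = x$n_repeats,
    n_cores = x$n_cores,
    n_types = length(x$type_counts),
    nterm_len = nchar(x$nterm),
    cterm_len = nchar(x$cterm),
    alt_pairs = x$alternation$n_pairs,
    alt_run_length = x$alternation$run_length
  )
}

#' Tidy a composition profile into residue rows
#'
#' @param x A `composition_profile` from [residue_profile()].
#' @param ... Unused.
#' @return Tibble with `residue`, `count`, `fraction`.
#' @export
tidy.composition_profile <- function(x, ...) {
  tibble(residue = names(x$counts), count = unname(x$counts),
         fraction = unname(x$fractions))
}

#' One-row summary of a composition profile
#'
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @export
glance.composition_profile <- function(x, ...) {
  tibble(length = x$length, cys_percent = x$cys_percent,
         cys_percent_rounded = x$cys_percent_rounded)
}

#' Tidy CC-periodicity sites
#'
#' @param x A `cc_periodicity` from [cc_periodicity()].
#' @param ... Unused.
#' @return Tibble with `site` (0-based CC run start) and
#'   `spacing_to_next` (`NA` for the last site).
#' @export
tidy.cc_periodicity <- function(x, ...) {
  tibble(site = x$sites,
         spacing_to_next = c(x$spacings, NA_integer_)[seq_along(x$sites)])
}

#' One-row summary of CC periodicity
#'
#' @param x A `cc_periodicity`.
#' @param ... Unused.
#' @export
glance.cc_periodicity <- function(x, ...) {
  tibble(n_sites = x$n_sites, median_spacing = x$median_spacing,
         in_band_fraction = x$in_band_fraction)
}
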