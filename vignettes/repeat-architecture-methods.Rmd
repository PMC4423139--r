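---
title: "Methods: repeat architecture of cysteine-rich epidermal proteins"
author: "edcrp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat architecture of cysteine-rich epidermal proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcrp)
```

## The biological model

Hard skin appendages — feathers, hair, claws — are built from dead,
cornified keratinocytes whose proteins are covalently cross-linked, either
through disulfide bonds between cysteine residues or through
transglutamination of lysine and glutamine. Avian epidermal differentiation
cysteine-rich proteins (EDCRPs) and the cysteine-rich subset of mammalian
keratin-associated proteins (KRTAPs) sit at the extreme of this chemistry:
roughly a third of their residues are cysteines.

An EDCRP has a three-part architecture that this package makes executable:

* a short, unique **N-terminal segment** (8–20 residues);
* a **central region of tandem repeats**, 6–56 units of 7–9 (exceptionally
  10) residues, each anchored on the core hexapeptide `CCDPCQ` and typed by
  the residues C-terminal of the core (its *tail*): the main types are
  `KP`, `K(T/S)V`, `(T/S)` and `QS(V)`, and in some species two types
  alternate in long regular runs;
* a longer, unique **C-terminal segment** (52–75 residues).

Consecutive-cysteine (CC) dipeptides — the presumptive cross-linking hot
spots — recur along the whole protein with a spacing of about 8–11
residues. Gene-level evidence distinguishes homology from convergence:
EDCRP genes have a non-coding first exon and a coding second exon and sit
between *EDWM* and the loricrin genes of the epidermal differentiation
complex, whereas KRTAP genes are single-exon and live in keratin gene
clusters. Similar repeats in genes with discordant structure and disjoint
neighborhoods are better explained by convergent evolution.

## Segmentation procedure

`decompose()` composes four deterministic steps; all coordinates throughout
the package are 0-based, half-open.

1. **Core scan** (`find_cores()`). A greedy left-to-right scan accepts a
   6-residue window when its first `exact_prefix_len = 2` residues equal
   the `CC` anchor exactly and the window has at most `max_mismatch = 1`
   mismatches in total; `X` (a residue unknown because of genome-assembly
   gaps) never matches. The scan resumes at the end of each accepted match,
   so cores never overlap, and ties are always resolved leftmost-first. The
   exact CC anchor prevents spurious matches inside the cysteine-rich
   termini. Because all windows have equal length, greedy earliest-fit
   provably maximizes the number of non-overlapping cores; the test suite
   verifies this against an exhaustive dynamic program on short sequences.
2. **Unit segmentation** (`segment_units()`). The N-terminus is everything
   before the first core. For consecutive cores with gap *g*, a unit spans
   the whole gap when *g* is at most `6 + max_tail` (default `max_tail = 4`);
   larger gaps truncate the unit at core + `max_tail` and record the surplus
   explicitly as a *linker*, so irregular regions are flagged rather than
   silently absorbed. The last unit's tail is the longest stretch of at most
   `max_tail` residues after its core that matches an inventory rule; if
   none matches, the tail is empty and the remaining residues belong to the
   C-terminus. This last-unit rule is a package design choice: it keeps the
   repeat/C-terminus boundary well defined and testable where the
   underlying biology offers no sharp criterion.
3. **Tail typing** (`classify_tail()`). An ordered rule list maps tails to
   labels; the first matching rule wins, empty tails are `CORE_ONLY`, and
   unmatched tails are `OTHER`. The default inventory treats T and S as
   equivalent at the T/S position and folds an optional trailing V into the
   same label, which is how the field writes these types (`K(T/S)V`,
   `QS(V)`); the inventory is a configurable table, so stricter typings
   that would raise the per-species type count are one argument away.
4. **Alternation** (`alternation_stats()`). The longest contiguous run of
   units whose labels strictly alternate between exactly two labels, ties
   broken by the earliest start; `n_pairs` is `floor(run_length / 2)`.

The key invariant, checked on every input class the tests generate:
concatenating N-terminus, units and linkers in coordinate order, and
C-terminus reproduces the input exactly. Because the repeat count is
ambiguous between "core occurrences" and "fully typed units", results
report both `n_cores` and `n_repeats` (they coincide under the default
segmentation).

## Composition and CC periodicity

`residue_profile()` counts every residue; `X` positions are included by
default (`include_x = FALSE` excludes them, since it is unknowable whether
published percentages for partial sequences counted them). Cysteine percent
is reported on the 0–100 scale with an integer rounding that uses
round-half-away-from-zero, so values compare directly to printed whole-number
percentages. A CC *site* is the start of each maximal run of two or more
consecutive cysteines — a run `CCC…` counts once, at its start, which keeps
successive spacings well defined — and `cc_periodicity()` reports the
fraction of spacings inside the closed band [8, 11].

## Promoter classification

`scan_promoter()` searches the given strand only, inside a window relative
to the declared TSS, for exact-match core elements: a canonical TATA box
(`TATAAA`/`TATAAAA`) or, failing that, the TATA-like element `AATAAAA`. A
canonical match anywhere in the window takes precedence; among canonical
matches the longer motif and then the most-upstream position win. Exact
matching (no position-weight matrix) reflects that the biological argument
rests on presence/absence of discrete elements, not on scores. The default
window of (−100, −15) generously brackets the typical core-promoter TATA
position near −30; no published window exists for these genes, so the
window is a configuration value. With an unknown TSS, a fallback mode
anchors the window at the 3′ end of the sequence and flags the annotation
as approximate.

## The homology-versus-convergence verdict

`convergence_verdict()` operationalizes a qualitative argument as a pure
function of three scores:

* `motif_similarity()`: Jaccard index of the families' unions of 5-mer
  sets, restricted to k-mers with at least two cysteines. The restriction
  targets the shared cysteine-rich motif signal in these low-complexity
  sequences; unrestricted k-mer sharing would be dominated by the skewed
  residue composition. When neither family contributes any such k-mer the
  similarity is defined as 0.
* `structure_signature()` equality: exon count, coding-exon count, and
  presence of a non-coding first exon.
* `synteny_jaccard()`: Jaccard of up to `k_neighbors = 3` flanking gene
  names per side, case-insensitive exact match.

Similarity above `ms_min` with concordant structure and synteny at least
`sj_min` supports homology; similarity above `ms_min` with discordant
structure and synteny below `sj_min` supports convergence; everything else
is indeterminate — deliberately including the unresolved case of genes with
concordant structure but lost synteny, where gene loss and convergence
cannot be distinguished. The thresholds `ms_min = 0.05` and `sj_min = 0.34`
are package defaults chosen so that one shared neighbor out of three per
side (Jaccard 1/3) does not count as conserved synteny and that the
similarity gate requires a non-trivial shared motif vocabulary; they are
configuration values, not published quantities, and the verdict should be
read with that in mind.

## The synthetic-data generator

`generate_edcrp_like()` emits `N-terminus + units + C-terminus` from a
`repeat_plan()` (exact unit strings, arrangement: as listed, alternating,
or random) and records the truth architecture before applying noise.
Defaults mirror the study conditions: unit counts in [6, 56], unit lengths
in [7, 10], N-termini of 8–20 and C-termini of 52–75 residues, and terminal
segments sampled with cysteine fraction 0.25 (the remainder drawn from
K, Q, P, S, V, D, G, L, the residues that dominate real termini).

Two generator details matter for interpretation:

* **Clean-terminal rejection.** Terminal segments are resampled (bounded
  retries) until the assembled zero-noise sequence's core scan returns
  exactly the planned core grid. Random cysteine-rich termini occasionally
  contain chance `CCDPCQ`-like windows; without rejection the recorded
  truth would not be the decomposition of the emitted sequence and
  exact-recovery benchmarks would be meaningless.
* **Composition band.** For plans built from the four main unit types the
  zero-noise cysteine content falls in the observed 29–38% band at
  realistic repeat counts (about 20 units and up). At the extreme corner of
  the parameter space — 6 units with maximal 20 + 75 terminals — the
  expected content sits just below 29% under the default terminal
  composition, and the generator emits a warning whenever a sequence
  leaves the band rather than silently re-weighting.

`mutate_seq()` applies independent per-position substitutions (to a
uniformly chosen different residue) and single-residue indels (equal chance
of deletion or insertion). `generate_promoter()` plants one element into a
uniform A/C/G/T background and rejection-filters the scan window so no
unintended motif instance (including planting-junction artifacts) remains.

What the generator does **not** emulate: phylogenetic correlation between
sequences, conserved terminal motifs (termini are random-composition),
codon-level or nucleotide evolution, and the inter-species length variation
of linkers. Passing recovery benchmarks therefore demonstrates that the
segmentation machinery is correct under the stated noise model, not that it
will segment any real proteome perfectly.

## Problem sizes and numerical choices

The test suite exercises: exact recovery across the full parameter grid
(units ∈ {6, 20, 56} × N-terminus ∈ {8, 20} × C-terminus ∈ {52, 75});
reconstruction on 1,000 random and synthetic sequences; greedy-versus-DP
equality on 50 sequences of at most 60 residues; alternation against an
exhaustive substring oracle on 200 label lists; boundary recovery at a 2%
substitution rate over 100 replicates (observed mean ≈ 0.96 against the
0.95 bar); and a 300-promoter planted-truth confusion matrix. These sizes
were chosen to pin the properties tightly while keeping the default test
run comfortably fast on a single CPU.

Tie-breaks are leftmost-first everywhere; all scans are deterministic; all
randomness flows through explicit integer seeds recorded in the synthetic
truth, so every figure and benchmark in the package is exactly
reproducible.

## Known limitations

* Repeat detection is motif-anchored, not profile- or HMM-based: a unit
  whose CC anchor is mutated is invisible, which is the dominant failure
  mode at nonzero substitution rates.
* Indel noise shifts coordinates, so boundary-recovery benchmarks are
  defined only for substitution-only noise.
* The verdict thresholds encode a qualitative published argument; they are
  not fitted to data and should not be over-interpreted near the
  boundaries.
* Promoter classification is exact-match on a declared strand and TSS; it
  performs no TSS prediction and no general core-promoter cataloguing.
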