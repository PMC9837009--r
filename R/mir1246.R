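# Worked-example constants for the hsa-miR-1246 EXO-motif study.

#' The native hsa-miR-1246 mimic sequence
#'
#' 5'-AAUGGAUUUUUGGAGCAGG-3' (19 nt; miRBase MIMAT0005898). The two
#' overlapping EXO-motifs GGAG (positions 12-15) and GCAG (15-18) share the G
#' at position 15.
#' @return An `rna_sequence` with id `"0"` (the native sequence's
#'   conventional id in the variant study).
#' @export
mir1246_sequence <- function() {
  normalize_sequence("AAUGGAUUUUUGGAGCAGG", id = "0")
}

#' The GGAG EXO-motif window of miR-1246 (positions 12-15)
#' @export
mir1246_window <- function() {
  motif_window(12L, 15L, "GGAG", sequence = mir1246_sequence())
}

#' Default catalogue of EXO-motif patterns
#'
#' A small set of short motifs reported as enriched in extracellular-vesicle
#' miRNAs and used as the exclusion list when designing control probes that
#' must carry one EXO-motif only. User-supplied lists can replace it.
#' @return Character vector of IUPAC RNA patterns.
#' @export
exo_motif_patterns <- function() {
  c("GGAG", "GCAG", "UGAG", "CCCU", "UCCU")
}

#' Internal-to-published variant id aliases for the miR-1246 study
#'
#' [enumerate_motif_variants()] numbers variants deterministically (positions
#' 5'-to-3', alternative bases A<C<G<U). The published study's own numbering
#' of the 12 variants is only partially recoverable from its text; the three
#' variants it pins explicitly are A14C (published 5), G15C (published 6) and
#' G15U (published 7). This table maps the internal ids of those variants to
#' the published ids; it is also shipped as
#' `inst/extdata/mir1246_paper_aliases.tsv`.
#' @return Data frame with columns `internal_id`, `published_id`, `label`.
#' @export
mir1246_paper_aliases <- function() {
  data.frame(
    internal_id = c(7L, 11L, 12L),
    published_id = c(5L, 6L, 7L),
    label = c("A14C", "G15C", "G15U"),
    stringsAsFactors = FALSE
  )
}

#' Published binding-site counts for miR-1246 and its 12 variants
#'
#' The per-sequence counts of putative RBP consensus motifs and of distinct
#' binding RBPs printed for the native miR-1246 (id 0) and its variants
#' (published ids 1-12). These counts derive from a specific snapshot of an
#' external motif database and are therefore shipped as a fixture: they are
#' the documented input of the example selection configuration, not something
#' the scanner recomputes.
#' @return Data frame with columns `sequence_id`, `n_motif_hits`,
#'   `n_distinct_rbps`, ordered as published (by decreasing motif count).
#' @export
mir1246_rbp_counts <- function() {
  data.frame(
    sequence_id = c("0", "1", "9", "10", "3", "2", "7", "8", "5", "4", "6", "11", "12"),
    n_motif_hits = c(25L, 16L, 14L, 11L, 5L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L),
    n_distinct_rbps = c(15L, 12L, 13L, 6L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Example selection configuration reproducing the published probe set
#'
#' The published study took variants 6 and 7 (structure-divergent: they fold
#' into hairpins and form their own 2D and 3D cluster), the variant with the
#' highest RBP count among the rest (9), and two judgement picks (5 and 8).
#' Encoded as selection rules: rule 1 = structure-divergent, rule 2 = one
#' highest-RBP-count variant, rule 3 = pins \{5, 8\}.
#' @return List with elements `pins`, `n_highest`, `n_lowest`.
#' @export
mir1246_selection_rules <- function() {
  list(pins = c("5", "8"), n_highest = 1L, n_lowest = 0L)
}
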