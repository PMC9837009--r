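---
title: "Screening single-nucleotide EXO-motif variants of a miRNA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening single-nucleotide EXO-motif variants of a miRNA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exovar)
```

## The screening problem

Mature miRNAs are sorted into exosomes in part through short sequence motifs
(EXO-motifs, e.g. GGAG and GCAG) recognized by RNA-binding proteins such as
hnRNPA2B1. The worked example throughout this package is the 19-nt
hsa-miR-1246 mimic, 5'-AAUGGAUUUUUGGAGCAGG-3', which carries both motifs
overlapping at position 15 (GGAG at 12-15, GCAG at 15-18). The screening
question: which single-nucleotide substitutions inside the GGAG window
plausibly change the molecule's protein-binding content or its 2D/3D
structure, and therefore deserve wet-lab validation?

The workflow answers it in five computational stages, each an exported
operation so that every stage is independently testable:

1. **Variant enumeration** (`enumerate_motif_variants`): all 3 x window-width
   substitutions, here 12 variants of the 4-nt window.
2. **RBP motif scanning** (`scan_motifs`, `summarize_hits`,
   `rank_sequences`): IUPAC-aware matching of a consensus-motif table
   against each sequence, collapse of hit genes into homolog groups, and a
   ranking by binding-site content.
3. **Secondary structure** (`fold_maxpair`, `fold_mfe_hairpin`,
   `read_vienna`, `extract_hairpin_features`): built-in folding engines or
   ingestion of an external predictor's dot-bracket output, plus hairpin
   feature extraction (stem length, loop length, motif placement).
4. **Structure clustering** (`pairwise_distances` + `cluster_dbscan` for
   dot-brackets; `kabsch_rmsd`, `ensemble_stats`, `cross_ensemble_cluster`
   for 3D ensembles).
5. **Selection** (`select_candidates`): explicit, tagged rules that turn the
   stage outputs into a candidate list.

`run_insilico()` composes the stages; the numbered scripts under `analysis/`
run them one at a time and narrate what they find.

## Variant identity and numbering

Variants are numbered deterministically: window positions 5'-to-3', and at
each position the alternative bases in the fixed order A < C < G < U,
skipping the native base. The native sequence is id 0 and is never part of
the variant list. The original study's own 1-12 numbering is only partially
recoverable from its text; the three variants it pins are A14C, G15C and
G15U (published ids 5, 6, 7; internal ids 7, 11, 12). Rather than guess the
remaining nine, the package ships the pinned map as a documented alias table
(`mir1246_paper_aliases()`, also in `inst/extdata/`). All user-facing
coordinates are 1-based inclusive; the 3'-end counting used in the probe
descriptions is converted by `pos_from_3prime()` (`length - k + 1`).

## Motif scanning conventions

Patterns are IUPAC RNA codes; `N` matches anything and degenerate positions
carry no weight — matching is binary, not scored (the optional score column
of a motif table is parsed but unused). Every match of every (motif, gene)
row counts as one hit, overlaps and self-overlaps included, so the
"potential consensus motifs" count of a sequence is its total hit count and
the "binding RBPs" count is the number of distinct homolog groups after
collapsing hit genes through the annotation table. Genes missing from the
annotation degrade into singleton groups rather than failing, because a
partial annotation should bias counts, not abort a screen. Only the sense
strand is scanned: the object of study is a single-stranded mature miRNA.
Homology lookups are strictly offline (a TSV replaces live database
queries), which is what makes the whole pipeline reproducible in CI.

Ranking is descending by hit count, ties broken by descending distinct-RBP
count, then ascending id. The published table's tie order among 3-hit
variants follows no recoverable key; ours is simply deterministic.

## Secondary structure: a pluggable stage

The predictors used in the original study are trained probabilistic models
whose parameter sets this package does not reproduce — their printed
energies (-0.84 / -1.37 kcal/mol) are therefore never targets. The stage is
pluggable instead:

* `fold_maxpair` — classic base-pair maximization (Nussinov recursion) over
  AU/GC/GU pairs with a minimum loop of 3 nt. Deterministic traceback:
  pairing is preferred whenever it attains the optimum, and among tying
  partners the 5'-most is taken.
* `fold_mfe_hairpin` — exhaustive enumeration of single-hairpin candidates
  (one contiguous helix plus terminal loop), scored with a packaged
  nearest-neighbor-style table (`default_energy_params()`): stacking
  energies ≤ 0 with Turner-like magnitudes, hairpin-loop initiation
  penalties ≥ 0 (log-extrapolated beyond 9 nt), and a 0.5 kcal/mol terminal
  AU/GU penalty applied at the outer helix end. The table is a documented
  stand-in: it supports sign and ordering statements ("folds vs does not
  fold", "hairpin A is more stable than B"), nothing more. A candidate must
  score strictly below zero, else the all-unpaired structure is returned
  with energy exactly 0.0 — mirroring the dichotomy between sequences that
  do and do not form structures.
* `read_vienna` — ingestion of 2/3-line dot-bracket records with optional
  trailing `(energy)`, for fidelity runs with any external predictor.

Structures are validated on construction: balanced, strictly nested
brackets (no pseudoknots), loops ≥ 3 nt, and only AU/UA/GC/CG/GU/UG pairs.

`extract_hairpin_features` reports the hairpin with the longest maximal
contiguous helix (ties: more GC pairs, then 5'-most). The motif placement
call is `stem` when every window position is paired, `loop` when every
window position lies within the span of the hairpin's closing pair — the
loop plus that closing pair, so a motif ending on the pair that closes a
loop still counts as "in the loop", which matches how such figures are read
— `unpaired` for a pair-free structure, and `mixed` otherwise.

## Clustering choices

**2D.** Dot-bracket strings are compared by Levenshtein distance (unit-cost
edits, via base R's `adist`) and clustered by DBSCAN over the precomputed
matrix. The study conditions fix `min_samples = 2` (the published small
cluster has two members) and a radius of `eps = 6` edits for 19-nt
dot-brackets; neighbourhoods are `d <= eps`. Noise points are reported
separately and excluded from the cluster count, with an option to convert
them to singleton clusters — the two conventions are both available and
named because published cluster counts rarely say which they used.

**3D.** Models are compared on the backbone atom set {P, C4', C1'}, paired
by residue index and atom name. Pairing by index (not alignment) is exact
here because variants differ by substitution only, and the backbone atom
set keeps structures of different sequences fully comparable across a
substituted base. Superposition is plain Kabsch — SVD of the covariance
matrix with the determinant correction that excludes reflections, RMSD
evaluated as the residual after applying the optimal rotation (the
closed-form trace expression loses half the significant digits to
cancellation near zero; the residual form is exact to machine precision,
which the rigid-motion invariance tests rely on). No iterative outlier
rejection is performed, unlike the viewer used in the original study, so
published RMSD magnitudes are not bit-targets.

Per-ensemble statistics summarize all unordered model pairs; the centroid is
the member minimizing mean RMSD to the others, and the reported
average-to-centroid excludes the centroid's zero self-distance. That
convention is forced by the published two-model rows, where the average
RMSD to centroid equals the single pairwise RMSD rather than half of it.

Cross-ensemble clustering is single linkage (via `hclust`) over the
centroid RMSD matrix. An explicit cut at height `t` groups items merged at
height ≤ t, which coincides with the connected components of the
sub-threshold distance graph. The automatic `"largest-gap"` cut sorts the
merge heights and cuts in the middle of the largest gap — but only when
that gap exceeds the merge height at its lower edge. A gap no larger than
the merges below it is indistinguishable from sampling noise, and without
the guard any unimodal height profile would be split somewhere; with it,
all-equal or jitter-only profiles return one cluster, while planted
two-scale profiles cut cleanly. Ties in the largest gap resolve towards
fewer clusters.

## The synthetic-data module

Three external resources feed the real workflow: a consensus-motif
database, a homology annotation service, and 2D/3D structure predictors. No
accessions were deposited for any of them, so the `synthdata` generators
emulate each one as first-class, tested code:

* `make_motif_table` — an ATtRACT-dialect TSV whose cored patterns are true
  substrings of the target sequence around the EXO-motifs (so planted hits
  are guaranteed), plus degenerate-code patterns; alongside it, a manifest
  of every pattern occurrence in the target computed by an independent
  naive regex matcher, the ground truth for scanner tests.
* `make_annotation_table` — gene-to-homolog-group assignments of
  configurable group sizes.
* `make_dotbracket_set` — the published 2D outcome: 11 all-dot records and
  two hairpins. The study reports the loop sizes (9 nt for variant 6, 4 nt
  for variant 7) and the motif placements (loop and stem respectively) but
  not the stems. The defaults — stem 4 with a 1-nt 5' overhang for the 9-nt
  loop, and stem 6 whose 3' helix spans positions 12-17 for the 4-nt
  loop — realize the published loops and placements on a 19-mer, and their
  dot-bracket strings sit 6 edits from each other but 8 and 12 edits from
  the unfolded records, i.e. the two Levenshtein scales that the published
  two-cluster partition requires at the default radius. Stem sequences are
  generated Watson-Crick complementary so every record passes structure
  validation.
* `make_structure_ensembles` — an idealized helical backbone trace (fixed
  rise 2.81 Å, twist 32.7°/residue, three atoms per residue named P, C4',
  C1', matching the superposition atom set so synthetic and real PDBs
  exercise identical code paths). Each model adds isotropic Gaussian jitter
  (σ, default 0.1 Å); ensembles in the divergent group additionally shift
  the motif-window residues rigidly by δ (default 3 Å) in a shared
  direction — a controlled stand-in for the local conformational difference
  around the motif, with no claim of RNA physics. Defaults mirror the study
  conditions: 13 ensembles (ids 0-12), divergent pair {6, 7} with 10 models
  each, 2 models for the rest.

What the generators do **not** emulate: real motif-table redundancy and
organism annotation quirks, sequence-dependent 3D geometry, multi-hairpin
or pseudoknotted structures, and realistic within-ensemble conformational
spread (real prediction ensembles of the background sequences show
pairwise RMSDs around 2.3 Å, not the 0.1-Å jitter scale used here). Tests
passing on synthetic data therefore demonstrate that the *mechanics* —
scanning, distances, superposition, clustering, selection — are correct
under known ground truth; they do not certify any biological conclusion
about miR-1246.

## Selection rules

The published probe choice mixes a stated criterion with judgement. The
package encodes it as three explicit, tagged rules: (1)
*structure-divergent* — every variant separated from the native in all
available clusterings (noise counts as separated); (2) *rbp-count-extreme*
— among the remaining variants, the configured number of highest and lowest
distinct-RBP-count ids (defaults 1 and 0; rule 2 reads the distinct-RBP
column because, with the published counts, that makes variant 9 the unique
top pick among non-divergent variants, matching the published set); (3)
*user-pinned* — ids always included. The published outcome {5, 6, 7, 8, 9}
is reproduced by `mir1246_selection_rules()`: rules 1 and 2 contribute
{6, 7} and {9}, and the two judgement picks {5, 8} are shipped as pins
rather than pretending they were algorithmic.

## Determinism and problem sizes

Every stochastic operation takes an explicit seed, generation is a pure
function of spec + seed, and pipeline artifacts embed the seed and a config
fingerprint, so reruns are byte-identical. The test suite works at the
study's own scale — 19-nt sequences, 13 structures, 13 ensembles of at most
10 models — with exhaustive oracles on reduced sizes chosen so each
property is still fully checkable: folding equivalence on random sequences
up to 12 nt, energy-candidate enumeration up to 25 nt, rotation-grid
superposition checks on 10-point sets, and 50-seed planted-partition
recovery at δ/σ = 30.

## Known limitations

* The energy model is a stand-in; absolute ΔG values are not comparable to
  any trained predictor's output, only signs and orderings within one run.
* Single-hairpin enumeration ignores interior loops, bulges and multibranch
  structures; the base-pair-maximization engine ignores energetics
  entirely.
* Kabsch superposition without outlier rejection systematically differs
  from viewers that perform rejection cycles; comparisons should stay
  within one convention.
* The DBSCAN radius default (6 edits) is calibrated for 19-nt dot-brackets;
  other lengths need their own radius.
* PDB input only (fixed-width, MODEL/ENDMDL, altLoc blank/'A'); no mmCIF.
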