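# exovar

In silico screening of single-nucleotide EXO-motif variants of a miRNA.

Short exosome-sorting motifs (EXO-motifs, e.g. GGAG and GCAG) inside mature
miRNAs are bound by RNA-binding proteins such as hnRNPA2B1 and influence
whether a miRNA is loaded into extracellular vesicles. `exovar` implements,
as a tested and fully offline R pipeline, the screening workflow used to
decide which single-nucleotide substitutions inside such a motif deserve
wet-lab validation. The worked example is the 19-nt hsa-miR-1246 mimic
(5'-AAUGGAUUUUUGGAGCAGG-3', GGAG at positions 12-15 overlapping GCAG at
15-18). The package is aimed at computational RNA biologists who want the
screening mechanics — enumeration, motif scanning, structure comparison,
clustering, selection — reproducible and testable without external
services.

## What it computes

* **Variant enumeration** — all 3 × w single-nucleotide substitutions of a
  w-nt motif window (12 variants for GGAG), numbered deterministically.
* **RBP motif content** — IUPAC-aware scanning of an ATtRACT-dialect
  consensus-motif table against each sequence; hits collapsed to distinct
  RBPs via an offline homolog-group table; sequences ranked by binding-site
  content.
* **Secondary structure** — a pluggable 2D stage: base-pair maximization
  (Nussinov recursion), a simplified single-hairpin minimum-free-energy
  engine with a packaged nearest-neighbor-style parameter table, or
  ingestion of any external predictor's Vienna dot-bracket output; hairpin
  features (stem, loop, motif placement in loop/stem) extracted per
  sequence.
* **2D clustering** — Levenshtein distance between dot-bracket strings,
  DBSCAN over the precomputed matrix (defaults eps = 6 edits,
  min_samples = 2).
* **3D comparison** — multi-model PDB ensembles superimposed by the Kabsch
  algorithm (SVD with reflection correction) on the {P, C4', C1'} backbone
  trace; per-ensemble RMSD statistics and centroids; single-linkage
  clustering of ensemble centroids with an automatic largest-gap cut.
* **Selection** — explicit tagged rules (structure-divergent variants,
  RBP-count extremes, user pins) that turn the stage outputs into a
  candidate list.
* **Synthetic data** — generators that emulate every external input (motif
  database, homology annotation, 2D predictions, 3D ensembles with a
  planted cluster partition), so the full pipeline runs and is tested with
  no network and known ground truth.

## Worked example

```r
library(exovar)

native <- mir1246_sequence()
variants <- enumerate_motif_variants(native, mir1246_window())
nrow(variants)
#> [1] 12

# the two overlapping EXO-motifs of the native sequence
scan_motifs(native, data.frame(motif_id = c("m1", "m2"),
                               pattern = c("GGAG", "GCAG"),
                               gene_id = c("g1", "g2")))
#>   sequence_id motif_id gene_id start end matched
#> 1           0       m1      g1    12  15    GGAG
#> 2           0       m2      g2    15  18    GCAG

# synthetic 2D prediction set: 11 unfolded records + 2 hairpins
structs <- make_dotbracket_set(seed = 1)
D <- pairwise_distances(vapply(structs, function(s) s$dot_bracket, ""))
cluster_dbscan(D, eps = 6, min_samples = 2)
#> 2 cluster(s)
#>   1: {0, 1, 2, 3, 4, 5, 8, 9, 10, 11, 12}
#>   2: {6, 7}

# synthetic 3D ensembles with a planted {11, 2} partition
gen <- make_structure_ensembles(seed = 1)
cc <- cross_ensemble_cluster(lapply(gen$ensembles, ensemble_centroid_model))
cc$clusters
#> 2 cluster(s)
#>   1: {0, 1, 2, 3, 4, 5, 8, 9, 10, 11, 12}
#>   2: {6, 7}

# selection from the published binding-site counts and the two partitions
sel <- select_candidates(mir1246_rbp_counts(),
                         cluster2d = cluster_dbscan(D, eps = 6, min_samples = 2),
                         cluster3d = cc$clusters,
                         rules = mir1246_selection_rules())
sel$sequence_id
#> [1] "5" "6" "7" "8" "9"
```

The variants separated from the native in both structure clusterings ({6, 7})
are tagged `structure-divergent`; variant 9 is the `rbp-count-extreme` pick
(highest distinct-RBP count among the rest); 5 and 8 are `user-pinned`
judgement picks. Together they are the probe set taken to validation.

## The analysis, step by step

The numbered scripts under `analysis/` run the workflow one stage at a time,
print what they find, and write their tables under `results/`:

```sh
Rscript analysis/01_enumerate_variants.R   # 12 variants + control probes
Rscript analysis/02_rbp_motif_scan.R       # scan, homolog collapse, ranking
Rscript analysis/03_secondary_structure.R  # built-in engines + ingested set
Rscript analysis/04_cluster_2d.R           # Levenshtein + DBSCAN
Rscript analysis/05_tertiary_ensembles.R   # ensembles, RMSD stats, clustering
Rscript analysis/06_select_candidates.R    # rule-based selection
```

`run_insilico(pipeline_config(...))` executes the same stages in one call
and writes one TSV per stage plus a JSON summary, each artifact headed by
the seed and a config fingerprint. See
`vignettes/exomotif-variant-screening.Rmd` for the methods, parameter
defaults and their rationale, and known limitations.

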