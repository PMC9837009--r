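#!/usr/bin/env Rscript
# Stage 4 - secondary-structure clustering.
# Pairwise Levenshtein distances between the dot-bracket strings of stage 3's
# ingested prediction set, then DBSCAN over the precomputed matrix
# (eps = 6 edits, min_samples = 2).

library(exovar)

outdir <- "results/04_cluster2d"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

vpath <- "results/03_structures/predicted_set.dbn"
structs <- if (file.exists(vpath)) read_vienna(vpath) else make_dotbracket_set(seed = 1)
dbs <- vapply(structs, function(s) s$dot_bracket, "")

D <- pairwise_distances(dbs)
write_dist_matrix(D, file.path(outdir, "levenshtein_matrix.tsv"))
message("distance matrix over ", nrow(D), " structures; off-diagonal range ",
        min(D[upper.tri(D)]), "-", max(D))

cl <- cluster_dbscan(D, eps = 6, min_samples = 2)
write_assignments(cl, file.path(outdir, "clusters.tsv"))
message(cl$n_clusters, " clusters:")
for (k in seq_along(cl$members)) {
  message("  cluster ", k, ": {", paste(cl$members[[k]], collapse = ", "), "}")
}
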