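#!/usr/bin/env Rscript
# Stage 2 - RNA-binding-protein motif content.
# Scan the native sequence and all 12 variants against a consensus-motif
# table, collapse hits through homolog groups, and rank the sequences by
# binding-site content. The motif table and homology annotation are produced
# by the synthetic generators (offline stand-ins for a real database
# download; a real ATtRACT TSV can be passed through read_motif_table
# unmodified).

library(exovar)

outdir <- "results/02_rbp_scan"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

native <- mir1246_sequence()
variants <- enumerate_motif_variants(native, mir1246_window())
seqs <- c(list(native), lapply(seq_len(nrow(variants)), function(i) {
  normalize_sequence(variants$sequence[i], as.character(variants$variant_id[i]))
}))
names(seqs) <- vapply(seqs, function(s) attr(s, "id"), "")

mt <- make_motif_table(n_motifs = 25, target = native, seed = 2,
                       path = file.path(outdir, "motif_table.tsv"))
motifs <- read_motif_table(file.path(outdir, "motif_table.tsv"))
annotation <- make_annotation_table(motifs$gene_id, group_sizes = 2L,
                                    path = file.path(outdir, "annotation.tsv"))
message(nrow(motifs), " motifs over ", length(unique(motifs$gene_id)),
        " genes in ", length(unique(annotation$homolog_group_id)),
        " homolog groups")

hits <- do.call(rbind, lapply(seqs, scan_motifs, motifs = motifs))
rownames(hits) <- NULL
write_hits(hits, file.path(outdir, "hits.tsv"))

summaries <- do.call(rbind, lapply(names(seqs), function(id) {
  summarize_hits(hits, annotation, id)
}))
ranking <- rank_sequences(summaries)
utils::write.table(ranking, file.path(outdir, "ranking.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("ranking (id: hits/RBPs): ",
        paste(sprintf("%s:%d/%d", ranking$sequence_id, ranking$n_motif_hits,
                      ranking$n_distinct_rbps), collapse = "  "))
message("top-ranked sequence: ", ranking$sequence_id[1],
        if (ranking$sequence_id[1] == "0") " (the native miR-1246)" else "")

freq <- motif_frequency(hits, motifs)
utils::write.table(freq, file.path(outdir, "motif_frequency.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("most frequent motif: ", freq$pattern[1], " (", freq$count[1], " hits)")
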