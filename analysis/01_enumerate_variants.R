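#!/usr/bin/env Rscript
# Stage 1 - the variant set.
# Enumerate every single-nucleotide substitution inside the GGAG EXO-motif
# window (positions 12-15) of the 19-nt miR-1246 mimic. The native sequence
# is id 0; the 12 variants are numbered deterministically (positions 5'->3',
# alternative bases A<C<G<U), with the three ids the published study pins
# mapped through the shipped alias table.

library(exovar)

outdir <- "results/01_variants"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

native <- mir1246_sequence()
window <- mir1246_window()
message("native miR-1246: ", as.character(native), " (", nchar(native), " nt)")
message("EXO-motif window: ", window$pattern, " at ", window$start, "-", window$end)

variants <- enumerate_motif_variants(native, window)
message(nrow(variants), " single-substitution variants enumerated")

write_variant_table(variants, file.path(outdir, "variants.tsv"))
seqs <- c(list(native), lapply(seq_len(nrow(variants)), function(i) {
  normalize_sequence(variants$sequence[i], as.character(variants$variant_id[i]))
}))
write_fasta(seqs, file.path(outdir, "sequences.fasta"))

aliases <- mir1246_paper_aliases()
utils::write.table(aliases, file.path(outdir, "paper_aliases.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (k in seq_len(nrow(aliases))) {
  message("internal variant ", aliases$internal_id[k], " (", aliases$label[k],
          ") = published variant ", aliases$published_id[k])
}

# control probes: random sequences carrying exactly one EXO-motif at the
# native location and no other EXO-motif anywhere
excl_ggag <- setdiff(exo_motif_patterns(), "GGAG")
probe13 <- generate_constrained_sequence(19, window, excl_ggag, seed = 13,
                                         id = "probe13_GGAG_only")
gcag_window <- motif_window(15, 18, "GCAG")
excl_gcag <- setdiff(exo_motif_patterns(), "GCAG")
probe14 <- generate_constrained_sequence(19, gcag_window, excl_gcag, seed = 14,
                                         id = "probe14_GCAG_only")
write_fasta(list(probe13, probe14), file.path(outdir, "control_probes.fasta"))
message("control probes written: ", as.character(probe13), " / ",
        as.character(probe14))
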