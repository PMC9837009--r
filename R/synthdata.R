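# Offline emulation of every external input the workflow consumes: an
# ATtRACT-dialect motif table, a homology annotation table, a secondary
# structure set mirroring the published 11-unfolded/2-hairpin configuration,
# and 3D model ensembles with a planted cluster partition.

RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

# independent naive matcher used only to build ground-truth manifests:
# expands the IUPAC pattern into a regex and finds overlapping matches via
# a lookahead, a mechanism deliberately different from the scanner under test
naive_pattern_hits <- function(sequence, pattern) {
  classes <- vapply(strsplit(pattern, "")[[1]], function(ch) {
    bases <- IUPAC_RNA[[ch]]
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, "")
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  m <- gregexpr(rx, as.character(sequence), perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  k <- nchar(pattern)
  if (length(starts) == 0L) {
    return(data.frame(start = integer(), end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(start = starts, end = starts + k - 1L,
             matched = substring(as.character(sequence), starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic ATtRACT-dialect motif table with a hit manifest
#'
#' Emulates a consensus-motif database download: `n_motifs` patterns over the
#' IUPAC RNA alphabet, a configurable fraction of which embed a GGAG or GCAG
#' core (so EXO-motif-overlapping hits are planted), assigned to synthetic
#' gene ids cycling over the requested organisms. Alongside the table, a
#' manifest lists every occurrence of every pattern in the target sequence,
#' computed at generation time by an independent naive regex matcher — the
#' ground truth for scanner tests.
#'
#' @param n_motifs Number of motif rows.
#' @param target Sequence used for the manifest (default miR-1246).
#' @param len_range Pattern length range (nt), default 4-7.
#' @param frac_core Fraction of patterns embedding a GGAG/GCAG core.
#' @param organisms Character vector cycled over rows.
#' @param degenerate_prob Per-position probability of a degenerate IUPAC code
#'   in non-core patterns.
#' @param seed RNG seed (generation is a pure function of the arguments).
#' @param path Optional TSV output path (ATtRACT column names).
#' @return List: `table` (ATtRACT-dialect data frame), `manifest` (data frame
#'   sequence_id, motif_id, gene_id, start, end, matched).
#' @export
make_motif_table <- function(n_motifs, target = mir1246_sequence(),
                             len_range = c(4L, 7L), frac_core = 0.3,
                             organisms = "Homo_sapiens",
                             degenerate_prob = 0.15, seed = 1L, path = NULL) {
  set.seed(seed)
  degenerate <- c("R", "Y", "S", "W", "K", "M", "N")
  empty_manifest <- data.frame(sequence_id = character(), motif_id = character(),
                               gene_id = character(), start = integer(),
                               end = integer(), matched = character(),
                               stringsAsFactors = FALSE)
  if (n_motifs == 0L) {
    tab <- data.frame(Gene_name = character(), Gene_id = character(),
                      Organism = character(), Motif = character(),
                      Len = integer(), Matrix_id = character(),
                      Score = numeric(), stringsAsFactors = FALSE)
    if (!is.null(path)) {
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(list(table = tab, manifest = empty_manifest))
  }
  target_str <- as.character(target)
  rows <- lapply(seq_len(n_motifs), function(i) {
    len <- sample(seq.int(len_range[1], len_range[2]), 1L)
    if (stats::runif(1) < frac_core) {
      core <- sample(c("GGAG", "GCAG"), 1L)
      core_at <- regexpr(core, target_str, fixed = TRUE)[1]
      extra <- max(len - 4L, 0L)
      pre <- sample(0:extra, 1L)
      if (core_at > 0L) {
        # flanks copied from the target context, so the planted motif is a
        # true target substring and guaranteed to appear in the manifest
        start <- min(max(core_at - pre, 1L), nchar(target_str) - len + 1L)
        pat <- substr(target_str, start, start + len - 1L)
      } else {
        pat <- paste0(paste(sample(RNA_BASES, pre, replace = TRUE), collapse = ""),
                      core,
                      paste(sample(RNA_BASES, extra - pre, replace = TRUE), collapse = ""))
      }
    } else {
      chars <- vapply(seq_len(len), function(j) {
        if (stats::runif(1) < degenerate_prob) sample(degenerate, 1L)
        else sample(RNA_BASES, 1L)
      }, "")
      pat <- paste(chars, collapse = "")
    }
    data.frame(
      Gene_name = sprintf("RBP%02d", i), Gene_id = sprintf("SYNG%05d", i),
      Organism = organisms[(i - 1L) %% length(organisms) + 1L],
      Motif = pat, Len = nchar(pat), Matrix_id = sprintf("M%03d", i),
      Score = round(stats::runif(1), 3), stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  manifest <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    h <- naive_pattern_hits(target, tab$Motif[i])
    if (nrow(h) == 0L) return(NULL)
    data.frame(sequence_id = seq_id(target), motif_id = tab$Matrix_id[i],
               gene_id = tab$Gene_id[i], h, stringsAsFactors = FALSE)
  }))
  if (is.null(manifest)) manifest <- empty_manifest
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, manifest = manifest)
}

#' Generate a synthetic gene-to-homolog-group annotation table
#'
#' Assigns the given gene ids, in order, to homolog groups of the requested
#' sizes (recycled until all genes are covered).
#'
#' @param gene_ids Character vector of gene ids (e.g. the motif table's).
#' @param group_sizes Integer vector of group sizes, recycled (default 2).
#' @param path Optional TSV output path.
#' @return Data frame: gene_id, homolog_group_id, transcript_id, protein_id,
#'   go_terms.
#' @export
make_annotation_table <- function(gene_ids, group_sizes = 2L, path = NULL) {
  gene_ids <- unique(gene_ids)
  n <- length(gene_ids)
  if (n == 0L) {
    df <- data.frame(gene_id = character(), homolog_group_id = character(),
                     transcript_id = character(), protein_id = character(),
                     go_terms = character(), stringsAsFactors = FALSE)
  } else {
    groups <- integer(0)
    g <- 0L
    while (length(groups) < n) {
      g <- g + 1L
      size <- group_sizes[(g - 1L) %% length(group_sizes) + 1L]
      groups <- c(groups, rep(g, size))
    }
    groups <- groups[seq_len(n)]
    df <- data.frame(
      gene_id = gene_ids,
      homolog_group_id = sprintf("HG%03d", groups),
      transcript_id = sprintf("SYNT%05d", seq_len(n)),
      protein_id = sprintf("SYNP%05d", seq_len(n)),
      go_terms = "GO:0003723",
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Default hairpin geometries for the synthetic dot-bracket set
#'
#' The published study reports that two of the thirteen sequences fold into
#' hairpins, one with a 9-nt and one with a 4-nt terminal loop, the first
#' carrying the motif in the loop and the second in the stem. Stems are not
#' printed; the defaults (stem 4 with a 1-nt 5' overhang, and stem 6 whose 3'
#' helix spans positions 12-17) realize those loop sizes on a 19-mer with the
#' motif placements described, and give dot-bracket strings whose Levenshtein
#' geometry separates the two hairpins from the unfolded records at the
#' default DBSCAN radius.
#' @return List of two lists with fields `id`, `offset`, `stem`, `loop`.
#' @export
default_hairpin_geometries <- function() {
  list(list(id = "6", offset = 1L, stem = 4L, loop = 9L),
       list(id = "7", offset = 1L, stem = 6L, loop = 4L))
}

#' Generate a synthetic secondary-structure set (Vienna records)
#'
#' Emulates the published 2D-prediction outcome: `unfolded_ids` all-dot
#' records plus hairpin records with the requested stem/loop geometry. Every
#' record is built with a sequence compatible with its structure (stem sides
#' are Watson-Crick complementary) and validated through
#' [secondary_structure()].
#'
#' @param unfolded_ids Ids of the all-dot records (default the published
#'   configuration: 0-5 and 8-12).
#' @param hairpins List of geometries (`id`, `offset`, `stem`, `loop`), see
#'   [default_hairpin_geometries()].
#' @param length Record length in nt (default 19).
#' @param seed RNG seed.
#' @param path Optional Vienna-format output path.
#' @return Named list of `secondary_structure` objects, in id order.
#' @export
make_dotbracket_set <- function(unfolded_ids = as.character(c(0:5, 8:12)),
                                hairpins = default_hairpin_geometries(),
                                length = 19L, seed = 1L, path = NULL) {
  set.seed(seed)
  out <- list()
  for (id in unfolded_ids) {
    s <- paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
    out[[id]] <- secondary_structure(id, s, strrep(".", length))
  }
  for (hp in hairpins) {
    if (hp$offset + 2L * hp$stem + hp$loop > length) {
      stop("infeasible hairpin geometry for id '", hp$id, "': offset ", hp$offset,
           " + 2*stem ", hp$stem, " + loop ", hp$loop, " exceeds length ", length)
    }
    chars <- sample(RNA_BASES, length, replace = TRUE)
    stem5 <- sample(RNA_BASES, hp$stem, replace = TRUE)
    i5 <- hp$offset + seq_len(hp$stem)
    i3 <- hp$offset + hp$stem + hp$loop + seq_len(hp$stem)
    chars[i5] <- stem5
    chars[i3] <- rev(RNA_COMPLEMENT[stem5])
    db <- rep(".", length)
    db[i5] <- "("
    db[i3] <- ")"
    out[[hp$id]] <- secondary_structure(hp$id, paste(chars, collapse = ""),
                                        paste(db, collapse = ""))
  }
  ids <- names(out)
  ord <- order(suppressWarnings(as.numeric(ids)))
  if (!anyNA(suppressWarnings(as.numeric(ids)))) out <- out[ord]
  if (!is.null(path)) write_vienna(out, path)
  out
}

#' Idealized helical backbone trace
#'
#' A coarse 3-atoms-per-residue (P, C4', C1') trace laid on a regular helix
#' (fixed rise and twist, three concentric radii). It is the deterministic
#' base conformation that synthetic ensembles perturb; it carries no
#' sequence-dependent geometry.
#'
#' @param n_residues Number of residues.
#' @param rise Axial rise per residue (Angstroms).
#' @param twist Twist per residue (degrees).
#' @return Model data frame (resno, resname, atom, x, y, z).
#' @export
helix_backbone <- function(n_residues = 19L, rise = 2.81, twist = 32.7) {
  radii <- c(P = 8.7, `C4'` = 9.2, `C1'` = 6.1)
  offs <- c(P = 0, `C4'` = 14, `C1'` = 25)  # angular offsets, degrees
  rows <- list()
  for (r in seq_len(n_residues)) {
    for (a in names(radii)) {
      th <- (twist * (r - 1L) + offs[[a]]) * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        resno = r, resname = "G", atom = a,
        x = radii[[a]] * cos(th), y = radii[[a]] * sin(th),
        z = rise * (r - 1L), stringsAsFactors = FALSE
      )
    }
  }
  validate_model(do.call(rbind, rows), "helix backbone")
}

#' Generate synthetic 3D ensembles with a planted cluster partition
#'
#' Each ensemble's models are the idealized backbone plus isotropic Gaussian
#' jitter of sd `sigma` per coordinate. Ensembles in the divergent group
#' additionally displace the atoms of the motif-window residues by a rigid
#' shift of magnitude `delta` (a fixed direction shared by the group),
#' mimicking a local conformational difference around the motif without
#' modelling RNA physics. The default configuration mirrors the published
#' study: 13 ensembles (ids 0-12), divergent group \{6, 7\}, 10 models for
#' the divergent ensembles and 2 for the rest.
#'
#' @param ids Ensemble labels.
#' @param divergent_ids Labels forming the planted divergent group.
#' @param n_models_background,n_models_divergent Models per ensemble.
#' @param n_residues Residues per model (default 19).
#' @param sigma Global jitter sd in Angstroms (default 0.1).
#' @param delta Local displacement magnitude in Angstroms (default 3).
#' @param window Residue indices displaced in divergent ensembles.
#' @param seed RNG seed; generation is byte-reproducible.
#' @param dir Optional directory: one multi-model PDB per ensemble
#'   (`ens_<id>.pdb`) plus a `manifest.json` with the planted partition and
#'   the generator's own centroid-pair RMSD matrix.
#' @return List: `ensembles` (named list of `ensemble3d`), `manifest` (list
#'   with `planted_partition` and `centroid_rmsd`).
#' @export
make_structure_ensembles <- function(ids = as.character(0:12),
                                     divergent_ids = c("6", "7"),
                                     n_models_background = 2L,
                                     n_models_divergent = 10L,
                                     n_residues = 19L, sigma = 0.1, delta = 3.0,
                                     window = 12:15, seed = 1L, dir = NULL) {
  stopifnot(sigma >= 0, delta >= 0)
  set.seed(seed)
  base <- helix_backbone(n_residues)
  shift_dir <- c(1, 0, 0)
  ensembles <- list()
  for (id in ids) {
    conf <- base
    if (id %in% divergent_ids) {
      sel <- conf$resno %in% window
      conf$x[sel] <- conf$x[sel] + delta * shift_dir[1]
      conf$y[sel] <- conf$y[sel] + delta * shift_dir[2]
      conf$z[sel] <- conf$z[sel] + delta * shift_dir[3]
    }
    m <- if (id %in% divergent_ids) n_models_divergent else n_models_background
    models <- lapply(seq_len(m), function(k) {
      jit <- conf
      n_at <- nrow(jit)
      jit$x <- jit$x + stats::rnorm(n_at, sd = sigma)
      jit$y <- jit$y + stats::rnorm(n_at, sd = sigma)
      jit$z <- jit$z + stats::rnorm(n_at, sd = sigma)
      jit
    })
    ensembles[[id]] <- structure(list(sequence_id = id, models = models),
                                 class = "ensemble3d")
  }
  centroids <- lapply(ensembles, ensemble_centroid_model)
  crmsd <- rmsd_matrix(centroids)
  manifest <- list(
    planted_partition = list(background = setdiff(ids, divergent_ids),
                             divergent = intersect(ids, divergent_ids)),
    centroid_rmsd = as.data.frame(crmsd)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in ids) {
      write_pdb_ensemble(ensembles[[id]], file.path(dir, paste0("ens_", id, ".pdb")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ensembles = ensembles, manifest = manifest)
}
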