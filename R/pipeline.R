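# Orchestration of the full in-silico workflow and the rule-based selection
# of variants for wet-lab validation.

#' Build a pipeline configuration
#'
#' Collects every knob of the workflow with the worked-example defaults (the
#' miR-1246 GGAG study). `motif_table`/`annotation` may be TSV paths, data
#' frames, or NULL to fall back on the synthetic generators. The 2D engine is
#' one of `"maxpair"` (base-pair maximization), `"mfe"` (single-hairpin
#' minimum energy), or `"vienna"` (ingest `vienna_path`). 3D ensembles are
#' read from `ensemble_dir` (multi-model PDBs named `ens_<id>.pdb`); NULL
#' skips the 3D arm; `"synthetic"` generates the default planted ensembles.
#'
#' @param native Native `rna_sequence` (id "0").
#' @param window `motif_window` of the EXO-motif.
#' @param motif_table,annotation Paths, data frames, or NULL (synthetic).
#' @param organism Optional organism filter for the motif table.
#' @param engine 2D engine: "maxpair", "mfe" or "vienna".
#' @param vienna_path Dot-bracket file when `engine = "vienna"`.
#' @param eps,min_samples DBSCAN parameters for the 2D arm (defaults 6 edits
#'   and 2, the documented configuration for 19-nt dot-brackets).
#' @param cut3d Single-linkage cut for the 3D arm ("largest-gap" or numeric).
#' @param atom_set Atom names for 3D superposition.
#' @param ensemble_dir Directory of PDB ensembles, "synthetic", or NULL.
#' @param rules Selection rules (list: `pins`, `n_highest`, `n_lowest`).
#' @param outdir Output directory for stage artifacts.
#' @param seed Seed for every stochastic stage; recorded in artifact headers.
#' @return Config list, class `pipeline_config`.
#' @export
pipeline_config <- function(native = mir1246_sequence(),
                            window = mir1246_window(),
                            motif_table = NULL, annotation = NULL,
                            organism = NULL,
                            engine = c("maxpair", "mfe", "vienna"),
                            vienna_path = NULL,
                            eps = 6, min_samples = 2L,
                            cut3d = "largest-gap",
                            atom_set = DEFAULT_ATOM_SET,
                            ensemble_dir = NULL,
                            rules = list(pins = character(), n_highest = 1L,
                                         n_lowest = 0L),
                            outdir = tempfile("exovar_run_"),
                            seed = 1L) {
  engine <- match.arg(engine)
  if (engine == "vienna" && is.null(vienna_path)) {
    stop("engine 'vienna' requires vienna_path")
  }
  structure(list(native = native, window = window, motif_table = motif_table,
                 annotation = annotation, organism = organism, engine = engine,
                 vienna_path = vienna_path, eps = eps,
                 min_samples = as.integer(min_samples), cut3d = cut3d,
                 atom_set = atom_set, ensemble_dir = ensemble_dir,
                 rules = rules, outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  flat <- config
  flat$outdir <- NULL  # fingerprint the analysis settings, not the destination
  flat$native <- as.character(config$native)
  flat$window <- unclass(config$window)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(lapply(flat, function(x) {
    if (is.data.frame(x)) "inline-table" else x
  }), auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

resolve_motif_table <- function(config) {
  mt <- config$motif_table
  if (is.data.frame(mt)) return(mt)
  if (is.character(mt)) return(read_motif_table(mt, organism = config$organism))
  synth <- make_motif_table(n_motifs = 25L, target = config$native,
                            seed = config$seed)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(synth$table, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_motif_table(tmp, organism = config$organism)
}

resolve_annotation <- function(config, motifs) {
  an <- config$annotation
  if (is.data.frame(an)) return(an)
  if (is.character(an)) return(read_annotation_table(an))
  make_annotation_table(motifs$gene_id, group_sizes = 2L)
}

#' Run the full in-silico screening workflow
#'
#' Executes the stages in order — variant enumeration, motif scanning /
#' summarizing / ranking, secondary-structure prediction or ingestion and
#' feature extraction, 2D Levenshtein+DBSCAN clustering, 3D ensemble
#' statistics and centroid clustering (when ensembles are available), and
#' rule-based candidate selection — writing one TSV per stage plus a JSON
#' summary under `config$outdir`. Every artifact carries a provenance header
#' (package version, seed, config fingerprint). Stages lacking inputs are
#' skipped with a message; reruns with the same config are byte-identical.
#'
#' @param config A `pipeline_config`.
#' @return List: `variants`, `hits`, `summaries`, `ranking`,
#'   `motif_frequency`, `structures`, `structure_report`, `cluster2d`,
#'   `ensemble_stats`, `cluster3d`, `selection`, `outdir`.
#' @export
run_insilico <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- c(sprintf("exovar %s", as.character(utils::packageVersion("exovar"))),
           sprintf("seed=%d", config$seed),
           sprintf("config=%s", config_fingerprint(config)))

  # 1 - variants
  variants <- enumerate_motif_variants(config$native, config$window)
  write_variant_table(variants, file.path(outdir, "variants.tsv"), hdr)
  seqs <- c(list(config$native),
            lapply(seq_len(nrow(variants)), function(i) {
              normalize_sequence(variants$sequence[i], id = as.character(variants$variant_id[i]))
            }))
  names(seqs) <- vapply(seqs, seq_id, "")
  write_fasta(seqs, file.path(outdir, "sequences.fasta"))

  # 2 - motif scanning
  motifs <- resolve_motif_table(config)
  annotation <- resolve_annotation(config, motifs)
  hits <- do.call(rbind, lapply(seqs, scan_motifs, motifs = motifs))
  rownames(hits) <- NULL
  write_hits(hits, file.path(outdir, "hits.tsv"), hdr)
  summaries <- do.call(rbind, lapply(names(seqs), function(id) {
    summarize_hits(hits, annotation, id)
  }))
  ranking <- rank_sequences(summaries)
  write_tsv_with_header(ranking, file.path(outdir, "ranking.tsv"), hdr)
  freq <- motif_frequency(hits, motifs)
  write_tsv_with_header(freq, file.path(outdir, "motif_frequency.tsv"), hdr)

  # 3 - secondary structures
  structures <- switch(config$engine,
    maxpair = lapply(seqs, fold_maxpair),
    mfe = lapply(seqs, fold_mfe_hairpin),
    vienna = read_vienna(config$vienna_path)
  )
  report <- structure_report(structures, config$window)
  write_tsv_with_header(report, file.path(outdir, "structure_report.tsv"), hdr)
  write_vienna(structures, file.path(outdir, "structures.dbn"))

  # 4 - 2D clustering
  dbs <- vapply(structures, function(x) x$dot_bracket, "")
  D2 <- pairwise_distances(dbs)
  cluster2d <- cluster_dbscan(D2, eps = config$eps, min_samples = config$min_samples)
  write_dist_matrix(D2, file.path(outdir, "dist2d.tsv"), hdr)
  write_assignments(cluster2d, file.path(outdir, "clusters2d.tsv"), hdr)

  # 5 - 3D arm (optional)
  stats3d <- NULL; cluster3d <- NULL
  if (!is.null(config$ensemble_dir)) {
    if (identical(config$ensemble_dir, "synthetic")) {
      gen <- make_structure_ensembles(seed = config$seed)
      ensembles <- gen$ensembles
    } else {
      files <- sort(list.files(config$ensemble_dir, pattern = "\\.pdb$",
                               full.names = TRUE))
      if (length(files) == 0L) stop("3D stage: no PDB files in ", config$ensemble_dir)
      ensembles <- lapply(files, function(f) {
        read_pdb_ensemble(f, sequence_id = sub("^ens_", "", sub("\\.pdb$", "", basename(f))))
      })
      names(ensembles) <- vapply(ensembles, function(e) e$sequence_id, "")
    }
    stats3d <- do.call(rbind, lapply(ensembles, ensemble_stats,
                                     atom_set = config$atom_set))
    rownames(stats3d) <- NULL
    write_tsv_with_header(stats3d, file.path(outdir, "ensemble_stats.tsv"), hdr)
    centroids <- lapply(ensembles, ensemble_centroid_model,
                        atom_set = config$atom_set)
    cc <- cross_ensemble_cluster(centroids, cut = config$cut3d,
                                 atom_set = config$atom_set)
    cluster3d <- cc$clusters
    write_tsv_with_header(cc$stats, file.path(outdir, "cluster3d_stats.tsv"), hdr)
    write_assignments(cluster3d, file.path(outdir, "clusters3d.tsv"), hdr)
  } else {
    message("3D stage skipped: no ensembles configured")
  }

  # 6 - selection
  selection <- select_candidates(summaries, cluster2d = cluster2d,
                                 cluster3d = cluster3d, rules = config$rules,
                                 fold_flags = stats::setNames(report$folded,
                                                              report$sequence_id),
                                 native_id = seq_id(config$native))
  write_tsv_with_header(selection, file.path(outdir, "selection.tsv"), hdr)

  summary_json <- list(
    seed = config$seed, config = config_fingerprint(config),
    n_variants = nrow(variants),
    n_hits = nrow(hits),
    n_clusters_2d = cluster2d$n_clusters,
    n_clusters_3d = if (is.null(cluster3d)) NULL else cluster3d$n_clusters,
    selected = selection$sequence_id
  )
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  list(variants = variants, hits = hits, summaries = summaries,
       ranking = ranking, motif_frequency = freq, structures = structures,
       structure_report = report, cluster2d = cluster2d,
       ensemble_stats = stats3d, cluster3d = cluster3d,
       selection = selection, outdir = outdir)
}

#' Rule-based selection of variants for wet-lab validation
#'
#' Rule 1 (structure-divergent): select every variant that does not share a
#' cluster with the native sequence in any of the available clusterings
#' (noise counts as not sharing). Rule 2 (RBP-count extremes): among the
#' remaining variants, select the `n_highest` highest and `n_lowest` lowest
#' by distinct-RBP count (ties to the smaller id). Rule 3: user-pinned ids
#' are always included. Every selected id carries its rationale tags.
#'
#' @param summaries Data frame with `sequence_id`, `n_motif_hits`,
#'   `n_distinct_rbps` (e.g. from [summarize_hits()] or
#'   [mir1246_rbp_counts()]).
#' @param cluster2d,cluster3d `cluster_result` objects or NULL when a
#'   clustering is unavailable.
#' @param rules List: `pins` (character ids), `n_highest`, `n_lowest`.
#' @param fold_flags Optional named logical vector (id -> folds into a
#'   hairpin), recorded in the report.
#' @param native_id Id of the native sequence (default "0").
#' @return Data frame: `sequence_id`, `tags` (semicolon-joined rationale),
#'   `cluster2d`, `cluster3d`, `folded`, `n_motif_hits`, `n_distinct_rbps`;
#'   zero rows (with a warning) when the rules select nothing.
#' @export
select_candidates <- function(summaries, cluster2d = NULL, cluster3d = NULL,
                              rules = list(pins = character(), n_highest = 1L,
                                           n_lowest = 0L),
                              fold_flags = NULL, native_id = "0") {
  if (!native_id %in% summaries$sequence_id) {
    stop("native id '", native_id, "' absent from summaries")
  }
  clusterings <- Filter(Negate(is.null), list(cluster2d, cluster3d))
  ids <- setdiff(summaries$sequence_id, native_id)

  divergent <- character()
  if (length(clusterings) > 0L) {
    divergent <- Filter(function(id) {
      all(vapply(clusterings, function(cl) {
        a <- cl$assignments
        if (!id %in% names(a) || !native_id %in% names(a)) return(FALSE)
        is.na(a[[id]]) || is.na(a[[native_id]]) || a[[id]] != a[[native_id]]
      }, TRUE))
    }, ids)
  }

  remaining <- setdiff(ids, divergent)
  rem <- summaries[summaries$sequence_id %in% remaining, , drop = FALSE]
  id_num <- suppressWarnings(as.numeric(rem$sequence_id))
  id_key <- if (anyNA(id_num)) rem$sequence_id else id_num
  n_hi <- if (is.null(rules$n_highest)) 0L else rules$n_highest
  n_lo <- if (is.null(rules$n_lowest)) 0L else rules$n_lowest
  highest <- rem$sequence_id[order(-rem$n_distinct_rbps, id_key)][seq_len(min(n_hi, nrow(rem)))]
  lowest <- rem$sequence_id[order(rem$n_distinct_rbps, id_key)][seq_len(min(n_lo, nrow(rem)))]
  pins <- intersect(as.character(rules$pins %||% character()), summaries$sequence_id)

  selected <- unique(c(divergent, highest, lowest, pins))
  if (length(selected) == 0L) {
    warning("selection rules matched no variant")
    return(data.frame(sequence_id = character(), tags = character(),
                      cluster2d = integer(), cluster3d = integer(),
                      folded = logical(), n_motif_hits = integer(),
                      n_distinct_rbps = integer(), stringsAsFactors = FALSE))
  }
  s_num <- suppressWarnings(as.numeric(selected))
  selected <- selected[order(if (anyNA(s_num)) selected else s_num)]
  tag_of <- function(id) {
    tags <- c(if (id %in% divergent) "structure-divergent",
              if (id %in% c(highest, lowest)) "rbp-count-extreme",
              if (id %in% pins) "user-pinned")
    paste(tags, collapse = ";")
  }
  lookup <- function(cl, id) {
    if (is.null(cl) || !id %in% names(cl$assignments)) return(NA_integer_)
    cl$assignments[[id]]
  }
  rows <- lapply(selected, function(id) {
    srow <- summaries[summaries$sequence_id == id, , drop = FALSE]
    data.frame(sequence_id = id, tags = tag_of(id),
               cluster2d = lookup(cluster2d, id), cluster3d = lookup(cluster3d, id),
               folded = if (!is.null(fold_flags) && id %in% names(fold_flags))
                 unname(fold_flags[[id]]) else NA,
               n_motif_hits = srow$n_motif_hits[1],
               n_distinct_rbps = srow$n_distinct_rbps[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
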