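# IUPAC-aware motif scanning against an RBP consensus-motif table,
# homolog-group collapsing and per-sequence binding-site ranking.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

is_iupac_rna <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  length(chars) > 0L && all(chars %in% names(IUPAC_RNA))
}

# All matches of one IUPAC pattern in one plain RNA string.
# Returns a data.frame(start, end, matched); overlapping matches included.
iupac_hits <- function(sequence, pattern) {
  s <- strsplit(as.character(sequence), "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); k <- length(p)
  empty <- data.frame(start = integer(), end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  if (k == 0L || k > n) return(empty)
  sets <- IUPAC_RNA[p]
  starts <- integer()
  for (i in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1L] %in% sets[[j]]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  if (length(starts) == 0L) return(empty)
  data.frame(start = starts, end = starts + k - 1L,
             matched = substring(as.character(sequence), starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

# ATtRACT-style column names accepted out of the box.
DEFAULT_MOTIF_COLMAP <- c(
  motif_id = "Matrix_id", pattern = "Motif", gene_id = "Gene_id",
  gene_name = "Gene_name", organism = "Organism", score = "Score"
)

#' Read a consensus-motif table (ATtRACT dialect)
#'
#' Tab-separated with a header. Canonical column names are `motif_id`,
#' `pattern`, `gene_id`, `gene_name`, `organism` and optional `score`; the
#' ATtRACT export names (`Matrix_id`, `Motif`, `Gene_id`, `Gene_name`,
#' `Organism`, `Score`) are accepted unmodified, and other mappings can be
#' supplied via `col_map` (named vector: canonical name -> file column).
#' DNA-alphabet patterns are normalized (T to U, uppercase). Rows whose
#' pattern contains a non-IUPAC character are skipped with a warning giving
#' their line numbers. Duplicate (motif_id, gene_id) pairs keep the first
#' occurrence.
#'
#' @param path TSV file.
#' @param organism Optional filter; only rows with this organism are kept.
#' @param col_map Optional named character vector overriding the ATtRACT
#'   column mapping.
#' @return Data frame with canonical columns (score is NA when absent).
#' @export
read_motif_table <- function(path, organism = NULL, col_map = NULL) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("motif_id", "pattern", "gene_id", "gene_name", "organism")
  cmap <- if (is.null(col_map)) DEFAULT_MOTIF_COLMAP else col_map
  out <- list()
  for (col in c(required, "score")) {
    if (col %in% names(raw)) {
      out[[col]] <- raw[[col]]
    } else if (!is.null(cmap[col]) && !is.na(cmap[col]) && cmap[[col]] %in% names(raw)) {
      out[[col]] <- raw[[cmap[[col]]]]
    } else if (col == "score") {
      out[[col]] <- rep(NA_real_, nrow(raw))
    } else {
      stop("motif table ", path, " is missing required column '", col, "'")
    }
  }
  df <- data.frame(out, stringsAsFactors = FALSE)
  df$pattern <- chartr("Tt", "Uu", toupper(df$pattern))
  bad <- which(!vapply(df$pattern, is_iupac_rna, TRUE))
  if (length(bad) > 0L) {
    warning(length(bad), " motif row(s) skipped for invalid IUPAC characters (file line ",
            paste(bad + 1L, collapse = ", "), ")")
    df <- df[-bad, , drop = FALSE]
  }
  if (!is.null(organism)) df <- df[df$organism == organism, , drop = FALSE]
  df <- df[!duplicated(df[, c("motif_id", "gene_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a gene-to-homolog-group annotation table
#'
#' Offline replacement for live homology lookups: TSV with columns `gene_id`,
#' `homolog_group_id` and optional `transcript_id`, `protein_id`, `go_terms`
#' (semicolon-separated). Every gene id must appear in exactly one group.
#'
#' @param path TSV file.
#' @return Data frame with at least `gene_id` and `homolog_group_id`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in c("gene_id", "homolog_group_id")) {
    if (!col %in% names(df)) stop("annotation table missing required column '", col, "'")
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0L) {
    stop("gene id(s) in more than one homolog group: ", paste(dup, collapse = ", "))
  }
  df
}

#' Scan a sequence against a motif table
#'
#' Every position where a pattern matches under IUPAC semantics yields one hit
#' per (motif_id, gene_id) row; overlapping and self-overlapping matches are
#' all reported. Hits are sorted by (start, motif_id).
#'
#' @param seq An `rna_sequence` (normalized).
#' @param motifs Data frame from [read_motif_table()] (or any frame with
#'   columns `motif_id`, `pattern`, `gene_id`).
#' @return Data frame with columns `sequence_id`, `motif_id`, `gene_id`,
#'   `start`, `end`, `matched`.
#' @examples
#' motifs <- data.frame(motif_id = c("m1", "m2"), pattern = c("GGAG", "GCAG"),
#'                      gene_id = c("g1", "g2"))
#' scan_motifs(mir1246_sequence(), motifs)  # hits at 12-15 and 15-18
#' @export
scan_motifs <- function(seq, motifs) {
  empty <- data.frame(sequence_id = character(), motif_id = character(),
                      gene_id = character(), start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  if (is.null(motifs) || nrow(motifs) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    h <- iupac_hits(seq, motifs$pattern[i])
    if (nrow(h) == 0L) return(NULL)
    data.frame(sequence_id = seq_id(seq), motif_id = motifs$motif_id[i],
               gene_id = motifs$gene_id[i], start = h$start, end = h$end,
               matched = h$matched, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$start, hits$motif_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse scan hits into a per-sequence binding summary
#'
#' `n_motif_hits` counts every hit; `n_distinct_rbps` counts distinct homolog
#' groups among the hit genes (genes absent from the annotation degrade
#' gracefully into their own singleton groups, with a message).
#'
#' @param hits Data frame from [scan_motifs()] (possibly several sequences).
#' @param annotation Data frame from [read_annotation_table()], or NULL to
#'   treat every gene as its own group.
#' @param sequence_id Which sequence to summarize.
#' @return One-row data frame: `sequence_id`, `n_motif_hits`,
#'   `n_distinct_rbps`, `gene_ids` (comma-joined sorted unique ids).
#' @export
summarize_hits <- function(hits, annotation = NULL, sequence_id) {
  h <- hits[hits$sequence_id == sequence_id, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(sequence_id = sequence_id, n_motif_hits = 0L,
                      n_distinct_rbps = 0L, gene_ids = "",
                      stringsAsFactors = FALSE))
  }
  genes <- h$gene_id
  if (is.null(annotation)) {
    groups <- genes
  } else {
    idx <- match(genes, annotation$gene_id)
    groups <- annotation$homolog_group_id[idx]
    missing <- is.na(idx)
    if (any(missing)) {
      message(sum(missing), " hit(s) with gene ids absent from the annotation ",
              "treated as singleton groups")
      groups[missing] <- paste0("ungrouped:", genes[missing])
    }
  }
  data.frame(
    sequence_id = sequence_id,
    n_motif_hits = nrow(h),
    n_distinct_rbps = length(unique(groups)),
    gene_ids = paste(sort(unique(genes)), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Rank per-sequence summaries by binding-site content
#'
#' Descending by `n_motif_hits`, ties broken by descending `n_distinct_rbps`,
#' then ascending `sequence_id` (numeric order when all ids are numeric).
#'
#' @param summaries Data frame of rows from [summarize_hits()].
#' @return The same frame, reordered (stable, total order).
#' @export
rank_sequences <- function(summaries) {
  ids <- suppressWarnings(as.numeric(summaries$sequence_id))
  id_key <- if (anyNA(ids)) summaries$sequence_id else ids
  ord <- order(-summaries$n_motif_hits, -summaries$n_distinct_rbps, id_key)
  out <- summaries[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally motif patterns across all hits
#'
#' @param hits Data frame from [scan_motifs()] over one or many sequences.
#' @param motifs The motif table used for scanning (to map motif_id to
#'   pattern).
#' @return Data frame (`pattern`, `count`) sorted by descending count then
#'   pattern.
#' @export
motif_frequency <- function(hits, motifs) {
  if (nrow(hits) == 0L) {
    return(data.frame(pattern = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  pat <- motifs$pattern[match(hits$motif_id, motifs$motif_id)]
  tab <- table(pat)
  df <- data.frame(pattern = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write scan hits to TSV
#' @param hits Data frame from [scan_motifs()].
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @export
write_hits <- function(hits, path, header = character()) {
  write_tsv_with_header(hits, path, header)
}
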