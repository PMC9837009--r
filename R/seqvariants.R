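RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a raw nucleotide string into a validated RNA sequence
#'
#' Uppercases, strips whitespace and maps the DNA alphabet (T) onto RNA (U).
#' Any character outside the DNA/RNA alphabet aborts with a message naming the
#' offending character and its 1-based position in the stripped input.
#'
#' @param raw Character scalar, the sequence as typed or read from file.
#' @param id Label attached to the sequence (stored in the `id` attribute).
#' @return A character scalar over \{A,C,G,U\} with attributes `id` and class
#'   `rna_sequence`.
#' @examples
#' normalize_sequence("aaugg", "toy")
#' normalize_sequence("AATGGATTTTTGGAGCAGG", "dna-input")
#' @export
normalize_sequence <- function(raw, id = "seq") {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[[:space:]]", "", raw)
  if (nchar(s) == 0L) stop("sequence '", id, "' is empty after whitespace stripping")
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c(RNA_BASES, "T"))
  if (length(bad) > 0L) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "' (alphabet is A/C/G/T/U)")
  }
  s <- chartr("T", "U", s)
  structure(s, id = id, class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d nt)\n%s\n", attr(x, "id"), nchar(x), unclass(x)))
  invisible(x)
}

seq_id <- function(x) {
  id <- attr(x, "id")
  if (is.null(id)) "seq" else id
}

seq_chars <- function(x) strsplit(as.character(x), "")[[1]]

#' Define a motif window on a sequence
#'
#' 1-based inclusive coordinates. When `sequence` is supplied the window is
#' checked against it: the substring at `[start, end]` must equal `pattern`.
#'
#' @param start,end 1-based inclusive bounds.
#' @param pattern The motif occupying the window (A/C/G/U).
#' @param sequence Optional `rna_sequence` to validate against.
#' @return A list with elements `start`, `end`, `pattern`, class `motif_window`.
#' @export
motif_window <- function(start, end, pattern, sequence = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) stop("invalid window coordinates [", start, ", ", end, "]")
  if (end - start + 1L != nchar(pattern)) {
    stop("window width ", end - start + 1L, " does not match pattern length ", nchar(pattern))
  }
  if (!is.null(sequence)) {
    if (end > nchar(sequence)) {
      stop("window [", start, ", ", end, "] exceeds sequence length ", nchar(sequence))
    }
    found <- substr(sequence, start, end)
    if (found != pattern) {
      stop("sequence has '", found, "' at [", start, ", ", end, "], expected '", pattern, "'")
    }
  }
  structure(list(start = start, end = end, pattern = pattern), class = "motif_window")
}

#' Enumerate all single-nucleotide substitutions inside a motif window
#'
#' Produces one variant per (window position, alternative base) combination:
#' window positions are visited 5'-to-3' and, at each position, alternative
#' bases in the fixed order A < C < G < U skipping the native base, numbering
#' the variants sequentially from 1. The native sequence itself (id 0 by
#' convention) is not in the output. For the 4-nt GGAG window of miR-1246 this
#' yields 12 variants. The published study numbers three of them differently;
#' see [mir1246_paper_aliases()] for the internal-to-published id map.
#'
#' @param native An `rna_sequence`.
#' @param window A `motif_window` valid against `native`.
#' @return A data.frame with columns `variant_id`, `position`, `ref`, `alt`,
#'   `sequence` (one row per variant).
#' @examples
#' v <- enumerate_motif_variants(mir1246_sequence(), mir1246_window())
#' nrow(v)  # 12
#' @export
enumerate_motif_variants <- function(native, window) {
  window <- motif_window(window$start, window$end, window$pattern, sequence = native)
  chars <- seq_chars(native)
  rows <- list()
  k <- 0L
  for (pos in seq.int(window$start, window$end)) {
    ref <- chars[pos]
    for (alt in setdiff(RNA_BASES, ref)) {
      k <- k + 1L
      mutated <- chars
      mutated[pos] <- alt
      rows[[k]] <- data.frame(
        variant_id = k, position = pos, ref = ref, alt = alt,
        sequence = paste(mutated, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Convert a 3'-end index into a 5'-based position
#'
#' The published description of the variants counts bases from the 3' end
#' ("the sixth base from the 3' end"); this converts such an index into the
#' usual 1-based position from the 5' end: `length - k + 1`.
#'
#' @param length Sequence length in nt.
#' @param k 1-based index from the 3' end.
#' @export
pos_from_3prime <- function(length, k) {
  length <- as.integer(length); k <- as.integer(k)
  if (k < 1L || k > length) stop("index ", k, " from the 3' end is outside 1..", length)
  length - k + 1L
}

#' Generate a random sequence carrying one placed motif and no excluded motifs
#'
#' Rejection sampling: draw uniform random bases, overwrite the window with the
#' placed pattern, and accept the draw only if scanning against the excluded
#' IUPAC pattern list yields zero hits. Used to build control probes that carry
#' a single EXO-motif at the native location and no other EXO-motif anywhere.
#'
#' @param length Target length in nt.
#' @param placed A `motif_window` giving the pattern and its coordinates.
#' @param excluded Character vector of IUPAC patterns that must not occur
#'   anywhere in the output (the placed pattern must not match any of them).
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @param max_attempts Rejection-sampling budget (default 10000).
#' @param id Label for the returned sequence.
#' @return An `rna_sequence` of the requested length.
#' @export
generate_constrained_sequence <- function(length, placed, excluded = character(),
                                          seed = 1L, max_attempts = 10000L,
                                          id = "random") {
  if (placed$end > length) stop("placed window does not fit inside length ", length)
  placed_hits <- sum(vapply(excluded, function(p) nrow(iupac_hits(placed$pattern, p)), 1L))
  if (placed_hits > 0L) stop("the placed pattern itself matches an excluded pattern")
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    chars <- sample(RNA_BASES, length, replace = TRUE)
    chars[seq.int(placed$start, placed$end)] <- strsplit(placed$pattern, "")[[1]]
    s <- paste(chars, collapse = "")
    n_hits <- sum(vapply(excluded, function(p) nrow(iupac_hits(s, p)), 1L))
    if (n_hits == 0L) return(normalize_sequence(s, id))
  }
  stop("no admissible sequence found within ", max_attempts, " attempts")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file; multi-record files accepted; T is mapped to U.
#' @return Named list of `rna_sequence` objects (names = record ids).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    normalize_sequence(as.character(set[[i]]), id = names(set)[i])
  })
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file (wrapped at 60 columns)
#'
#' @param seqs A single `rna_sequence` or a list of them.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, as.character, ""))
  names(set) <- vapply(seqs, seq_id, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a variant table to TSV
#'
#' Columns: variant_id, position, ref, alt, sequence.
#' @param variants Data frame from [enumerate_motif_variants()].
#' @param path Output path.
#' @param header Optional comment lines (prefixed with `#`) written first.
#' @export
write_variant_table <- function(variants, path, header = character()) {
  write_tsv_with_header(variants, path, header)
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_body <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
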