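# Secondary structures for short RNAs: base-pair-maximization and simplified
# minimum-free-energy hairpin engines, Vienna dot-bracket I/O, and hairpin
# feature extraction (stem/loop geometry, motif placement).

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

can_pair <- function(a, b) paste0(a, b) %in% ALLOWED_PAIRS

# dot-bracket -> pair list; errors on unbalanced brackets
dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c("(", ")", "."))) stop("dot-bracket contains characters outside (, ), .")
  stack <- integer()
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1L]] <- c(j, i)
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets: unmatched '(' at position ", stack[1])
  if (length(pairs) == 0L) return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, pairs)
  colnames(m) <- c("i", "j")
  m[order(m[, "i"]), , drop = FALSE]
}

pairs_to_dotbracket <- function(pairs, n) {
  chars <- rep(".", n)
  if (nrow(pairs) > 0L) {
    chars[pairs[, "i"]] <- "("
    chars[pairs[, "j"]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Construct and validate a secondary structure
#'
#' Enforces the structural invariants used throughout the 2D arm: the
#' dot-bracket string matches the sequence length, brackets are balanced and
#' strictly nested (no pseudoknots, guaranteed by dot-bracket semantics),
#' every hairpin loop spans at least `min_loop` unpaired bases, and every
#' paired base combination is one of AU/UA/GC/CG/GU/UG.
#'
#' @param sequence_id Label.
#' @param sequence The RNA string (A/C/G/U).
#' @param dot_bracket Structure string over `(`, `)`, `.`.
#' @param energy Optional folding free energy in kcal/mol.
#' @param min_loop Minimum hairpin loop size (default 3 nt).
#' @return List with elements `sequence_id`, `sequence`, `dot_bracket`,
#'   `pairs` (matrix, 1-based i < j), `energy`; class `secondary_structure`.
#' @export
secondary_structure <- function(sequence_id, sequence, dot_bracket,
                                energy = NA_real_, min_loop = 3L) {
  sequence <- as.character(sequence)
  if (nchar(dot_bracket) != nchar(sequence)) {
    stop("record '", sequence_id, "': dot-bracket length ", nchar(dot_bracket),
         " does not match sequence length ", nchar(sequence))
  }
  pairs <- dotbracket_pairs(dot_bracket)
  chars <- strsplit(sequence, "")[[1]]
  if (nrow(pairs) > 0L) {
    loop_ok <- pairs[, "j"] - pairs[, "i"] - 1L >= min_loop
    if (!all(loop_ok)) {
      k <- which(!loop_ok)[1]
      stop("record '", sequence_id, "': pair (", pairs[k, "i"], ", ", pairs[k, "j"],
           ") closes a loop shorter than ", min_loop, " nt")
    }
    comb <- paste0(chars[pairs[, "i"]], chars[pairs[, "j"]])
    bad <- which(!comb %in% ALLOWED_PAIRS)
    if (length(bad) > 0L) {
      stop("record '", sequence_id, "': disallowed base pair ", comb[bad[1]],
           " at (", pairs[bad[1], "i"], ", ", pairs[bad[1], "j"], ")")
    }
  }
  structure(list(sequence_id = as.character(sequence_id), sequence = sequence,
                 dot_bracket = dot_bracket, pairs = pairs, energy = energy),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  e <- if (is.na(x$energy)) "" else sprintf(" (%.2f)", x$energy)
  cat(sprintf(">%s\n%s\n%s%s\n", x$sequence_id, x$sequence, x$dot_bracket, e))
  invisible(x)
}

#' Fold by base-pair maximization (Nussinov recursion)
#'
#' Returns a nested structure maximizing the number of AU/GC/GU pairs subject
#' to a minimum loop of `min_loop` unpaired bases. Traceback is deterministic:
#' at each subproblem the pairing branch is preferred over leaving the 5' base
#' unpaired whenever it attains the optimum, and among tying partners the
#' 5'-most is chosen.
#'
#' @param seq An `rna_sequence` (length >= min_loop + 2).
#' @param min_loop Minimum hairpin loop (default 3).
#' @return A `secondary_structure` (energy NA; this engine does not score).
#' @examples
#' fold_maxpair(normalize_sequence("GGGAAACCC", "toy"))$dot_bracket  # "(((...)))"
#' @export
fold_maxpair <- function(seq, min_loop = 3L) {
  s <- seq_chars(seq)
  n <- length(s)
  if (n < min_loop + 2L) stop("sequence shorter than min_loop + 2")
  M <- matrix(0L, n, n)
  for (span in seq.int(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      for (k in seq.int(i + min_loop + 1L, j)) {
        if (can_pair(s[i], s[k])) {
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
          best <- max(best, 1L + inner + rest)
        }
      }
      M[i, j] <- best
    }
  }
  pairs <- list()
  traceback <- function(i, j) {
    while (i < j) {
      if (M[i, j] == 0L) return(invisible())
      paired <- FALSE
      for (k in seq.int(i + min_loop + 1L, j)) {
        if (can_pair(s[i], s[k])) {
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
          if (1L + inner + rest == M[i, j]) {
            pairs[[length(pairs) + 1L]] <<- c(i, k)
            if (k + 1L <= j) traceback(k + 1L, j)
            i <- i + 1L; j <- k - 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  traceback(1L, n)
  pm <- if (length(pairs) == 0L) {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j")))
  } else {
    m <- do.call(rbind, pairs); colnames(m) <- c("i", "j"); m[order(m[, 1]), , drop = FALSE]
  }
  secondary_structure(seq_id(seq), as.character(seq), pairs_to_dotbracket(pm, n),
                      min_loop = min_loop)
}

#' Packaged stand-in energy parameters
#'
#' A minimal nearest-neighbor-style table with Turner-like magnitudes: helix
#' stacking energies (kcal/mol, all <= 0) indexed by the two adjacent pairs,
#' hairpin-loop initiation penalties by loop size (all >= 0, log-extrapolated
#' beyond 9 nt), and a terminal AU/GU penalty. It is a documented stand-in
#' that supports sign and ordering comparisons between candidate hairpins; it
#' does not reproduce any published predictor's energies.
#' @return List with elements `stack` (6x6 matrix over AU/CG/GC/UA/GU/UG),
#'   `hairpin` (named vector, loop sizes 3-9), `terminal_au` (scalar).
#' @export
default_energy_params <- function() {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # columns: 3' pair following the row pair (5' side)
    #  AU    CG    GC    UA    GU    UG
    -0.9, -2.2, -2.1, -1.1, -0.6, -1.4,  # AU
    -2.1, -3.3, -2.4, -2.1, -1.4, -2.1,  # CG
    -2.4, -3.4, -3.3, -2.2, -1.5, -2.5,  # GC
    -1.3, -2.4, -2.1, -0.9, -1.0, -1.3,  # UA
    -1.3, -2.5, -2.1, -1.4, -0.5, -1.3,  # GU
    -1.0, -1.5, -1.4, -0.6, -0.3, -0.5   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  hairpin <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4, `7` = 6.0,
               `8` = 6.0, `9` = 6.2)
  list(stack = stack, hairpin = hairpin, terminal_au = 0.5)
}

hairpin_penalty <- function(loop, params) {
  tab <- params$hairpin
  sizes <- as.integer(names(tab))
  if (loop <= max(sizes)) return(unname(tab[as.character(loop)]))
  unname(tab[as.character(max(sizes))]) + 1.1 * log(loop / max(sizes))
}

# energy of one candidate hairpin: outer pair (i, j), h consecutive pairs
single_hairpin_energy <- function(s, i, j, h, params) {
  ptypes <- paste0(s[i + seq_len(h) - 1L], s[j - seq_len(h) + 1L])
  if (any(!ptypes %in% ALLOWED_PAIRS)) return(NA_real_)
  loop <- j - i - 2L * h + 1L
  e <- hairpin_penalty(loop, params)
  if (h >= 2L) {
    for (t in seq_len(h - 1L)) e <- e + params$stack[ptypes[t], ptypes[t + 1L]]
  }
  if (ptypes[1] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal_au
  e
}

#' Fold into the minimum-energy single hairpin (simplified engine)
#'
#' Enumerates every candidate single-hairpin structure (one contiguous helix
#' of `h` consecutive allowed pairs closed by a terminal loop of >= `min_loop`
#' nt) over all (helix 5' start, helix 3' end, helix length) triples, scores
#' each as stacking energies + hairpin-loop penalty + terminal AU/GU penalty,
#' and returns the lowest-energy candidate if its energy is negative —
#' otherwise the all-unpaired structure with energy exactly 0. Ties resolve
#' to the 5'-most outer pair, then the smaller 3' position, then the longer
#' helix.
#'
#' @param seq An `rna_sequence`.
#' @param params Energy parameters, see [default_energy_params()].
#' @param min_loop Minimum loop size (default 3).
#' @return A `secondary_structure` with `energy` set (<= 0 always).
#' @export
fold_mfe_hairpin <- function(seq, params = default_energy_params(), min_loop = 3L) {
  s <- seq_chars(seq)
  n <- length(s)
  best <- list(energy = 0)
  if (n >= min_loop + 2L) {
    for (i in seq_len(n - min_loop - 1L)) {
      for (j in seq.int(i + min_loop + 1L, n)) {
        h_max <- (j - i + 1L - min_loop) %/% 2L
        for (h in seq_len(h_max)) {
          e <- single_hairpin_energy(s, i, j, h, params)
          if (!is.na(e) && e < best$energy - 1e-12) {
            best <- list(energy = e, i = i, j = j, h = h)
          }
        }
      }
    }
  }
  if (best$energy >= 0) {
    return(secondary_structure(seq_id(seq), as.character(seq),
                               strrep(".", n), energy = 0, min_loop = min_loop))
  }
  chars <- rep(".", n)
  chars[best$i + seq_len(best$h) - 1L] <- "("
  chars[best$j - seq_len(best$h) + 1L] <- ")"
  secondary_structure(seq_id(seq), as.character(seq), paste(chars, collapse = ""),
                      energy = best$energy, min_loop = min_loop)
}

#' Read structures from a Vienna dot-bracket file
#'
#' Records of 2 or 3 lines: `>id`, sequence, and (optionally) a dot-bracket
#' line with an optional trailing `(energy)` suffix. Each record is validated
#' through [secondary_structure()]; malformed records abort with the record
#' id in the message.
#'
#' @param path Input file.
#' @return Named list of `secondary_structure` objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) stop("expected '>' header at line ", i, " of ", path)
    id <- sub("^>\\s*", "", lines[i])
    if (i + 1L > length(lines)) stop("record '", id, "': missing sequence line")
    sequence <- trimws(lines[i + 1L])
    i <- i + 2L
    db <- NULL; energy <- NA_real_
    if (i <= length(lines) && !startsWith(lines[i], ">")) {
      m <- regmatches(trimws(lines[i]),
                      regexec("^([().]+)(?:\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?$", trimws(lines[i])))[[1]]
      if (length(m) == 0L) stop("record '", id, "': malformed structure line")
      db <- m[2]
      if (nzchar(m[3])) energy <- as.numeric(m[3])
      i <- i + 1L
    }
    if (is.null(db)) db <- strrep(".", nchar(sequence))
    out[[id]] <- secondary_structure(id, normalize_sequence(sequence, id), db, energy)
  }
  out
}

#' Write structures to a Vienna dot-bracket file
#'
#' @param structures List of `secondary_structure` objects.
#' @param path Output file. Energies, when present, are appended as
#'   `(value)` after the dot-bracket.
#' @export
write_vienna <- function(structures, path) {
  lines <- unlist(lapply(structures, function(x) {
    e <- if (is.na(x$energy)) "" else sprintf(" (%.2f)", x$energy)
    c(paste0(">", x$sequence_id), x$sequence, paste0(x$dot_bracket, e))
  }))
  writeLines(lines, path)
  invisible(path)
}

# maximal contiguous helix containing the innermost pair (i, j)
helix_around <- function(pairs, i, j) {
  key <- paste(pairs[, "i"], pairs[, "j"])
  h <- 1L
  while (paste(i - h, j + h) %in% key) h <- h + 1L
  h
}

#' Extract hairpin features and EXO-motif placement from a structure
#'
#' Hairpins are the innermost pairs (no pair nested inside). The reported
#' hairpin is the one with the longest maximal contiguous helix, ties broken
#' by GC-pair count then 5'-most position. `loop_length` is the span enclosed
#' by its innermost pair; `stem_length` the helix pair count. The motif is
#' classified `stem` when every window position is paired, `loop` when every
#' window position lies within the closing pair's span (the loop plus its
#' closing pair), `unpaired` when the structure has no pairs at all, and
#' `mixed` otherwise.
#'
#' @param s A `secondary_structure`.
#' @param window A `motif_window`.
#' @return List: `n_hairpins`, `stem_length`, `loop_length`, `motif_location`.
#' @export
extract_hairpin_features <- function(s, window) {
  pairs <- s$pairs
  if (nrow(pairs) == 0L) {
    return(list(n_hairpins = 0L, stem_length = 0L, loop_length = 0L,
                motif_location = "unpaired"))
  }
  inner <- vapply(seq_len(nrow(pairs)), function(k) {
    !any(pairs[, "i"] > pairs[k, "i"] & pairs[, "j"] < pairs[k, "j"])
  }, TRUE)
  hp <- pairs[inner, , drop = FALSE]
  chars <- strsplit(s$sequence, "")[[1]]
  helix <- vapply(seq_len(nrow(hp)), function(k) helix_around(pairs, hp[k, "i"], hp[k, "j"]), 1L)
  gc <- vapply(seq_len(nrow(hp)), function(k) {
    h <- helix[k]
    comb <- paste0(chars[hp[k, "i"] - seq_len(h) + 1L], chars[hp[k, "j"] + seq_len(h) - 1L])
    sum(comb %in% c("GC", "CG"))
  }, 1L)
  sel <- order(-helix, -gc, hp[, "i"])[1]
  i0 <- unname(hp[sel, "i"]); j0 <- unname(hp[sel, "j"])
  wpos <- seq.int(window$start, window$end)
  paired_pos <- c(pairs[, "i"], pairs[, "j"])
  location <- if (all(wpos %in% paired_pos)) {
    "stem"
  } else if (all(wpos >= i0 & wpos <= j0)) {
    "loop"
  } else {
    "mixed"
  }
  list(n_hairpins = nrow(hp), stem_length = unname(helix[sel]),
       loop_length = j0 - i0 - 1L, motif_location = location)
}

#' Tabulate a structure set into the per-sequence structure report
#'
#' @param structures Named list of `secondary_structure` objects.
#' @param window The motif window used for placement calls.
#' @return Data frame: `sequence_id`, `folded`, `energy`, `stem_length`,
#'   `loop_length`, `motif_location`.
#' @export
structure_report <- function(structures, window) {
  rows <- lapply(structures, function(x) {
    f <- extract_hairpin_features(x, window)
    data.frame(sequence_id = x$sequence_id, folded = nrow(x$pairs) > 0L,
               energy = x$energy, stem_length = f$stem_length,
               loop_length = f$loop_length, motif_location = f$motif_location,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
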