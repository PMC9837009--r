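# Tertiary-structure arm: multi-model PDB ensembles, Kabsch superposition,
# RMSD matrices, per-ensemble statistics and cross-ensemble clustering.

DEFAULT_ATOM_SET <- c("P", "C4'", "C1'")

# a model is a data.frame(resno, resname, atom, x, y, z)
validate_model <- function(m, label = "model") {
  needed <- c("resno", "resname", "atom", "x", "y", "z")
  if (!all(needed %in% names(m))) stop(label, " lacks columns ", paste(needed, collapse = ", "))
  if (any(!is.finite(as.matrix(m[, c("x", "y", "z")])))) {
    stop(label, " contains non-finite coordinates")
  }
  if (is.unsorted(m$resno)) stop(label, " has non-increasing residue numbers")
  m
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM records via `bio3d` (fixed-width PDB columns); HETATM records
#' are ignored and alternate locations other than blank/'A' are skipped.
#' Files without MODEL records yield a single-model ensemble.
#'
#' @param path PDB file.
#' @param sequence_id Ensemble label (defaults to the file name without
#'   extension).
#' @return List with elements `sequence_id` and `models` (list of model data
#'   frames with columns resno, resname, atom, x, y, z); class `ensemble3d`.
#' @export
read_pdb_ensemble <- function(path, sequence_id = NULL) {
  if (is.null(sequence_id)) sequence_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep <- atom$type == "ATOM" & (is.na(atom$alt) | atom$alt %in% c("", "A"))
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no ATOM records in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- which(keep)
  models <- lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
    validate_model(data.frame(
      resno = atom$resno, resname = atom$resid, atom = atom$elety,
      x = co[, 1], y = co[, 2], z = co[, 3], stringsAsFactors = FALSE
    ), label = paste0(path, " model ", m))
  })
  structure(list(sequence_id = sequence_id, models = models), class = "ensemble3d")
}

#' Write an ensemble as a multi-model PDB file
#'
#' Fixed-width ATOM records inside MODEL/ENDMDL blocks (coordinates at the
#' standard 3-decimal PDB precision).
#'
#' @param ensemble An `ensemble3d` (or list with `sequence_id`, `models`).
#' @param path Output path.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated ensemble %s", ensemble$sequence_id), con)
  for (m in seq_along(ensemble$models)) {
    mod <- ensemble$models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(mod))) {
      name <- mod$atom[i]
      # PDB atom-name field (cols 13-16): single-char element names start col 14
      name_f <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else sprintf("%-4s", name)
      writeLines(sprintf("ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         i, name_f, mod$resname[i], mod$resno[i],
                         mod$x[i], mod$y[i], mod$z[i], 1, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Pair atoms of two models by residue index and atom name
#'
#' Pairing is the intersection of (residue number, atom name) keys restricted
#' to `atom_set`; atoms missing on either side are dropped symmetrically.
#' Pairing by residue index (not sequence alignment) keeps variants that
#' differ by a substitution fully comparable on the backbone atom set.
#'
#' @param a,b Model data frames (equal residue counts required).
#' @param atom_set Atom names to use (default backbone trace P, C4', C1').
#' @return List: `X`, `Y` (n x 3 coordinate matrices), `n` (pairing size).
#' @export
match_atoms <- function(a, b, atom_set = DEFAULT_ATOM_SET) {
  if (length(unique(a$resno)) != length(unique(b$resno))) {
    stop("models have different residue counts (",
         length(unique(a$resno)), " vs ", length(unique(b$resno)), ")")
  }
  a2 <- a[a$atom %in% atom_set, , drop = FALSE]
  b2 <- b[b$atom %in% atom_set, , drop = FALSE]
  ka <- paste(a2$resno, a2$atom)
  kb <- paste(b2$resno, b2$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3L) {
    stop("only ", length(common), " paired atoms; need >= 3 for superposition")
  }
  ia <- match(common, ka)
  ib <- match(common, kb)
  ord <- order(a2$resno[ia], match(a2$atom[ia], atom_set))
  list(X = as.matrix(a2[ia[ord], c("x", "y", "z")]),
       Y = as.matrix(b2[ib[ord], c("x", "y", "z")]),
       n = length(common))
}

#' Root-mean-square deviation after optimal (Kabsch) superposition
#'
#' Both point sets are centered; the optimal rotation is obtained from the
#' SVD of the covariance matrix with the determinant correction that excludes
#' reflections, and the RMSD is the root mean squared residual after applying
#' that rotation (residual evaluation avoids the catastrophic cancellation of
#' the closed-form trace expression near zero). Symmetric in its arguments
#' and invariant to rigid motions of either set.
#'
#' @param X,Y n x 3 coordinate matrices with matched rows (n >= 3).
#' @return RMSD in the coordinate units (Angstroms for PDB input).
#' @export
kabsch_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) stop("X and Y must be equal-size n x 3 matrices")
  if (nrow(X) < 3L) stop("need at least 3 paired points")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("coordinates contain non-finite values")
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(sum((Xc %*% R - Yc)^2) / n)
}

#' Pairwise Kabsch RMSD matrix over a set of models
#'
#' @param models Named list of model data frames.
#' @param atom_set Atom names used for pairing.
#' @return Validated symmetric distance matrix (Angstroms).
#' @export
rmsd_matrix <- function(models, atom_set = DEFAULT_ATOM_SET) {
  pairwise_distances(models, metric = function(a, b) {
    p <- match_atoms(a, b, atom_set)
    kabsch_rmsd(p$X, p$Y)
  })
}

#' Per-ensemble RMSD statistics and centroid
#'
#' All model pairs are superimposed once; `avg`/`sd`/`min`/`max` summarize
#' the unordered pairwise RMSDs, and the centroid (member minimizing mean
#' RMSD to the others) is reported with the average and sd of the distances
#' from it to the non-centroid members. A single-model ensemble reports all
#' statistics as 0 with itself as centroid; a two-model ensemble reports its
#' single pairwise RMSD for avg, min, max and avg-to-centroid alike.
#'
#' @param ensemble An `ensemble3d`.
#' @param atom_set Atom names used for pairing.
#' @return One-row data frame: `sequence_id`, `n_models`, `avg_rmsd`, `sd`,
#'   `min_rmsd`, `max_rmsd`, `centroid_id`, `avg_to_centroid`,
#'   `sd_to_centroid`.
#' @export
ensemble_stats <- function(ensemble, atom_set = DEFAULT_ATOM_SET) {
  m <- length(ensemble$models)
  if (m == 0L) stop("ensemble '", ensemble$sequence_id, "' has no models")
  if (m == 1L) {
    return(data.frame(sequence_id = ensemble$sequence_id, n_models = 1L,
                      avg_rmsd = 0, sd = 0, min_rmsd = 0, max_rmsd = 0,
                      centroid_id = "1", avg_to_centroid = 0, sd_to_centroid = 0,
                      stringsAsFactors = FALSE))
  }
  models <- ensemble$models
  names(models) <- as.character(seq_len(m))
  D <- rmsd_matrix(models, atom_set)
  vals <- D[upper.tri(D)]
  s <- stats::sd(vals)
  cen <- dist_centroid(D, rownames(D))
  data.frame(sequence_id = ensemble$sequence_id, n_models = m,
             avg_rmsd = mean(vals), sd = if (is.na(s)) 0 else s,
             min_rmsd = min(vals), max_rmsd = max(vals),
             centroid_id = cen$centroid_id, avg_to_centroid = cen$avg,
             sd_to_centroid = cen$sd, stringsAsFactors = FALSE)
}

#' Extract the centroid model of an ensemble
#'
#' @param ensemble An `ensemble3d`.
#' @param atom_set Atom names used for pairing.
#' @return The centroid model data frame.
#' @export
ensemble_centroid_model <- function(ensemble, atom_set = DEFAULT_ATOM_SET) {
  st <- ensemble_stats(ensemble, atom_set)
  ensemble$models[[as.integer(st$centroid_id)]]
}

#' Cluster ensemble centroids across sequences
#'
#' Computes the Kabsch RMSD matrix over one representative (centroid) model
#' per sequence, clusters it by single linkage, and reports per-cluster RMSD
#' statistics with the cluster centroid and the mean distance to it.
#'
#' @param centroids Named list of model data frames (one per sequence).
#' @param cut Passed to [cluster_single_linkage()] (default "largest-gap").
#' @param atom_set Atom names used for pairing.
#' @return List: `clusters` (a `cluster_result`), `stats` (data frame with
#'   columns `cluster`, `n_members`, `members`, `avg_rmsd`, `sd`, `min_rmsd`,
#'   `max_rmsd`, `centroid_id`, `avg_to_centroid`, `sd_to_centroid`), `dist`
#'   (the centroid RMSD matrix).
#' @export
cross_ensemble_cluster <- function(centroids, cut = "largest-gap",
                                   atom_set = DEFAULT_ATOM_SET) {
  if (length(centroids) < 2L) stop("need at least 2 centroids to compare")
  D <- rmsd_matrix(centroids, atom_set)
  cl <- cluster_single_linkage(D, cut)
  rows <- lapply(seq_along(cl$members), function(k) {
    ids <- cl$members[[k]]
    if (length(ids) == 1L) {
      return(data.frame(cluster = k, n_members = 1L, members = ids,
                        avg_rmsd = 0, sd = 0, min_rmsd = 0, max_rmsd = 0,
                        centroid_id = ids, avg_to_centroid = 0,
                        sd_to_centroid = 0, stringsAsFactors = FALSE))
    }
    sub <- D[ids, ids]
    vals <- sub[upper.tri(sub)]
    s <- stats::sd(vals)
    cen <- dist_centroid(D, ids)
    data.frame(cluster = k, n_members = length(ids),
               members = paste(ids, collapse = ","),
               avg_rmsd = mean(vals), sd = if (is.na(s)) 0 else s,
               min_rmsd = min(vals), max_rmsd = max(vals),
               centroid_id = cen$centroid_id, avg_to_centroid = cen$avg,
               sd_to_centroid = cen$sd, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  list(clusters = cl, stats = stats, dist = D)
}
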