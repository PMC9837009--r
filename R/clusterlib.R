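# Shared distance/clustering substrate for the 2D (Levenshtein + DBSCAN) and
# 3D (RMSD + single linkage) arms.

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertions, deletions, substitutions),
#' computed via `utils::adist`.
#'
#' @param a,b Character scalars (empty strings allowed).
#' @return Non-negative integer.
#' @examples
#' levenshtein("GGAG", "GCAG")  # 1
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Validate a labelled distance matrix
#'
#' Checks: square, labelled, zero diagonal, exact symmetry, all values finite
#' and non-negative.
#' @param D Numeric matrix with identical row/column dimnames.
#' @return `D`, invisibly (errors otherwise).
#' @export
validate_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix must carry identical row and column labels")
  }
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and non-negative")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (!identical(D, t(D))) stop("distance matrix must be exactly symmetric")
  invisible(D)
}

#' Pairwise distance matrix over labelled items
#'
#' Evaluates the metric once per unordered pair and mirrors the result. The
#' default metric is the Levenshtein distance over strings.
#'
#' @param items Named character vector (or named list) of items.
#' @param metric Function of two items returning a finite non-negative scalar.
#' @return Symmetric numeric matrix with the item names as labels.
#' @export
pairwise_distances <- function(items, metric = levenshtein) {
  if (length(items) < 1L) stop("need at least one item")
  labels <- names(items)
  if (is.null(labels)) labels <- as.character(seq_along(items))
  n <- length(items)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- metric(items[[i]], items[[j]])
        if (!is.finite(d) || d < 0) {
          stop("metric returned ", d, " for pair (", labels[i], ", ", labels[j], ")")
        }
        D[i, j] <- D[j, i] <- as.numeric(d)
      }
    }
  }
  validate_dist_matrix(D)
  D
}

cluster_result <- function(assignments, labels) {
  # renumber clusters 1..k, ordered by first (input-order) member; NA = noise
  ids <- unique(assignments[!is.na(assignments)])
  remap <- stats::setNames(seq_along(ids), ids)
  clean <- ifelse(is.na(assignments), NA_integer_,
                  remap[as.character(assignments)])
  names(clean) <- labels
  members <- split(labels[!is.na(clean)], clean[!is.na(clean)])
  structure(list(assignments = clean, n_clusters = length(members),
                 members = members), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(x$n_clusters, "cluster(s)")
  noise <- sum(is.na(x$assignments))
  if (noise > 0) cat(",", noise, "noise point(s)")
  cat("\n")
  for (k in seq_along(x$members)) {
    cat(sprintf("  %s: {%s}\n", names(x$members)[k], paste(x$members[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' DBSCAN over a precomputed distance matrix
#'
#' Standard density clustering: a point is core when it has at least
#' `min_samples` neighbours within `eps` (itself included; neighbourhood is
#' `d <= eps`). Clusters are the connected components of core points under
#' the eps-neighbour relation, plus border points attached to the
#' first-labelled neighbouring core point. Remaining points are noise
#' (assignment `NA`), excluded from `n_clusters` unless
#' `noise_as_singletons = TRUE` converts each into its own cluster.
#'
#' @param D Validated distance matrix.
#' @param eps Neighbourhood radius (> 0).
#' @param min_samples Core-point threshold (>= 1).
#' @param noise_as_singletons Convert noise points to singleton clusters.
#' @return A `cluster_result`: `assignments` (named integer vector, NA =
#'   noise), `n_clusters`, `members`.
#' @export
cluster_dbscan <- function(D, eps, min_samples = 2L, noise_as_singletons = FALSE) {
  validate_dist_matrix(D)
  stopifnot(eps > 0, min_samples >= 1)
  n <- nrow(D)
  labels <- rownames(D)
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples
  assign <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(assign[i])) next
    cl <- cl + 1L
    frontier <- i
    assign[i] <- cl
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (p in frontier) {
        for (q in which(nb[p, ])) {
          if (is.na(assign[q])) {
            assign[q] <- cl
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  if (noise_as_singletons) {
    for (i in which(is.na(assign))) {
      cl <- cl + 1L
      assign[i] <- cl
    }
  }
  cluster_result(assign, labels)
}

#' Single-linkage agglomerative clustering with automatic or fixed cut
#'
#' Merges by minimum inter-cluster distance (via `stats::hclust`). The tree
#' is cut either at an explicit height `cut` (clusters are groups merged at
#' height <= cut) or, with `cut = "largest-gap"`, in the middle of the
#' largest gap between consecutive sorted merge heights. The gap only counts
#' as a cut when it exceeds the merge height at its lower edge — a gap no
#' larger than the scale of the merges below it is indistinguishable from
#' sampling noise, so near-uniform height profiles (including all-equal
#' heights, which have no gap at all) yield a single cluster. Ties in the
#' largest gap resolve towards fewer clusters (the highest such gap).
#'
#' @param D Validated distance matrix (>= 1 item; a single item is its own
#'   cluster).
#' @param cut Numeric threshold or the string `"largest-gap"` (default).
#' @return A `cluster_result` (no noise; every item assigned).
#' @export
cluster_single_linkage <- function(D, cut = "largest-gap") {
  validate_dist_matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (n == 1L) return(cluster_result(1L, labels))
  tree <- stats::hclust(stats::as.dist(D), method = "single")
  if (identical(cut, "largest-gap")) {
    h <- sort(tree$height)
    if (length(h) < 2L || max(h) - min(h) < .Machine$double.eps^0.5) {
      return(cluster_result(rep(1L, n), labels))
    }
    gaps <- diff(h)
    k <- max(which(gaps == max(gaps)))
    if (gaps[k] <= h[k]) {
      return(cluster_result(rep(1L, n), labels))
    }
    cut <- (h[k] + h[k + 1L]) / 2
  }
  assign <- stats::cutree(tree, h = cut)
  cluster_result(as.integer(assign), labels)
}

#' Centroid of a member set under a distance matrix
#'
#' The centroid is the member minimizing the mean distance to the other
#' members (ties resolve to the earlier label in `members` order). The
#' average and standard deviation are computed over the distances from the
#' centroid to the non-centroid members only — so a two-member set reports
#' exactly its single pairwise distance with sd 0, matching the reporting
#' convention used for two-model ensembles.
#'
#' @param D Validated distance matrix.
#' @param members Character vector of labels (non-empty, all present in `D`).
#' @return List: `centroid_id`, `avg` (mean distance to centroid), `sd`.
#' @export
dist_centroid <- function(D, members) {
  validate_dist_matrix(D)
  if (length(members) == 0L) stop("members must be non-empty")
  unknown <- setdiff(members, rownames(D))
  if (length(unknown) > 0L) stop("unknown member id(s): ", paste(unknown, collapse = ", "))
  if (length(members) == 1L) {
    return(list(centroid_id = members, avg = 0, sd = 0))
  }
  sub <- D[members, members, drop = FALSE]
  mean_to_others <- rowSums(sub) / (length(members) - 1L)
  c_idx <- which.min(mean_to_others)  # first minimum = earlier label
  to_centroid <- sub[c_idx, -c_idx]
  s <- stats::sd(to_centroid)
  list(centroid_id = members[c_idx], avg = mean(to_centroid),
       sd = if (is.na(s)) 0 else s)
}

#' Write a distance matrix as TSV (label header row and column)
#' @param D Validated distance matrix.
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @export
write_dist_matrix <- function(D, path, header = character()) {
  validate_dist_matrix(D)
  df <- data.frame(id = rownames(D), D, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' Read a distance matrix written by [write_dist_matrix()]
#' @param path TSV path.
#' @return Validated distance matrix.
#' @export
read_dist_matrix <- function(path) {
  df <- read_tsv_body(path)
  labels <- as.character(df[[1]])
  D <- as.matrix(df[, -1, drop = FALSE])
  dimnames(D) <- list(labels, labels)
  validate_dist_matrix(D)
  D
}

#' Write cluster assignments as TSV (item, cluster; noise written as "noise")
#' @param result A `cluster_result`.
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @export
write_assignments <- function(result, path, header = character()) {
  df <- data.frame(item = names(result$assignments),
                   cluster = ifelse(is.na(result$assignments), "noise",
                                    result$assignments),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}
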