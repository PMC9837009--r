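# Independent brute-force oracles used to pin expected values.
# Each deliberately uses different machinery than the implementation it checks.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# expand an IUPAC pattern into every concrete string, then test each
# substring by set membership
oracle_iupac_starts <- function(sequence, pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  concrete <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste,
                    collapse = "")
  k <- nchar(pattern)
  n <- nchar(sequence)
  if (k > n) return(integer())
  starts <- integer()
  for (i in seq_len(n - k + 1L)) {
    if (substr(sequence, i, i + k - 1L) %in% concrete) starts <- c(starts, i)
  }
  starts
}

# memoized recursive edit distance (top-down; the implementation is bottom-up)
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (av[i] == bv[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# maximum pair count over all nested structures, by exhaustive recursion on
# the 3' base (no memoization, no traceback) - feasible for n <= 12
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  s <- strsplit(sequence, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in seq.int(i, j - min_loop - 1L)) {
      if (paste0(s[k], s[j]) %in% ORACLE_PAIRS) {
        left <- if (k - 1L >= i) rec(i, k - 1L) else 0L
        best <- max(best, 1L + left + rec(k + 1L, j - 1L))
      }
    }
    best
  }
  rec(1L, length(s))
}

# connected components of the graph with edges d <= t (BFS over labels)
oracle_components <- function(D, t) {
  labels <- rownames(D)
  n <- length(labels)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      nbr <- which(D[p, ] <= t & is.na(comp))
      comp[nbr] <- k
      queue <- c(queue, nbr)
    }
  }
  stats::setNames(comp, labels)
}

# same partition up to relabelling
same_partition <- function(a, b) {
  stopifnot(identical(sort(names(a)), sort(names(b))))
  b <- b[names(a)]
  key_a <- as.integer(factor(a, levels = unique(a)))
  key_b <- as.integer(factor(b, levels = unique(b)))
  identical(key_a, key_b)
}

rotation_from_axis_angle <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimum RMSD over a grid of rotations (Fibonacci-sphere axes x angle grid)
oracle_grid_rmsd <- function(X, Y, n_axes = 150L, n_angles = 72L) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  golden <- pi * (3 - sqrt(5))
  best <- Inf
  for (a in seq_len(n_axes)) {
    z <- 1 - 2 * (a - 0.5) / n_axes
    r <- sqrt(max(0, 1 - z^2))
    phi <- golden * (a - 1)
    axis <- c(r * cos(phi), r * sin(phi), z)
    for (t in seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]) {
      R <- rotation_from_axis_angle(axis, t)
      v <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
      if (v < best) best <- v
    }
  }
  best
}

# small backbone-style model for 3D tests
toy_model <- function(n_residues = 6L, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- helix_backbone(n_residues)
  if (jitter > 0) {
    m$x <- m$x + stats::rnorm(nrow(m), sd = jitter)
    m$y <- m$y + stats::rnorm(nrow(m), sd = jitter)
    m$z <- m$z + stats::rnorm(nrow(m), sd = jitter)
  }
  m
}

# apply a rigid motion to a model data frame
transform_model <- function(m, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
  m$x <- xyz[, 1] + shift[1]
  m$y <- xyz[, 2] + shift[2]
  m$z <- xyz[, 3] + shift[3]
  m
}

random_dist_matrix <- function(n, scale = 10) {
  P <- matrix(stats::runif(n * 3, 0, scale), ncol = 3)
  D <- as.matrix(stats::dist(P))
  dimnames(D) <- list(letters[seq_len(n)], letters[seq_len(n)])
  D
}
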