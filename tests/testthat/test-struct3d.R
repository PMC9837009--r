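test_that("multi-model PDB files round-trip at the 3-decimal PDB precision", {
  gen <- make_structure_ensembles(ids = c("0", "1"), divergent_ids = character(),
                                  n_models_background = 2L, n_residues = 19L,
                                  seed = 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ens_0.pdb")
  write_pdb_ensemble(gen$ensembles[["0"]], path)
  back <- read_pdb_ensemble(path, "0")
  expect_length(back$models, 2L)
  expect_equal(nrow(back$models[[1]]), 19L * 3L)
  for (m in 1:2) {
    a <- gen$ensembles[["0"]]$models[[m]]
    b <- back$models[[m]]
    expect_equal(b$resno, a$resno)
    expect_equal(b$atom, a$atom)
    expect_lt(max(abs(b$x - a$x), abs(b$y - a$y), abs(b$z - a$z)), 5e-4 + 1e-9)
  }
})

test_that("PDB dialect tolerance: no MODEL records, HETATM skipped", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "single.pdb")
  atom_line <- function(serial, name, resname, resno, x, y, z, rec = "ATOM  ") {
    sprintf("%s%5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            rec, serial, name, resname, resno, x, y, z, 1, 0)
  }
  writeLines(c(
    atom_line(1, "P", "G", 1, 1, 2, 3),
    atom_line(2, "C4'", "G", 1, 2, 2, 3),
    atom_line(3, "C1'", "G", 1, 3, 2, 3),
    atom_line(4, "O", "HOH", 99, 9, 9, 9, rec = "HETATM"),
    "END"
  ), path)
  e <- read_pdb_ensemble(path)
  expect_length(e$models, 1L)
  expect_equal(nrow(e$models[[1]]), 3L)
  expect_equal(e$models[[1]]$atom, c("P", "C4'", "C1'"))
  expect_equal(e$sequence_id, "single")
})

test_that("atom pairing intersects (residue, atom) keys symmetrically", {
  a <- toy_model(6)
  p <- match_atoms(a, a)
  expect_equal(p$n, 18L)
  expect_equal(p$X, p$Y)

  # base-identity differences are invisible to the backbone atom set
  b <- a
  b$resname <- rev(b$resname)
  expect_equal(match_atoms(a, b)$n, 18L)

  # random atom deletions: pairing equals the key intersection
  set.seed(19)
  for (rep in 1:8) {
    da <- a[-sample(nrow(a), 3), ]
    db <- a[-sample(nrow(a), 3), ]
    p <- match_atoms(da, db)
    expect_equal(p$n, length(intersect(paste(da$resno, da$atom),
                                       paste(db$resno, db$atom))))
  }

  tiny <- a[a$resno <= 2 & a$atom == "P", ]
  expect_error(match_atoms(tiny, tiny), "need >= 3")
})

test_that("superposition RMSD is rigid-motion invariant and excludes reflections", {
  set.seed(43)
  X <- matrix(stats::rnorm(30), ncol = 3)
  for (rep in 1:5) {
    R <- random_rotation()
    shift <- stats::rnorm(3, sd = 5)
    Y <- X %*% R + matrix(shift, nrow(X), 3, byrow = TRUE)
    expect_lt(kabsch_rmsd(X, Y), 1e-9)
  }

  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  rot90 <- rotation_from_axis_angle(c(0, 0, 1), pi / 2)
  expect_lt(kabsch_rmsd(tri, tri %*% rot90), 1e-12)

  # mirror image of a chiral set stays distant (determinant correction)
  chiral <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1, 0, 0.4, 0.3, 1.7), ncol = 3, byrow = TRUE)
  expect_gt(kabsch_rmsd(chiral, chiral %*% diag(c(-1, 1, 1))), 0.1)

  Y2 <- X + matrix(stats::rnorm(30, sd = 0.4), ncol = 3)
  expect_equal(kabsch_rmsd(X, Y2), kabsch_rmsd(Y2, X), tolerance = 1e-12)
  bad <- X; bad[1, 1] <- NaN
  expect_error(kabsch_rmsd(bad, Y2), "non-finite")
})

test_that("superposition attains the rotation-grid optimum", {
  set.seed(47)
  for (rep in 1:2) {
    X <- matrix(stats::rnorm(30), ncol = 3)
    Y <- X %*% random_rotation() + matrix(stats::rnorm(30, sd = 0.3), ncol = 3)
    exact <- kabsch_rmsd(X, Y)
    grid <- oracle_grid_rmsd(X, Y)
    expect_lte(exact, grid + 1e-12)   # Kabsch is optimal
    expect_lt(grid - exact, 0.08)     # and the grid comes close
  }
})

test_that("RMSD on fixed correspondences behaves like a metric", {
  set.seed(53)
  for (rep in 1:10) {
    X <- matrix(stats::rnorm(24), ncol = 3)
    Y <- matrix(stats::rnorm(24), ncol = 3)
    Z <- matrix(stats::rnorm(24), ncol = 3)
    expect_lte(kabsch_rmsd(X, Z),
               kabsch_rmsd(X, Y) + kabsch_rmsd(Y, Z) + 1e-9)
  }
})

test_that("ensemble statistics follow the reporting conventions", {
  a <- toy_model(19)
  set.seed(59)
  b <- a
  b$x <- b$x + stats::rnorm(nrow(b), sd = 1)
  ens <- structure(list(sequence_id = "e", models = list(a, b)),
                   class = "ensemble3d")
  st <- ensemble_stats(ens)
  r <- kabsch_rmsd(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
  expect_equal(st$avg_rmsd, r)
  expect_equal(st$min_rmsd, r)
  expect_equal(st$max_rmsd, r)
  expect_equal(st$avg_to_centroid, r)
  expect_equal(st$sd, 0)

  ident <- structure(list(sequence_id = "i", models = list(a, a, a)),
                     class = "ensemble3d")
  sti <- ensemble_stats(ident)
  expect_equal(sti$avg_rmsd, 0)
  expect_equal(sti$max_rmsd, 0)

  solo <- structure(list(sequence_id = "s", models = list(a)), class = "ensemble3d")
  sts <- ensemble_stats(solo)
  expect_equal(sts[, c("avg_rmsd", "sd", "min_rmsd", "max_rmsd",
                       "avg_to_centroid")],
               data.frame(avg_rmsd = 0, sd = 0, min_rmsd = 0, max_rmsd = 0,
                          avg_to_centroid = 0))
})

test_that("ensemble statistics equal direct recomputation and ignore model order", {
  gen <- make_structure_ensembles(ids = "x", divergent_ids = character(),
                                  n_models_background = 5L, seed = 61)
  ens <- gen$ensembles[["x"]]
  st <- ensemble_stats(ens)
  # independent recomputation from a directly assembled matrix
  coords <- lapply(ens$models, function(m) as.matrix(m[, c("x", "y", "z")]))
  vals <- c()
  M <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    r <- kabsch_rmsd(coords[[i]], coords[[j]])
    M[i, j] <- M[j, i] <- r
    vals <- c(vals, r)
  }
  expect_equal(st$avg_rmsd, mean(vals))
  expect_equal(st$sd, stats::sd(vals))
  expect_equal(st$min_rmsd, min(vals))
  expect_equal(st$max_rmsd, max(vals))
  cen_means <- rowSums(M) / 4
  expect_equal(as.integer(st$centroid_id), which.min(cen_means))

  perm <- sample(5)
  ens_p <- structure(list(sequence_id = "x", models = ens$models[perm]),
                     class = "ensemble3d")
  st_p <- ensemble_stats(ens_p)
  expect_equal(st_p[, c("avg_rmsd", "sd", "min_rmsd", "max_rmsd",
                        "avg_to_centroid", "sd_to_centroid")],
               st[, c("avg_rmsd", "sd", "min_rmsd", "max_rmsd",
                      "avg_to_centroid", "sd_to_centroid")])
  # same centroid structure, whatever its index after permutation
  expect_equal(ens_p$models[[as.integer(st_p$centroid_id)]],
               ens$models[[as.integer(st$centroid_id)]])
})

test_that("cross-ensemble clustering recovers planted partitions", {
  gen <- make_structure_ensembles(seed = 5)
  cents <- lapply(gen$ensembles, ensemble_centroid_model)
  cc <- cross_ensemble_cluster(cents)
  expect_equal(cc$clusters$n_clusters, 2L)
  sizes <- sort(lengths(cc$clusters$members))
  expect_equal(unname(sizes), c(2L, 11L))
  small <- cc$clusters$members[[which.min(lengths(cc$clusters$members))]]
  expect_setequal(small, c("6", "7"))
  expect_equal(sort(cc$stats$n_members), c(2L, 11L))

  # two centroids: threshold decides between one pair and two singletons
  two <- cents[c("0", "6")]
  d <- cc$dist["0", "6"]
  expect_equal(cross_ensemble_cluster(two, cut = d * 1.01)$clusters$n_clusters, 1L)
  expect_equal(cross_ensemble_cluster(two, cut = d * 0.5)$clusters$n_clusters, 2L)

  # planted 3-group recovery when scales separate
  set.seed(67)
  ok <- 0L
  for (s in 1:10) {
    g <- make_structure_ensembles(
      ids = as.character(1:9), divergent_ids = as.character(7:9),
      n_models_background = 2L, n_models_divergent = 2L,
      sigma = 0.05, delta = 4, seed = 100 + s
    )
    # second divergent group: shift a different window by hand
    for (id in as.character(4:6)) {
      g$ensembles[[id]]$models <- lapply(g$ensembles[[id]]$models, function(m) {
        sel <- m$resno %in% 1:4
        m$y[sel] <- m$y[sel] + 4
        m
      })
    }
    cen <- lapply(g$ensembles, ensemble_centroid_model)
    part <- cross_ensemble_cluster(cen)$clusters$assignments
    truth <- stats::setNames(rep(c(1, 2, 3), each = 3), as.character(1:9))
    if (same_partition(part, truth)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
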