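test_that("structure construction enforces the secondary-structure invariants", {
  expect_error(secondary_structure("x", "GGGAAACCC", "(((...))"), "length")
  unbal <- paste0(strrep("(", 4), "...", "()")
  expect_error(secondary_structure("x", "GGGAAACCC", unbal), "unbalanced")
  expect_error(secondary_structure("x", "GGGAACCCC", "((((.))))"), "shorter than 3")
  expect_error(secondary_structure("x", "GGGAAAGGG", "(((...)))"), "disallowed base pair GG")
  s <- secondary_structure("x", "GGGAAACCC", "(((...)))")
  expect_equal(nrow(s$pairs), 3L)
  expect_equal(s$pairs[, "i"], c(1L, 2L, 3L))
  expect_equal(s$pairs[, "j"], c(9L, 8L, 7L))
})

test_that("base-pair maximization reproduces hand-checkable folds", {
  expect_equal(fold_maxpair(normalize_sequence("GGGAAACCC", "x"))$dot_bracket,
               "(((...)))")
  expect_equal(fold_maxpair(normalize_sequence("AAAAAA", "x"))$dot_bracket,
               "......")
})

test_that("base-pair maximization attains the exhaustive optimum for n <= 12", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    raw <- random_rna(n)
    s <- fold_maxpair(normalize_sequence(raw, "r"))
    expect_equal(nrow(s$pairs), oracle_max_pairs(raw), info = raw)
  }
})

test_that("pair count grows weakly under complementary flank extension", {
  set.seed(9)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (rep in 1:10) {
    raw <- random_rna(sample(6:12, 1))
    base <- nrow(fold_maxpair(normalize_sequence(raw, "r"))$pairs)
    chars <- strsplit(raw, "")[[1]]
    ext <- paste0("G", raw, "C")
    extended <- nrow(fold_maxpair(normalize_sequence(ext, "r"))$pairs)
    expect_gte(extended, base)
  }
})

test_that("the energy model orders designed hairpins and never goes positive", {
  params <- default_energy_params()
  expect_true(all(params$stack <= 0))
  expect_true(all(params$hairpin >= 0))

  # GC-clamped 6-bp hairpin: strong helix, clearly below zero
  hp6 <- normalize_sequence("GGCGGCAAAAGCCGCC", "hp6")
  s6 <- fold_mfe_hairpin(hp6, params)
  expect_lt(s6$energy, 0)
  expect_equal(nrow(s6$pairs), 6L)
  # hand-summed energy of the returned helix from the packaged table
  ptypes <- paste0(strsplit(as.character(hp6), "")[[1]][s6$pairs[, "i"]],
                   strsplit(as.character(hp6), "")[[1]][s6$pairs[, "j"]])
  expected <- sum(params$stack[cbind(ptypes[-length(ptypes)], ptypes[-1])]) +
    params$hairpin[["4"]] +
    ifelse(ptypes[1] %in% c("AU", "UA", "GU", "UG"), params$terminal_au, 0)
  expect_equal(s6$energy, unname(expected))

  # a 2-bp version of the same clamp cannot pay the loop penalty
  hp2 <- normalize_sequence("GCAAAAGC", "hp2")
  s2 <- fold_mfe_hairpin(hp2, params)
  expect_equal(s2$energy, 0)
  expect_equal(s2$dot_bracket, strrep(".", 8))
  expect_lt(s6$energy, s2$energy)

  set.seed(21)
  for (rep in 1:15) {
    s <- fold_mfe_hairpin(normalize_sequence(random_rna(sample(8:22, 1)), "r"))
    expect_lte(s$energy, 0)
    if (s$energy == 0) expect_equal(nrow(s$pairs), 0L)
  }
})

test_that("the minimum-energy hairpin matches brute force over all helix triples", {
  params <- default_energy_params()
  brute <- function(raw) {
    s <- strsplit(raw, "")[[1]]
    n <- length(s)
    best <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i + 3) next
      for (h in seq_len((j - i + 1 - 3) %/% 2)) {
        e <- exovar:::single_hairpin_energy(s, i, j, h, params)
        if (!is.na(e) && e < best) best <- e
      }
    }
    best
  }
  set.seed(13)
  for (rep in 1:10) {
    raw <- random_rna(sample(10:25, 1))
    expect_equal(fold_mfe_hairpin(normalize_sequence(raw, "r"), params)$energy,
                 brute(raw), info = raw)
  }
})

test_that("Vienna files round-trip and parse trailing energies", {
  set.seed(2)
  structs <- make_dotbracket_set(seed = 4)
  expect_length(structs, 13L)
  path <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(structs, path)
  back <- read_vienna(path)
  expect_equal(names(back), names(structs))
  for (id in names(structs)) {
    expect_equal(back[[id]]$dot_bracket, structs[[id]]$dot_bracket)
    expect_equal(back[[id]]$sequence, structs[[id]]$sequence)
  }

  path2 <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">v7", "GGGGGGAAAACCCCCCAAA", "((((((....))))))... (-1.37)"), path2)
  v <- read_vienna(path2)
  expect_equal(v[["v7"]]$energy, -1.37)

  path3 <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">bad", "GGGAAACCC", "(((...))"), path3)
  expect_error(read_vienna(path3), "bad")
})

test_that("hairpin features recover the published loop/stem geometry", {
  # 3-bp stem with a 9-nt loop closed at (5, 15): window 12-15 sits in the loop
  s <- secondary_structure("6", "AAGGGAAAAAAAAACCCAA", "..(((.........)))..")
  f <- extract_hairpin_features(s, mir1246_window())
  expect_equal(f$loop_length, 9L)
  expect_equal(f$stem_length, 3L)
  expect_equal(f$motif_location, "loop")
  expect_equal(f$n_hairpins, 1L)

  # helix spanning 12-17: window fully paired -> stem
  s7 <- secondary_structure("7", "AGGGGGGAAAACCCCCCAA", ".((((((....)))))).." )
  f7 <- extract_hairpin_features(s7, mir1246_window())
  expect_equal(f7$motif_location, "stem")
  expect_equal(f7$loop_length, 4L)
  expect_equal(f7$stem_length, 6L)

  dots <- secondary_structure("u", strrep("A", 19), strrep(".", 19))
  fu <- extract_hairpin_features(dots, mir1246_window())
  expect_equal(fu, list(n_hairpins = 0L, stem_length = 0L, loop_length = 0L,
                        motif_location = "unpaired"))
})

test_that("hairpin readouts agree with an independent pair-list walk", {
  # oracle: recompute stem and loop of the hairpin containing the innermost
  # pair directly from the pair list
  oracle_features <- function(s) {
    p <- s$pairs
    if (nrow(p) == 0L) return(NULL)
    inner <- p[!vapply(seq_len(nrow(p)), function(k) {
      any(p[, "i"] > p[k, "i"] & p[, "j"] < p[k, "j"])
    }, TRUE), , drop = FALSE]
    res <- lapply(seq_len(nrow(inner)), function(k) {
      i <- inner[k, "i"]; j <- inner[k, "j"]
      stem <- 0L
      repeat {
        if (any(p[, "i"] == i - stem & p[, "j"] == j + stem)) stem <- stem + 1L
        else break
      }
      list(loop = j - i - 1L, stem = stem)
    })
    res
  }
  set.seed(31)
  checked <- 0L
  while (checked < 10L) {
    s <- fold_maxpair(normalize_sequence(random_rna(sample(12:26, 1)), "r"))
    orc <- oracle_features(s)
    if (is.null(orc)) next
    checked <- checked + 1L
    f <- extract_hairpin_features(s, motif_window(1, 2, substr(s$sequence, 1, 2)))
    expect_equal(f$n_hairpins, length(orc))
    # the selected hairpin's readouts must match one oracle hairpin with the
    # maximal stem
    stems <- vapply(orc, function(o) o$stem, 1L)
    expect_equal(f$stem_length, max(stems))
    loops <- vapply(orc[stems == max(stems)], function(o) o$loop, 1L)
    expect_true(f$loop_length %in% loops)
  }
})
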