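write_motif_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

attract_fixture <- function() {
  data.frame(
    Gene_name = c("HNRNPA2B1", "SRSF1", "ELAVL1"),
    Gene_id = c("G1", "G2", "G3"),
    Organism = c("Homo_sapiens", "Homo_sapiens", "Mus_musculus"),
    Motif = c("GGAG", "TTAG", "GCAG"),
    Len = c(4L, 4L, 4L),
    Matrix_id = c("M001", "M002", "M003"),
    Score = c(0.9, 0.8, 0.7),
    stringsAsFactors = FALSE
  )
}

test_that("motif tables parse the ATtRACT dialect with normalization and filters", {
  path <- write_motif_fixture(attract_fixture())
  tab <- read_motif_table(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$pattern[tab$motif_id == "M002"], "UUAG")  # T -> U
  expect_equal(tab$gene_name[1], "HNRNPA2B1")

  human <- read_motif_table(path, organism = "Homo_sapiens")
  raw <- attract_fixture()
  expect_equal(nrow(human), sum(raw$Organism == "Homo_sapiens"))
  expect_setequal(human$gene_id, raw$Gene_id[raw$Organism == "Homo_sapiens"])

  bad <- attract_fixture()
  bad$Motif[2] <- "GXAG"
  path2 <- write_motif_fixture(bad)
  expect_warning(tab2 <- read_motif_table(path2), "invalid IUPAC")
  expect_equal(nrow(tab2), 2L)

  broken <- attract_fixture()
  broken$Motif <- NULL
  path3 <- write_motif_fixture(broken)
  expect_error(read_motif_table(path3), "pattern")
})

test_that("scanning finds the overlapping EXO-motifs of the native miR-1246", {
  motifs <- data.frame(motif_id = c("m1", "m2"), pattern = c("GGAG", "GCAG"),
                       gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  hits <- scan_motifs(mir1246_sequence(), motifs)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(12L, 15L))
  expect_equal(hits$end, c(15L, 18L))
  expect_equal(hits$matched, c("GGAG", "GCAG"))
  # the two motifs overlap at position 15
  expect_true(hits$end[1] == hits$start[2])
  expect_equal(nrow(scan_motifs(mir1246_sequence(), motifs[0, ])), 0L)
})

test_that("IUPAC scanning agrees with the exhaustive substring oracle", {
  m <- data.frame(motif_id = "m", pattern = "GSAG", gene_id = "g")
  hits <- scan_motifs(mir1246_sequence(), m)
  expect_equal(hits$start, oracle_iupac_starts("AAUGGAUUUUUGGAGCAGG", "GSAG"))

  set.seed(11)
  pats <- c("GGAG", "RYAG", "NNAG", "SWK", "AUHG", "GN", "UUUU")
  for (rep in 1:20) {
    s <- normalize_sequence(random_rna(sample(10:30, 1)), "r")
    p <- sample(pats, 1)
    got <- scan_motifs(s, data.frame(motif_id = "m", pattern = p, gene_id = "g"))
    expect_equal(got$start, oracle_iupac_starts(as.character(s), p),
                 info = paste(s, p))
  }
})

test_that("hits away from a substituted position are unchanged between variants", {
  set.seed(7)
  motifs <- data.frame(motif_id = paste0("m", 1:4),
                       pattern = c("GGAG", "UUU", "RAG", "AU"),
                       gene_id = paste0("g", 1:4), stringsAsFactors = FALSE)
  native <- mir1246_sequence()
  v <- enumerate_motif_variants(native, mir1246_window())
  for (i in sample(nrow(v), 4)) {
    p <- v$position[i]
    h0 <- scan_motifs(native, motifs)
    h1 <- scan_motifs(normalize_sequence(v$sequence[i], "0"), motifs)
    off0 <- h0[h0$end < p | h0$start > p, ]
    off1 <- h1[h1$end < p | h1$start > p, ]
    rownames(off0) <- rownames(off1) <- NULL
    expect_equal(off0, off1)
  }
})

test_that("summaries collapse homolog groups and tolerate missing annotation", {
  hits <- data.frame(
    sequence_id = "s", motif_id = paste0("m", 1:4),
    gene_id = c("g1", "g1", "g2", "g3"),
    start = 1:4, end = 4:7, matched = "GGAG", stringsAsFactors = FALSE
  )
  ann <- data.frame(gene_id = c("g1", "g2"), homolog_group_id = c("H1", "H1"))
  expect_message(sm <- summarize_hits(hits, ann, "s"), "singleton")
  expect_equal(sm$n_motif_hits, 4L)
  expect_equal(sm$n_distinct_rbps, 2L)  # H1 + singleton g3
  expect_equal(sm$gene_ids, "g1,g2,g3")

  # same-group collapse: 4 hits from 2 genes in one group -> 1 RBP
  ann2 <- data.frame(gene_id = c("g1", "g2", "g3"),
                     homolog_group_id = c("H1", "H1", "H1"))
  sm2 <- summarize_hits(hits, ann2, "s")
  expect_equal(c(sm2$n_motif_hits, sm2$n_distinct_rbps), c(4L, 1L))

  empty <- summarize_hits(hits[0, ], ann2, "s")
  expect_equal(c(empty$n_motif_hits, empty$n_distinct_rbps), c(0L, 0L))
  expect_equal(empty$gene_ids, "")

  # permutation invariance
  perm <- hits[sample(nrow(hits)), ]
  expect_equal(summarize_hits(perm, ann2, "s"), sm2)
})

test_that("ranking is total, stable and matches a brute-force comparison sort", {
  sm <- data.frame(sequence_id = c("A", "B", "C"),
                   n_motif_hits = c(25L, 16L, 2L),
                   n_distinct_rbps = c(15L, 12L, 1L), stringsAsFactors = FALSE)
  expect_equal(rank_sequences(sm)$sequence_id, c("A", "B", "C"))

  tied <- data.frame(sequence_id = c("3", "1", "2"),
                     n_motif_hits = 5L, n_distinct_rbps = 2L)
  expect_equal(rank_sequences(tied)$sequence_id, c("1", "2", "3"))

  set.seed(3)
  rand <- data.frame(sequence_id = as.character(sample(20)),
                     n_motif_hits = sample(0:5, 20, TRUE),
                     n_distinct_rbps = sample(0:3, 20, TRUE))
  got <- rank_sequences(rand)$sequence_id
  # selection-sort oracle with the declared comparison key
  before <- function(a, b) {
    if (a$n_motif_hits != b$n_motif_hits) return(a$n_motif_hits > b$n_motif_hits)
    if (a$n_distinct_rbps != b$n_distinct_rbps) return(a$n_distinct_rbps > b$n_distinct_rbps)
    as.numeric(a$sequence_id) < as.numeric(b$sequence_id)
  }
  pool <- split(rand, seq_len(nrow(rand)))
  expected <- character()
  while (length(pool) > 0) {
    best <- 1
    for (i in seq_along(pool)) if (before(pool[[i]], pool[[best]])) best <- i
    expected <- c(expected, pool[[best]]$sequence_id)
    pool <- pool[-best]
  }
  expect_equal(got, expected)
})

test_that("ranking with a fixture table puts the native sequence first", {
  # table built to contain motifs overlapping both GGAG and GCAG: every
  # substitution inside the window destroys at least one of them
  motifs <- data.frame(
    motif_id = paste0("m", 1:5),
    pattern = c("GGAG", "GCAG", "GGAGC", "GAGCA", "AGCAG"),
    gene_id = paste0("g", 1:5), stringsAsFactors = FALSE
  )
  native <- mir1246_sequence()
  v <- enumerate_motif_variants(native, mir1246_window())
  seqs <- c(list(native), lapply(seq_len(nrow(v)), function(i) {
    normalize_sequence(v$sequence[i], as.character(v$variant_id[i]))
  }))
  hits <- do.call(rbind, lapply(seqs, scan_motifs, motifs = motifs))
  sms <- do.call(rbind, lapply(seqs, function(s) {
    summarize_hits(hits, NULL, attr(s, "id"))
  }))
  ranked <- rank_sequences(sms)
  expect_equal(ranked$sequence_id[1], "0")
  expect_true(all(ranked$n_motif_hits[-1] < ranked$n_motif_hits[1]))
})

test_that("motif frequencies equal a direct tally", {
  motifs <- data.frame(motif_id = c("m1", "m2", "m3"),
                       pattern = c("GGAG", "GCAG", "GGAG"),
                       gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  native <- mir1246_sequence()
  hits <- scan_motifs(native, motifs)
  freq <- motif_frequency(hits, motifs)
  expect_equal(freq$pattern, c("GGAG", "GCAG"))
  expect_equal(freq$count, c(2L, 1L))
  expect_equal(nrow(motif_frequency(hits[0, ], motifs)), 0L)
})
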