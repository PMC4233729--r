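test_that("promoter FASTA reading normalizes case and validates records", {
  p <- write_fasta_fixture(list("gene1 some description" = "acgtacgtnn",
                                gene2 = "AAAACCCCGGGGTTTT"))
  expect_warning(seqs <- read_promoter_fasta(p), "deviate")
  expect_identical(names(seqs), c("gene1", "gene2"))
  expect_identical(as.character(seqs[["gene1"]]), "ACGTACGTNN")
  dup <- write_fasta_fixture(list(g1 = "ACGTACGT", g1 = "TTTTACGT"))
  names_fix <- readLines(dup)
  expect_error(suppressWarnings(read_promoter_fasta(dup)), "duplicate")
  bad <- write_fasta_fixture(list(g1 = "ACGTXCGT"))
  expect_error(suppressWarnings(read_promoter_fasta(bad)), "g1")
})

test_that("motif counting is overlapping, single-strand, and N-safe", {
  expect_equal(count_motif("AAAAAA", "AAAAA"), 2L)
  expect_equal(count_motif("ATATAT", "ATATA"), 1L)
  expect_equal(count_motif("AANAAAAA", "AAAAA"), 1L)
  expect_equal(count_motif("GGGGGGG", "CCCCC"), 0L)
  expect_equal(count_motif("GGGGGGG", "CCCCC", both_strands = TRUE), 3L)
  expect_error(count_motif("ACGTACGT", "ACGT"), "5-8")
  expect_error(count_motif("ACGTACGT", "ACGTACGTA"), "5-8")
  expect_error(count_motif("ACGTACGT", "ACGNT"), "ACGT")
})

test_that("motif counts agree with a position-by-position scan on random sequence", {
  set.seed(3)
  brute_count <- function(s, m) {
    k <- nchar(m); n <- 0L
    for (i in seq_len(nchar(s) - k + 1L)) {
      if (substr(s, i, i + k - 1L) == m) n <- n + 1L
    }
    n
  }
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    for (k in c(5, 6, 8)) {
      start <- sample(300 - k, 1)
      m <- substr(s, start, start + k - 1L)
      expect_equal(count_motif(s, m), brute_count(s, m))
    }
  }
})

test_that("enrichment ranks planted motifs at the top", {
  set.seed(5)
  bases <- c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)
  mk <- function(n, plant = NULL, p = 0) {
    vapply(seq_len(n), function(i) {
      s <- sample(names(bases), 400, replace = TRUE, prob = bases)
      if (!is.null(plant) && runif(1) < p) {
        pos <- sample(400 - nchar(plant), 1)
        s[pos:(pos + nchar(plant) - 1)] <- strsplit(plant, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
  }
  tgt <- Biostrings::DNAStringSet(stats::setNames(mk(100, "GCATTGCC", 0.9),
                                                  sprintf("t%d", 1:100)))
  bgp <- Biostrings::DNAStringSet(stats::setNames(mk(400, "GCATTGCC", 0.1),
                                                  sprintf("b%d", 1:400)))
  enr <- enrichment_rank(tgt, bgp, top_n = 21)
  expect_lte(match("GCATTGCC", enr$motif), 5)
  expect_equal(enr$rank, 1:21)
  expect_equal(nrow(enrichment_rank(tgt, bgp, top_n = 0)), 0L)
  expect_error(enrichment_rank(tgt, bgp, top_n = 1e7), "exceeds")
  expect_warning(enrichment_rank(tgt, tgt, top_n = 5), "share")
})

test_that("distinct enrichment keeps one representative per motif family", {
  set.seed(6)
  tgt_str <- vapply(1:60, function(i) {
    s <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    s[100:107] <- strsplit("GCATTGCC", "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  bg_str <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1))
  tgt <- Biostrings::DNAStringSet(stats::setNames(tgt_str, sprintf("t%d", 1:60)))
  bgp <- Biostrings::DNAStringSet(stats::setNames(bg_str, sprintf("b%d", 1:60)))
  enr <- enrichment_rank(tgt, bgp, top_n = 10, distinct = TRUE)
  fam <- vapply(enr$motif, function(m)
    grepl(m, "GCATTGCC", fixed = TRUE) || grepl("GCATTGCC", m, fixed = TRUE),
    logical(1))
  expect_lte(sum(fam), 1L)  # at most one family member kept
})

test_that("feature matrices are deterministic, binary by default, and validated", {
  seqs <- Biostrings::DNAStringSet(c(
    g1 = paste(rep("A", 100), collapse = ""),
    g2 = "ACGTACGTCAAAAACGTACGTACGTACGTACGTACGT"
  ))
  fm <- build_feature_matrix(seqs, c("AATATC", "AAAAA"))
  expect_identical(unname(unlist(fm[1, -1])), c(0L, 1L))
  expect_identical(unname(unlist(fm[2, -1])), c(0L, 1L))
  fc <- build_feature_matrix(seqs, c("AAAAA", "CAAAA"), mode = "count")
  expect_equal(fc$AAAAA[1], count_motif(as.character(seqs[[1]]), "AAAAA"))
  expect_equal(ncol(build_feature_matrix(seqs, character(0))), 1L)
  expect_error(build_feature_matrix(seqs, c("AATATC"), genes = c("g1", "gX")), "gX")
  # permutation equivariance in gene order
  fm2 <- build_feature_matrix(seqs[c(2, 1)], c("AATATC", "AAAAA"))
  expect_equal(fm2[match(fm$gene_id, fm2$gene_id), ], fm, ignore_attr = TRUE)
})

test_that("counts are bounded by the window count", {
  set.seed(8)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    m <- substr(s, 1, 6)
    expect_lte(count_motif(s, m), nchar(s) - nchar(m) + 1L)
  }
})
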