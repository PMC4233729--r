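pair_fixture <- function(n = 40, m = 8, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  mk <- function() {
    v <- matrix(rnorm(n * m), n, m)
    v <- sweep(v, 2, colMeans(v))
    v <- sweep(v, 2, sqrt(colMeans(sweep(v, 2, colMeans(v))^2)), "/")
    v <- v - rowMeans(v)
    v / sqrt(rowMeans((v - rowMeans(v))^2))
  }
  xa <- expression_matrix(mk(), ids, seq(0, by = 4, length.out = m), normalized = TRUE)
  xb <- expression_matrix(mk(), ids, seq(0, by = 4, length.out = m), normalized = TRUE)
  list(xa = xa, xb = xb, map = tibble::tibble(gene_a = ids, gene_b = ids))
}

test_that("integrative correlation is 1 for duplicated or negated studies", {
  f <- pair_fixture()
  cc <- integrative_correlation(f$xa, f$xa, f$map)
  expect_equal(cc$corcor, rep(1, nrow(cc)), tolerance = 1e-9)
  neg <- expression_matrix(-f$xa$values, f$xa$gene_ids, f$xa$time_hours,
                           normalized = TRUE)
  cc2 <- integrative_correlation(f$xa, neg, f$map)
  expect_equal(cc2$corcor, rep(1, nrow(cc2)), tolerance = 1e-9)
})

test_that("matrix corCor equals the naive double-loop oracle", {
  f <- pair_fixture(n = 10, m = 6, seed = 3)
  cc <- integrative_correlation(f$xa, f$xb, f$map)
  # brute force: per gene, correlation profile with each other gene
  brute <- vapply(seq_len(10), function(i) {
    pa <- vapply(setdiff(1:10, i), function(j)
      stats::cor(f$xa$values[i, ], f$xa$values[j, ]), numeric(1))
    pb <- vapply(setdiff(1:10, i), function(j)
      stats::cor(f$xb$values[i, ], f$xb$values[j, ]), numeric(1))
    stats::cor(pa, pb)
  }, numeric(1))
  expect_equal(cc$corcor, brute, tolerance = 1e-10)
})

test_that("corCor is symmetric in the two studies", {
  f <- pair_fixture(n = 15, m = 7, seed = 5)
  ab <- integrative_correlation(f$xa, f$xb, f$map)
  ba <- integrative_correlation(f$xb, f$xa, f$map[, c(2, 1)])
  expect_equal(ab$corcor, ba$corcor, tolerance = 1e-12)
})

test_that("constant expression vectors are excluded with a warning", {
  f <- pair_fixture(n = 8, m = 6, seed = 7)
  v <- f$xb$values
  v[3, ] <- 0  # constant after normalization flag is forced below
  xb <- expression_matrix(v, f$xb$gene_ids, f$xb$time_hours)
  xb$normalized <- TRUE
  expect_warning(cc <- integrative_correlation(f$xa, xb, f$map), "constant")
  expect_equal(nrow(cc), 7L)
  expect_equal(nrow(attr(cc, "excluded")), 1L)
})

test_that("the within-gene permutation null is centred and reproducible", {
  spec <- simulation_spec(n_genes = 500, n_circadian = 100, seed = 11)
  pair <- simulate_study_pair(spec, conserved_fraction = 1, seed = 21)
  xa <- preprocess(pair$xa); xb <- preprocess(pair$xb)
  nn <- corcor_null(xa, xb, pair$map, n_permutations = 20, seed = 31)
  expect_gte(mean(nn$corcor), -0.02)
  expect_lte(mean(nn$corcor), 0.02)
  nn2 <- corcor_null(xa, xb, pair$map, n_permutations = 20, seed = 31)
  expect_identical(nn$corcor, nn2$corcor)
  # conserved pairs dominate the null
  cc <- integrative_correlation(xa, xb, pair$map)
  p <- stats::wilcox.test(cc$corcor, nn$corcor, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("co-expression edges follow the one-sided r >= threshold rule", {
  t <- seq(0, 28, by = 4)
  v <- rbind(sin(t), sin(t) + 0.001, -sin(t), cos(t))
  x <- expression_matrix(v, c("a", "b", "anti", "quad"), t)
  e <- coexpression_edges(x, c("a", "b", "anti"), threshold = 0.8)
  expect_equal(nrow(e), 1L)
  expect_identical(c(e$gene1, e$gene2), c("a", "b"))
  e2 <- coexpression_edges(x, c("a", "anti"), threshold = 0.8, absolute = TRUE)
  expect_equal(nrow(e2), 1L)
  # brute-force all-pairs agreement on random genes
  set.seed(13)
  v3 <- matrix(rnorm(20 * 8), 20, 8)
  x3 <- expression_matrix(v3, sprintf("g%d", 1:20), seq(0, 28, by = 4))
  e3 <- coexpression_edges(x3, x3$gene_ids, threshold = 0.5)
  brute <- 0L
  for (i in 1:19) for (j in (i + 1):20) {
    if (stats::cor(v3[i, ], v3[j, ]) >= 0.5) brute <- brute + 1L
  }
  expect_equal(nrow(e3), brute)
})

test_that("Jaccard similarity matches closed-form cases", {
  e <- function(...) {
    p <- list(...)
    tibble::tibble(gene1 = vapply(p, `[[`, "", 1), gene2 = vapply(p, `[[`, "", 2))
  }
  e1 <- e(c("a", "b"), c("b", "c"))
  expect_equal(jaccard_similarity(e1, e1), 1)
  expect_equal(jaccard_similarity(e1, e(c("b", "c"), c("c", "d"))), 1 / 3)
  expect_equal(jaccard_similarity(e1, e(c("x", "y"))), 0)
  empty <- e()[0, ]
  expect_equal(jaccard_similarity(empty, empty), 1)
  # monotone in the intersection at fixed union size
  expect_gte(jaccard_similarity(e1, e1), jaccard_similarity(e1, e(c("a", "b"), c("c", "d"))))
})

test_that("preserved modules score high z; degenerate nulls warn", {
  spec <- simulation_spec(n_genes = 400, n_circadian = 80, seed = 15)
  pair <- simulate_study_pair(spec, conserved_fraction = 1, seed = 25)
  xa <- preprocess(pair$xa); xb <- preprocess(pair$xb)
  dawn <- pair$truth_a$gene_id[pair$truth_a$is_circadian &
                                 pair$truth_a$class == "dawn"]
  mp <- module_preservation(xa, xb, pair$map, dawn, dawn,
                            n_permutations = 50, seed = 35)
  expect_gte(mp$z_score, 5)
  mp2 <- module_preservation(xa, xb, pair$map, dawn, dawn,
                             n_permutations = 50, seed = 35)
  expect_identical(mp$z_score, mp2$z_score)
  # tiny modules: every random draw has no edges -> degenerate null
  two <- pair$truth_a$gene_id[1:2]
  expect_warning(
    mpz <- module_preservation(xa, xb, pair$map, dawn[1:2], dawn[1:2],
                               n_permutations = 5, seed = 45, threshold = 0.999),
    "degenerate")
  expect_true(is.infinite(mpz$z_score) || mpz$z_score == 0)
})
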