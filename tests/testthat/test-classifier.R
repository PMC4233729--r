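# compact planted-motif classification fixture: 4 classes, binary features
classifier_fixture <- function(n_per_class = 60, n_noise_features = 4, seed = 1,
                               p_in = 0.9, p_out = 0.1) {
  set.seed(seed)
  classes <- c("dawn", "noon", "dusk", "midnight")
  ring <- ring_motifs
  cm <- ring_class_motifs(ring)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(4 * n_per_class)),
    module_label = rep(classes, each = n_per_class)
  )
  feats <- vapply(ring, function(mo) {
    inc <- vapply(genes$module_label, function(cl) mo %in% cm[[cl]], logical(1))
    as.integer(stats::runif(nrow(genes)) < ifelse(inc, p_in, p_out))
  }, integer(nrow(genes)))
  noise <- matrix(as.integer(stats::runif(nrow(genes) * n_noise_features) < 0.3),
                  ncol = n_noise_features,
                  dimnames = list(NULL, sprintf("TTAACCG%d", seq_len(n_noise_features))))
  colnames(noise) <- c("TTAACCGG", "CCGGTTAA", "ACACACGT", "TGTGTGCA")[seq_len(n_noise_features)]
  fm <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                         tibble::as_tibble(cbind(feats, noise)))
  class(fm) <- c("motif_feature_matrix", class(fm))
  list(features = fm, labels = genes, class_motifs = cm)
}

test_that("ROC and AUC follow the threshold-sweep contract", {
  r <- compute_roc(c(0.9, 0.8, 0.4, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_error(compute_roc(c(1, 2), c(TRUE, TRUE)), "negative")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(11)
  for (rep in 1:5) {
    scores <- stats::rnorm(60)
    truth <- stats::runif(60) < 0.4
    if (!any(truth) || all(truth)) next
    auc <- compute_roc(scores, truth)$auc
    u <- stats::wilcox.test(scores[truth], scores[!truth])$statistic
    expect_equal(auc, unname(u) / (sum(truth) * sum(!truth)), tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      proc_auc <- pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                      direction = "<",
                                      levels = c(FALSE, TRUE)))
      expect_equal(auc, as.numeric(proc_auc), tolerance = 1e-9)
    }
  }
})

test_that("null scores give chance-level AUC", {
  set.seed(12)
  scores <- stats::rnorm(2000)
  truth <- stats::runif(2000) < 0.5
  expect_lt(abs(compute_roc(scores, truth)$auc - 0.5), 0.05)
})

test_that("phase forests separate planted feature classes and reproduce exactly", {
  f <- classifier_fixture(seed = 2)
  cfg <- forest_config(n_trees = 300, seed = 9)
  m1 <- train_phase_forests(f$features, f$labels, cfg, vimp_repeats = 3)
  expect_true(all(glance(m1)$auc > 0.8))
  expect_equal(m1$mtry, floor(sqrt(9)))
  # balanced training: equal class counts
  tr_classes <- f$labels$module_label[match(m1$train_ids, f$labels$gene_id)]
  expect_equal(length(unique(table(tr_classes))), 1L)
  m2 <- train_phase_forests(f$features, f$labels, cfg, vimp_repeats = 3)
  expect_identical(glance(m1)$auc, glance(m2)$auc)
  expect_identical(m1$vimp, m2$vimp)
})

test_that("shuffled labels give chance AUC and small classes are rejected", {
  f <- classifier_fixture(seed = 3, n_per_class = 100)
  set.seed(21)
  shuffled <- f$labels
  shuffled$module_label <- sample(shuffled$module_label)
  m <- train_phase_forests(f$features, shuffled, forest_config(n_trees = 300, seed = 5),
                           vimp_repeats = 1)
  expect_true(all(glance(m)$auc > 0.35 & glance(m)$auc < 0.65))
  small <- f$labels[c(1:20, 101:120, 201:220, 301:303), ]
  expect_error(train_phase_forests(f$features, small, forest_config(n_trees = 50)),
               "fewer than 6")
})

test_that("variable importance highlights planted motifs and zero features score zero", {
  f <- classifier_fixture(seed = 4)
  zero_fm <- f$features
  zero_fm$ACACACGT <- 0L
  m <- train_phase_forests(zero_fm, f$labels, forest_config(n_trees = 400, seed = 6),
                           vimp_repeats = 5)
  for (cl in c("dawn", "dusk")) {
    v <- variable_importance(m, cl)
    expect_true(all(f$class_motifs[[cl]] %in% utils::head(v$motif, 6)))
    expect_lt(abs(v$vimp[v$motif == "ACACACGT"]), 1e-9)
  }
  expect_error(variable_importance(m, "twilight"), "unknown class")
  roc <- roc_and_auc(m)
  expect_setequal(unique(roc$class), m$classes)
})

test_that("the progressive table recovers the planted ring with day-ordered double rows", {
  f <- classifier_fixture(seed = 7, n_per_class = 80)
  m <- train_phase_forests(f$features, f$labels, forest_config(n_trees = 500, seed = 8),
                           vimp_repeats = 5)
  tab <- progressive_table(m, top_k = 4, extra_motifs = ring_motifs, grouped = TRUE)
  expect_identical(tab$phase, rep(c("dawn", "noon", "dusk", "midnight"), 2))
  got <- sapply(ring_motifs, function(r)
    if (r %in% names(tab)) tab[[r]][1:4] else rep(FALSE, 4))
  expd <- sapply(ring_motifs, function(r)
    vapply(c("dawn", "noon", "dusk", "midnight"), function(cl)
      r %in% f$class_motifs[[cl]], logical(1)))
  expect_equal(unname(got), unname(expd))
  # top_k beyond feature count: every motif eligible
  tab2 <- progressive_table(m, top_k = 100)
  expect_gte(ncol(tab2), length(ring_motifs) + 1)
})

test_that("mean phase of a combination averages carrier projections", {
  proj <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    q1 = c(0.5, 0.5, -0.3, 0.9), q2 = c(0, 0, 0.6, 0.1),
    radius = sqrt(q1^2 + q2^2), angle_rad = atan2(q2, q1),
    phase_h = (atan2(q2, q1) %% (2 * pi)) / (2 * pi) * 24,
    is_circadian = c(TRUE, TRUE, TRUE, FALSE), module = NA_integer_
  )
  class(proj) <- c("circadian_projection", class(proj))
  fm <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       AATATCGC = c(1L, 1L, 0L, 1L),
                       GATAAGCG = c(1L, 1L, 1L, 1L))
  class(fm) <- c("motif_feature_matrix", class(fm))
  mp <- mean_phase_of_combination(proj, fm, "AATATCGC")
  expect_equal(c(mp$q1, mp$q2), c(0.5, 0))
  expect_equal(mp$n_genes, 2L)
  # single ubiquitous motif: centroid of all circadian genes
  mp2 <- mean_phase_of_combination(proj, fm, "GATAAGCG")
  expect_equal(mp2$q1, mean(proj$q1[proj$is_circadian]))
  expect_error(mean_phase_of_combination(proj, fm, c("AATATCGC", "MISSING1")),
               "absent")
  fm$AATATCGC <- c(0L, 0L, 0L, 1L)
  expect_error(mean_phase_of_combination(proj, fm, "AATATCGC"), "no circadian")
})
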