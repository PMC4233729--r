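make_proj_fixture <- function() {
  t <- fixture_times
  v1 <- cos(2 * pi * t / 24); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- sin(2 * pi * t / 24); v2 <- v2 / sqrt(sum(v2^2))
  g1 <- v1                                  # identical to v1
  g2 <- rep(c(1, -1), 6); g2 <- g2 - mean(g2); g2 <- g2 / sqrt(sum(g2^2))
  g2 <- g2 - v1 * sum(g2 * v1) - v2 * sum(g2 * v2)  # orthogonal to both
  g2 <- g2 / sqrt(sum(g2^2))
  g3 <- (v1 + v2) / sqrt(2)
  vals <- rbind(g1, g2, g3)
  vals <- vals - rowMeans(vals)
  vals <- vals / sqrt(rowMeans((vals - rowMeans(vals))^2))
  x <- expression_matrix(vals, c("same", "ortho", "diag"), t, normalized = TRUE)
  list(x = x, v1 = v1, v2 = v2)
}

test_that("projection geometry matches closed forms", {
  f <- make_proj_fixture()
  proj <- project_genes(f$x, f$v1, f$v2)
  expect_equal(proj$q1[1], 1, tolerance = 1e-9)
  expect_equal(proj$q2[1], 0, tolerance = 1e-9)
  expect_equal(proj$radius[1], 1, tolerance = 1e-9)
  expect_equal(proj$angle_rad[1], 0, tolerance = 1e-9)
  expect_equal(proj$radius[2], 0, tolerance = 1e-9)
  expect_equal(proj$radius[3], 1, tolerance = 1e-9)
  expect_equal(proj$angle_rad[3], pi / 4, tolerance = 1e-9)
  expect_equal(proj$phase_h[3], 3, tolerance = 1e-6)
})

test_that("the radial cutoff is inclusive and validated", {
  f <- make_proj_fixture()
  proj <- project_genes(f$x, f$v1, f$v2)
  proj$radius <- c(0.8, 0.5, 0.9)
  out <- suppressMessages(classify_circadian(proj, cutoff = 0.8))
  expect_identical(out$is_circadian, c(TRUE, FALSE, TRUE))
  expect_error(classify_circadian(proj, cutoff = 0), "\\(0, 1\\]")
  expect_error(classify_circadian(proj, cutoff = 1.2), "\\(0, 1\\]")
})

test_that("module assignment follows the signed-axis argmax with fixed tie-break", {
  f <- make_proj_fixture()
  proj <- project_genes(f$x, f$v1, f$v2)
  proj$q1 <- c(0.9, -0.1, 0.6)
  proj$q2 <- c(0.1, -0.85, 0.6)
  proj$is_circadian <- c(TRUE, TRUE, TRUE)
  out <- assign_modules(proj)
  expect_identical(out$module, c(3L, 2L, 3L))  # noon, dusk, tie -> +q1 precedence
  expect_identical(as.character(out$module_label), c("noon", "dusk", "noon"))
  proj$is_circadian <- c(TRUE, FALSE, TRUE)
  out2 <- assign_modules(proj)
  expect_true(is.na(out2$module[2]))
})

test_that("circular order sorts by angle and survives joint rotation", {
  f <- make_proj_fixture()
  proj <- project_genes(f$x, f$v1, f$v2)
  proj$is_circadian <- rep(TRUE, 3)
  proj$angle_rad <- c(pi / 2, -pi / 2, 0)
  ord <- circular_order(proj)
  expect_identical(ord$gene_id, c("ortho", "diag", "same"))
  # joint rotation of the component pair leaves radii and relative order intact
  theta <- 0.4
  w1 <- cos(theta) * f$v1 + sin(theta) * f$v2
  w2 <- -sin(theta) * f$v1 + cos(theta) * f$v2
  p0 <- project_genes(f$x, f$v1, f$v2)
  p1 <- project_genes(f$x, w1, w2)
  expect_equal(p1$radius, p0$radius, tolerance = 1e-9)
  p0$is_circadian <- p1$is_circadian <- p0$radius > 0.5
  expect_identical(circular_order(p1)$gene_id,
                   circular_order(p0)$gene_id)
  p0$is_circadian <- rep(FALSE, 3)
  expect_equal(nrow(circular_order(p0)), 0L)
})

test_that("planted cyclers are called with high recall and low FPR at cutoff 0.8", {
  sim <- simulate_expression(simulation_spec(seed = 42))
  x <- preprocess(sim$expr)
  pl <- planted_trends()
  proj <- suppressMessages(classify_circadian(project_genes(x, pl[2, ], pl[1, ])))
  proj <- assign_modules(proj)
  truth <- sim$truth
  strong <- truth$is_circadian & truth$amplitude / 0.35 >= 2
  expect_gte(mean(proj$is_circadian[strong]), 0.90)
  expect_lte(mean(proj$is_circadian[!truth$is_circadian]), 0.05)
  # module recovery against the planted class (axes oriented: +q1 noon, +q2 dawn)
  called <- proj$is_circadian & truth$is_circadian
  acc <- mean(truth$class[called] == as.character(proj$module_label[called]))
  expect_gte(acc, 0.95)
  # phase recovery: circular (Fisher-Lee) correlation between planted and
  # recovered phase; magnitude is what matters, the sense of rotation is a
  # convention of the axis orientation
  circ_cor <- function(a, b) {
    ma <- atan2(mean(sin(a)), mean(cos(a)))
    mb <- atan2(mean(sin(b)), mean(cos(b)))
    sum(sin(a - ma) * sin(b - mb)) /
      sqrt(sum(sin(a - ma)^2) * sum(sin(b - mb)^2))
  }
  ph_t <- truth$peak_h[called] / 24 * 2 * pi
  ph_r <- proj$phase_h[called] / 24 * 2 * pi
  expect_gte(abs(circ_cor(ph_t, ph_r)), 0.95)
})

test_that("zero-norm genes and malformed components are rejected", {
  f <- make_proj_fixture()
  vals <- f$x$values
  x <- expression_matrix(vals, f$x$gene_ids, f$x$time_hours, normalized = TRUE)
  x$values[2, ] <- 0
  expect_error(project_genes(x, f$v1, f$v2), "zero-norm")
  expect_error(project_genes(f$x, f$v1 * 2, f$v2), "unit")
  expect_warning(project_genes(f$x, f$v1, (f$v1 + f$v2) / sqrt(2 + 2 * sum(f$v1 * f$v2))),
                 "orthogonal")
})
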