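#' Integrative correlation between two studies
#'
#' For every ortholog pair, correlates the gene's correlation profile in study
#' A (its Pearson correlations with the other mapped genes) with the matched
#' profile in study B over the same ortholog-aligned gene list. A gene whose
#' co-expression neighbourhood is conserved scores near 1 regardless of
#' platform or scale differences between the studies.
#'
#' @param xa,xb Normalized `expression_matrix` objects for the two studies.
#' @param map Ortholog map: data frame whose first two columns give gene ids
#'   in study A and study B (one-to-one; duplicates rejected).
#' @return A `corcor_result` tibble: `gene_a`, `gene_b`, `corcor`. Pairs with
#'   a constant expression vector are excluded with a warning and recorded in
#'   the `excluded` attribute.
#' @export
integrative_correlation <- function(xa, xb, map) {
  al <- align_studies(xa, xb, map)
  # pairs with a constant vector in either study can neither receive a score
  # nor contribute to other genes' correlation profiles
  ok <- row_pop_sd(al$va) > 0 & row_pop_sd(al$vb) > 0
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) excluded (constant expression vector): ",
            paste(utils::head(al$map[[1L]][!ok], 5L), collapse = ", "))
  }
  excluded <- tibble::tibble(gene_a = al$map[[1L]][!ok], gene_b = al$map[[2L]][!ok])
  cc <- corcor_values(al$va[ok, , drop = FALSE], al$vb[ok, , drop = FALSE])
  out <- tibble::tibble(gene_a = al$map[[1L]][ok], gene_b = al$map[[2L]][ok],
                        corcor = cc)
  attr(out, "excluded") <- excluded
  class(out) <- c("corcor_result", class(out))
  out
}

align_studies <- function(xa, xb, map) {
  check_normalized(xa); check_normalized(xb)
  map <- tibble::as_tibble(map[, 1:2])
  if (nrow(map) < 3L) stop("ortholog map needs at least 3 pairs", call. = FALSE)
  if (anyDuplicated(map[[1L]]) || anyDuplicated(map[[2L]])) {
    stop("ortholog map must be one-to-one; collapse duplicates upstream", call. = FALSE)
  }
  miss_a <- setdiff(map[[1L]], xa$gene_ids)
  miss_b <- setdiff(map[[2L]], xb$gene_ids)
  if (length(miss_a) || length(miss_b)) {
    stop("mapped genes missing from the studies: ",
         paste(utils::head(c(miss_a, miss_b), 5L), collapse = ", "), call. = FALSE)
  }
  list(map = map,
       va = xa$values[map[[1L]], , drop = FALSE],
       vb = xb$values[map[[2L]], , drop = FALSE])
}

# corCor over aligned value matrices; constant rows give NA.
corcor_values <- function(va, vb) {
  ca <- suppressWarnings(stats::cor(t(va)))
  cb <- suppressWarnings(stats::cor(t(vb)))
  n <- nrow(va)
  vapply(seq_len(n), function(i) {
    a <- ca[i, -i]; b <- cb[i, -i]
    if (anyNA(a) || anyNA(b)) return(NA_real_)
    suppressWarnings(stats::cor(a, b))
  }, numeric(1))
}

#' Permutation null for the integrative correlation
#'
#' Shuffles the expression values within every gene of study B, recomputes
#' the integrative correlation for all mapped pairs, and pools the values
#' across permutations. This is the negative control against which observed
#' corCor distributions are judged.
#'
#' @inheritParams integrative_correlation
#' @param n_permutations Number of within-gene shuffles of study B.
#' @param seed Integer seed.
#' @return A tibble with columns `permutation`, `gene_a`, `corcor`.
#' @export
corcor_null <- function(xa, xb, map, n_permutations = 20L, seed = 1L) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1", call. = FALSE)
  al <- align_studies(xa, xb, map)
  with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_permutations), function(p) {
      vb_perm <- t(apply(al$vb, 1L, sample))
      tibble::tibble(permutation = p, gene_a = al$map[[1L]],
                     corcor = corcor_values(al$va, vb_perm))
    })
  })
}

#' Co-expression edges of a gene set
#'
#' Undirected edges between genes whose Pearson correlation reaches the
#' threshold. The rule is one-sided (`r >= threshold`): strong
#' anti-correlation does not create an edge unless `absolute = TRUE`.
#'
#' @param x An `expression_matrix`.
#' @param genes Character vector of gene ids (subset of `x`).
#' @param threshold Correlation threshold (default 0.8).
#' @param absolute Use `|r| >= threshold` instead of the one-sided rule.
#' @return A tibble `gene1`, `gene2`, `r` with `gene1 < gene2` lexically.
#' @export
coexpression_edges <- function(x, genes, threshold = 0.8, absolute = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  missing <- setdiff(genes, x$gene_ids)
  if (length(missing)) {
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(t(x$values[genes, , drop = FALSE])))
  cm[is.na(cm)] <- 0
  idx <- which(upper.tri(cm) & (if (absolute) abs(cm) else cm) >= threshold,
               arr.ind = TRUE)
  g1 <- genes[idx[, 1L]]; g2 <- genes[idx[, 2L]]
  swap <- g1 > g2
  tibble::tibble(gene1 = ifelse(swap, g2, g1),
                 gene2 = ifelse(swap, g1, g2),
                 r = cm[idx])
}

#' Jaccard similarity of two edge sets
#'
#' `|E1 n E2| / |E1 u E2|`, i.e. TP / (TP + FP + FN) over edges. Two empty
#' edge sets count as identical (returns 1).
#'
#' @param e1,e2 Edge tibbles as returned by [coexpression_edges()] (only
#'   `gene1`/`gene2` are used; node ids must live in a shared universe).
#' @return A number in \[0, 1\].
#' @export
jaccard_similarity <- function(e1, e2) {
  k1 <- edge_keys(e1); k2 <- edge_keys(e2)
  u <- union(k1, k2)
  if (length(u) == 0L) return(1)
  length(intersect(k1, k2)) / length(u)
}

edge_keys <- function(e) {
  if (is.null(e) || nrow(e) == 0L) return(character())
  a <- pmin(e$gene1, e$gene2); b <- pmax(e$gene1, e$gene2)
  unique(paste(a, b, sep = "\r"))
}

#' Module preservation z-score across studies
#'
#' Builds the co-expression edge sets of a module in each study (study-B genes
#' mapped into study-A ids through the ortholog map so edges share a node
#' universe), scores their Jaccard similarity, and normalizes against a null
#' of random gene sets of the same sizes drawn from the mapped universe.
#'
#' @inheritParams integrative_correlation
#' @param module_a,module_b Gene sets (ids in their own study's namespace).
#' @param n_permutations Random same-size draws for the null (default 100).
#' @param threshold Co-expression edge threshold (default 0.8).
#' @param seed Integer seed.
#' @return A `module_preservation` list: `jaccard`, `null_mean`, `null_sd`,
#'   `z_score`, `n_permutations`, `edge_threshold`, `null_values`.
#' @export
module_preservation <- function(xa, xb, map, module_a, module_b,
                                n_permutations = 100L, threshold = 0.8, seed = 1L) {
  al <- align_studies(xa, xb, map)
  map_ab <- stats::setNames(al$map[[1L]], al$map[[2L]])
  module_a <- intersect(as.character(module_a), al$map[[1L]])
  module_b <- intersect(as.character(module_b), al$map[[2L]])
  if (length(module_a) < 2L || length(module_b) < 2L) {
    stop("modules must keep at least 2 mapped genes each", call. = FALSE)
  }
  edges_a <- function(genes_a) coexpression_edges(xa, genes_a, threshold)
  edges_b <- function(genes_b) {
    e <- coexpression_edges(xb, genes_b, threshold)
    e$gene1 <- unname(map_ab[e$gene1]); e$gene2 <- unname(map_ab[e$gene2])
    e
  }
  observed <- jaccard_similarity(edges_a(module_a), edges_b(module_b))
  null_values <- with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(p) {
      ra <- sample(al$map[[1L]], length(module_a))
      rb <- sample(al$map[[2L]], length(module_b))
      jaccard_similarity(edges_a(ra), edges_b(rb))
    }, numeric(1))
  })
  mu <- mean(null_values); sdv <- stats::sd(null_values)
  z <- if (sdv == 0) {
    warning("null distribution degenerate (sd = 0); z reported as Inf")
    if (observed > mu) Inf else if (observed < mu) -Inf else 0
  } else {
    (observed - mu) / sdv
  }
  structure(
    list(jaccard = observed, null_mean = mu, null_sd = sdv, z_score = z,
         n_permutations = as.integer(n_permutations), edge_threshold = threshold,
         null_values = null_values),
    class = "module_preservation"
  )
}

#' @export
print.module_preservation <- function(x, ...) {
  cat("<module_preservation> Jaccard = ", sprintf("%.4f", x$jaccard),
      ", null ", sprintf("%.4f +/- %.4f", x$null_mean, x$null_sd),
      ", z = ", sprintf("%.2f", x$z_score),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
glance.module_preservation <- function(x, ...) {
  tibble::tibble(jaccard = x$jaccard, null_mean = x$null_mean,
                 null_sd = x$null_sd, z_score = x$z_score,
                 n_permutations = x$n_permutations,
                 edge_threshold = x$edge_threshold)
}

#' Read a two-column ortholog map TSV
#'
#' @param path TSV with a header and two columns of gene ids.
#' @return A tibble with the two id columns.
#' @export
read_ortholog_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(m) < 2L) stop("ortholog map needs two columns", call. = FALSE)
  m[, 1:2]
}
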