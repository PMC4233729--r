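#' Pipeline configuration
#'
#' Collects the paths and stage parameters of the end-to-end analysis. The
#' defaults are the canonical settings of the method: radial cutoff 0.8, 100
#' averaged ICA runs, 1000 randomizations for the component-count test,
#' 5-8 bp motifs with the top 21 kept, 2000-tree forests with default `mtry`,
#' top-10 VIMP rows in the progressive table.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param expression_tsv,promoter_fasta,ortholog_tsv Optional input paths;
#'   stages that need a missing input fail with a clear message unless the
#'   `simulate` stage provided it.
#' @param cutoff,n_runs,n_randomizations,component_d,k_min,k_max,top_n,n_trees,mtry,top_k
#'   Stage parameters (see the stage functions). `component_d` is the number
#'   of eigentrends extracted and tested (3 by default — the two circadian
#'   trends plus the damping trend).
#' @param sim Optional [simulation_spec()] for the `simulate` stage.
#' @param seed Master seed; every stage derives its randomness from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "circatrend_run",
                            expression_tsv = NULL, promoter_fasta = NULL,
                            ortholog_tsv = NULL,
                            cutoff = 0.8, n_runs = 100L, n_randomizations = 1000L,
                            component_d = 3L, k_min = 5L, k_max = 8L, top_n = 21L,
                            n_trees = 2000L, mtry = NULL, top_k = 10L,
                            sim = NULL, seed = 1L) {
  structure(list(out_dir = out_dir, expression_tsv = expression_tsv,
                 promoter_fasta = promoter_fasta, ortholog_tsv = ortholog_tsv,
                 cutoff = cutoff, n_runs = as.integer(n_runs),
                 n_randomizations = as.integer(n_randomizations),
                 component_d = as.integer(component_d),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 top_n = as.integer(top_n), n_trees = as.integer(n_trees),
                 mtry = mtry, top_k = as.integer(top_k), sim = sim,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "preprocess", "ica", "significance", "project",
                     "modules", "motifs", "classify", "progressive", "full")

#' Run one pipeline stage (or the whole pipeline)
#'
#' Each stage reads its inputs from `config` (or from the artifacts an
#' earlier stage wrote under `config$out_dir`), writes its outputs as TSV,
#' and appends a JSON run manifest recording the package version, seed and
#' parameters. `stage = "full"` chains every applicable stage.
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"ica"`, `"significance"`,
#'   `"project"`, `"modules"`, `"motifs"`, `"classify"`, `"progressive"`,
#'   `"full"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths written by the stage.
#' @export
run_stage <- function(stage, config) {
  if (length(stage) != 1L || !stage %in% pipeline_stages) {
    stop("unknown stage '", paste(stage, collapse = ","), "'; stages: ",
         paste(pipeline_stages, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(stage,
    simulate = stage_simulate(config),
    preprocess = stage_preprocess(config),
    ica = stage_ica(config),
    significance = stage_significance(config),
    project = stage_project(config),
    modules = stage_modules(config),
    motifs = stage_motifs(config),
    classify = stage_classify(config),
    progressive = stage_progressive(config),
    full = {
      out <- list()
      for (s in setdiff(pipeline_stages, "full")) {
        out <- c(out, run_stage(s, config))
      }
      out
    }
  )
  write_manifest(stage, config)
  invisible(paths)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) run_stage("full", config)

art <- function(config, name) file.path(config$out_dir, name)

write_manifest <- function(stage, config) {
  manifest <- list(
    stage = stage,
    package = "circatrend",
    version = as.character(utils::packageVersion("circatrend")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "out_dir"))]
  )
  path <- art(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

stage_simulate <- function(config) {
  spec <- config$sim
  if (is.null(spec)) spec <- simulation_spec(seed = config$seed)
  sim <- simulate_expression(spec)
  p_expr <- art(config, "expression.tsv")
  write_expression_table(sim$expr, p_expr)
  p_truth <- art(config, "truth.tsv")
  readr::write_tsv(sim$truth, p_truth, progress = FALSE)
  list(expression = p_expr, truth = p_truth)
}

load_expression <- function(config) {
  path <- config$expression_tsv
  if (is.null(path)) path <- art(config, "expression.tsv")
  if (!file.exists(path)) {
    stop("expression input not found (looked at '", path,
         "'); run the simulate stage or set `expression_tsv`", call. = FALSE)
  }
  read_expression_table(path, log_transformed = TRUE)
}

load_normalized <- function(config) {
  path <- art(config, "normalized.tsv")
  if (!file.exists(path)) {
    stop("normalized matrix not found; run the preprocess stage first", call. = FALSE)
  }
  x <- read_expression_table(path, log_transformed = TRUE)
  expression_matrix(x$values, x$gene_ids, x$time_hours, normalized = TRUE)
}

stage_preprocess <- function(config) {
  x <- preprocess(load_expression(config), apply_log2 = FALSE)
  p <- art(config, "normalized.tsv")
  write_expression_table(x, p)
  list(normalized = p)
}

stage_ica <- function(config) {
  x <- load_normalized(config)
  dec <- run_ica(x, n_components = config$component_d, n_runs = config$n_runs,
                 seed = config$seed)
  p <- art(config, "eigentrends.tsv")
  readr::write_tsv(tidy(dec), p, progress = FALSE)
  pca <- run_pca(x, n_components = ncol(x$values) - 1L)
  p2 <- art(config, "pca_trends.tsv")
  readr::write_tsv(tidy(pca), p2, progress = FALSE)
  list(eigentrends = p, pca_trends = p2)
}

stage_significance <- function(config) {
  x <- load_normalized(config)
  test <- empirical_component_test(x, d = config$component_d,
                                   n_randomizations = config$n_randomizations,
                                   seed = config$seed,
                                   n_runs = max(1L, config$n_runs %/% 10L))
  p <- art(config, "component_test.tsv")
  readr::write_tsv(tidy(test), p, progress = FALSE)
  p2 <- art(config, "component_test.json")
  jsonlite::write_json(as.list(glance(test)), p2, auto_unbox = TRUE, digits = NA)
  list(component_test = p, component_test_summary = p2)
}

run_projection <- function(config) {
  x <- load_normalized(config)
  dec <- run_ica(x, n_components = config$component_d, n_runs = config$n_runs,
                 seed = config$seed)
  pick <- select_circadian_components(dec)
  ax <- orient_axes(dec, pick)
  proj <- project_genes(x, ax$v1, ax$v2)
  classify_circadian(proj, cutoff = config$cutoff)
}

stage_project <- function(config) {
  proj <- run_projection(config)
  p <- art(config, "projection.tsv")
  readr::write_tsv(tibble::as_tibble(proj), p, progress = FALSE)
  list(projection = p)
}

stage_modules <- function(config) {
  proj <- assign_modules(run_projection(config))
  p <- art(config, "modules.tsv")
  readr::write_tsv(tibble::as_tibble(proj), p, progress = FALSE)
  p2 <- art(config, "circular_order.tsv")
  readr::write_tsv(circular_order(proj), p2, progress = FALSE)
  list(modules = p, circular_order = p2)
}

load_modules <- function(config) {
  p <- art(config, "modules.tsv")
  if (!file.exists(p)) stop("modules not found; run the modules stage", call. = FALSE)
  out <- readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
  class(out) <- c("circadian_projection", class(out))
  out
}

load_promoters <- function(config) {
  path <- config$promoter_fasta
  if (is.null(path)) path <- art(config, "promoters.fasta")
  if (!file.exists(path)) {
    stop("promoter FASTA not found (looked at '", path, "')", call. = FALSE)
  }
  read_promoter_fasta(path)
}

stage_motifs <- function(config) {
  proj <- load_modules(config)
  promoters <- ensure_promoters(config, proj)
  circ <- proj$gene_id[proj$is_circadian]
  bg <- setdiff(proj$gene_id, circ)
  have <- names(promoters)
  enr <- enrichment_rank(promoters[intersect(circ, have)],
                         promoters[intersect(bg, have)],
                         k_min = config$k_min, k_max = config$k_max,
                         top_n = config$top_n)
  p <- art(config, "enrichment.tsv")
  readr::write_tsv(enr, p, progress = FALSE)
  fm <- build_feature_matrix(promoters, enr$motif, mode = "binary",
                             genes = intersect(circ, have))
  p2 <- art(config, "features.tsv")
  readr::write_tsv(tibble::as_tibble(fm), p2, progress = FALSE)
  list(enrichment = p, features = p2)
}

# When no promoter FASTA is supplied, derive one from the module calls so the
# full pipeline is exercisable end-to-end on simulated data alone.
ensure_promoters <- function(config, proj) {
  path <- config$promoter_fasta
  if (!is.null(path) && file.exists(path)) return(read_promoter_fasta(path))
  gen <- art(config, "promoters.fasta")
  if (file.exists(gen)) return(read_promoter_fasta(gen))
  cls <- ifelse(proj$is_circadian & !is.na(proj$module),
                module_labels[proj$module], "background")
  pspec <- promoter_sim_spec(
    genes = tibble::tibble(gene_id = proj$gene_id, class = cls),
    seed = config$seed + 1L
  )
  sim <- simulate_promoters(pspec)
  write_promoter_fasta(sim$promoters, gen)
  readr::write_tsv(sim$truth, art(config, "promoter_truth.tsv"), progress = FALSE)
  sim$promoters
}

load_features <- function(config) {
  p <- art(config, "features.tsv")
  if (!file.exists(p)) stop("features not found; run the motifs stage", call. = FALSE)
  out <- readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
  class(out) <- c("motif_feature_matrix", class(out))
  out
}

fit_forests <- function(config) {
  proj <- load_modules(config)
  fm <- load_features(config)
  labels <- proj[proj$is_circadian & !is.na(proj$module),
                 c("gene_id", "module"), drop = FALSE]
  labels <- labels[labels$gene_id %in% fm$gene_id, , drop = FALSE]
  train_phase_forests(fm, labels,
                      cfg = forest_config(n_trees = config$n_trees,
                                          mtry = config$mtry,
                                          seed = config$seed + 2L))
}

stage_classify <- function(config) {
  model <- fit_forests(config)
  p <- art(config, "vimp.tsv")
  readr::write_tsv(tidy(model), p, progress = FALSE)
  p2 <- art(config, "roc.tsv")
  readr::write_tsv(roc_and_auc(model), p2, progress = FALSE)
  p3 <- art(config, "classifier.json")
  jsonlite::write_json(list(auc = as.list(stats::setNames(as.numeric(model$auc),
                                                          model$classes)),
                            mtry = model$mtry, n_trees = model$cfg$n_trees),
                       p3, auto_unbox = TRUE, digits = NA)
  list(vimp = p, roc = p2, classifier_summary = p3)
}

stage_progressive <- function(config) {
  model <- fit_forests(config)
  tab <- progressive_table(model, top_k = config$top_k)
  p <- art(config, "progressive_table.tsv")
  readr::write_tsv(tab, p, progress = FALSE)
  list(progressive_table = p)
}
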