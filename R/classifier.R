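#' Random-forest configuration for phase classification
#'
#' Defaults follow the published scheme: 2000 trees, `mtry` equal to the
#' integer square root of the feature count (4 for the canonical 21 motifs),
#' a stratified two-thirds training split with equal class counts
#' (downsampled to the smallest class), and vote fractions as scores.
#'
#' @param n_trees Trees per forest (default 2000).
#' @param mtry Features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param train_fraction Training fraction (default 2/3).
#' @param balanced_training Equalize class counts in the training set.
#' @param n_repeats Repeated-split mode: number of independent splits whose
#'   AUCs are averaged (default 1 = a single split).
#' @param seed Integer seed.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 2000L, mtry = NULL, train_fraction = 2 / 3,
                          balanced_training = TRUE, n_repeats = 1L, seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 train_fraction = train_fraction,
                 balanced_training = isTRUE(balanced_training),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "forest_config")
}

#' Train one-vs-rest phase forests on motif features
#'
#' Fits one random forest per phase class (class versus rest) on a stratified
#' two-thirds training set with equal class counts, scores the held-out third
#' by in-class vote fraction, and reports per-class ROC/AUC, a confusion
#' table, and held-out permutation variable importance. One-vs-rest forests
#' are used because class-conditional importance rankings are the object of
#' interest; a single multiclass forest does not yield them cleanly.
#'
#' @param features A `motif_feature_matrix` (from [build_feature_matrix()]).
#' @param labels Data frame with columns `gene_id` and `module` (or
#'   `module_label`); every labelled gene needs a feature row.
#' @param cfg A [forest_config()].
#' @param vimp_repeats Permutation repeats for variable importance
#'   (default 10).
#' @return A `phase_forest` object; see [tidy.phase_forest()] and
#'   [glance.phase_forest()] for tabular views.
#' @export
train_phase_forests <- function(features, labels, cfg = forest_config(),
                                vimp_repeats = 10L) {
  stopifnot(inherits(features, "motif_feature_matrix"))
  labels <- normalize_labels(labels)
  if (!all(labels$gene_id %in% features$gene_id)) {
    miss <- setdiff(labels$gene_id, features$gene_id)
    stop("labelled gene(s) without feature rows: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  fm <- as.data.frame(features[match(labels$gene_id, features$gene_id), -1L,
                               drop = FALSE])
  rownames(fm) <- labels$gene_id
  classes <- sort(unique(labels$class))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  sizes <- table(labels$class)
  if (any(sizes < 6L)) {
    stop("class(es) with fewer than 6 genes cannot support a 2/3 - 1/3 split: ",
         paste(names(sizes)[sizes < 6L], collapse = ", "), call. = FALSE)
  }
  p <- ncol(fm)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(p))) else as.integer(cfg$mtry)

  fit_split <- function(split_seed) {
    with_seed(split_seed, {
      n_per <- floor(cfg$train_fraction * min(sizes))
      train_ids <- unlist(lapply(classes, function(cl) {
        ids <- labels$gene_id[labels$class == cl]
        sample(ids, if (cfg$balanced_training) n_per
               else floor(cfg$train_fraction * length(ids)))
      }), use.names = FALSE)
      holdout_ids <- setdiff(labels$gene_id, train_ids)
      ytr <- labels$class[match(train_ids, labels$gene_id)]
      forests <- stats::setNames(lapply(classes, function(cl) {
        y <- factor(ifelse(ytr == cl, "in", "out"), levels = c("out", "in"))
        randomForest::randomForest(x = fm[train_ids, , drop = FALSE], y = y,
                                   ntree = cfg$n_trees, mtry = mtry)
      }), classes)
      list(forests = forests, train_ids = train_ids, holdout_ids = holdout_ids)
    })
  }

  split <- fit_split(cfg$seed)
  yho <- labels$class[match(split$holdout_ids, labels$gene_id)]
  scores <- vapply(classes, function(cl) {
    stats::predict(split$forests[[cl]], fm[split$holdout_ids, , drop = FALSE],
                   type = "prob")[, "in"]
  }, numeric(length(split$holdout_ids)))
  pred <- classes[max.col(scores, ties.method = "first")]
  confusion <- table(truth = yho, predicted = factor(pred, levels = classes))
  roc <- stats::setNames(lapply(classes, function(cl) {
    compute_roc(scores[, cl], yho == cl)
  }), classes)
  auc <- vapply(roc, function(r) r$auc, numeric(1))

  extra_auc <- NULL
  if (cfg$n_repeats > 1L) {
    extra_auc <- vapply(seq_len(cfg$n_repeats - 1L), function(r) {
      sp <- fit_split(cfg$seed + r * 131L)
      yh <- labels$class[match(sp$holdout_ids, labels$gene_id)]
      vapply(classes, function(cl) {
        sc <- stats::predict(sp$forests[[cl]], fm[sp$holdout_ids, , drop = FALSE],
                             type = "prob")[, "in"]
        compute_roc(sc, yh == cl)$auc
      }, numeric(1))
    }, numeric(length(classes)))
    extra_auc <- cbind(auc, extra_auc)
  }

  vimp <- with_seed(cfg$seed + 7L, {
    stats::setNames(lapply(classes, function(cl) {
      permutation_vimp(split$forests[[cl]], fm[split$holdout_ids, , drop = FALSE],
                       yho == cl, n_repeats = vimp_repeats)
    }), classes)
  })

  structure(
    list(forests = split$forests, classes = classes, labels = labels,
         features = features, train_ids = split$train_ids,
         holdout_ids = split$holdout_ids, scores = scores, confusion = confusion,
         roc = roc, auc = auc, auc_repeats = extra_auc, vimp = vimp,
         cfg = cfg, mtry = mtry),
    class = "phase_forest"
  )
}

normalize_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  if (!"gene_id" %in% names(labels)) stop("labels need a `gene_id` column", call. = FALSE)
  cl <- if ("module_label" %in% names(labels)) as.character(labels$module_label)
        else if ("module" %in% names(labels)) {
          v <- labels$module
          if (is.numeric(v)) module_labels[v] else as.character(v)
        } else stop("labels need a `module` or `module_label` column", call. = FALSE)
  out <- tibble::tibble(gene_id = as.character(labels$gene_id), class = cl)
  out <- out[!is.na(out$class), , drop = FALSE]
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in labels", call. = FALSE)
  out
}

# Held-out permutation importance: mean decrease, over n_repeats permutations
# of each feature column, of the binary vote accuracy (vote fraction >= 0.5).
permutation_vimp <- function(forest, fm_holdout, is_class, n_repeats) {
  base_scores <- stats::predict(forest, fm_holdout, type = "prob")[, "in"]
  base_acc <- mean((base_scores >= 0.5) == is_class)
  features <- colnames(fm_holdout)
  drops <- vapply(features, function(f) {
    mean(vapply(seq_len(n_repeats), function(r) {
      perm <- fm_holdout
      perm[[f]] <- sample(perm[[f]])
      sc <- stats::predict(forest, perm, type = "prob")[, "in"]
      base_acc - mean((sc >= 0.5) == is_class)
    }, numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(motif = features, vimp = unname(drops))
  out[order(-out$vimp, out$motif), , drop = FALSE]
}

#' ROC curve and AUC from scores
#'
#' Threshold sweep over the score values: each point is the false-positive
#' and true-positive rate of calling scores at or above the threshold
#' positive. The curve starts at (0, 0), ends at (1, 1), and the AUC is the
#' trapezoid-rule area (equivalently the normalized Mann-Whitney U
#' statistic).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Logical vector of true positives.
#' @return A list with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
compute_roc <- function(scores, truth) {
  truth <- as.logical(truth)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need both positive and negative examples", call. = FALSE)
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & truth) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !truth) / n_neg, numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Per-class variable importance ranking
#'
#' Held-out permutation importance. With `grouped = TRUE` each feature is
#' permuted jointly with the features it correlates with (|r| at or above
#' `group_cor` across labelled genes, identical row shuffle for the whole
#' group): correlated motif features mask each other under single-feature
#' permutation — the forest leans on one member of a correlated pair and the
#' other scores near zero — so the grouped score is the one that reflects an
#' element family's real contribution.
#'
#' @param model A `phase_forest`.
#' @param class Class name (e.g. `"dawn"`).
#' @param grouped Use grouped (joint) permutation importance.
#' @param group_cor Correlation threshold defining a feature's group
#'   (default 0.3).
#' @param n_repeats Permutation repeats for the grouped score (default 10).
#' @return A tibble `motif`, `vimp` sorted by descending importance (ties
#'   broken lexicographically).
#' @export
variable_importance <- function(model, class, grouped = FALSE, group_cor = 0.3,
                                n_repeats = 10L) {
  stopifnot(inherits(model, "phase_forest"))
  if (!class %in% model$classes) {
    stop("unknown class '", class, "'; classes: ",
         paste(model$classes, collapse = ", "), call. = FALSE)
  }
  if (!grouped) return(model$vimp[[class]])
  fm <- as.data.frame(model$features[match(model$labels$gene_id,
                                           model$features$gene_id), -1L,
                                     drop = FALSE])
  rownames(fm) <- model$labels$gene_id
  cm <- suppressWarnings(stats::cor(as.matrix(fm)))
  cm[is.na(cm)] <- 0
  groups <- lapply(colnames(fm), function(f) {
    colnames(fm)[abs(cm[f, ]) >= group_cor]
  })
  names(groups) <- colnames(fm)
  fm_holdout <- fm[model$holdout_ids, , drop = FALSE]
  is_class <- model$labels$class[match(model$holdout_ids,
                                       model$labels$gene_id)] == class
  forest <- model$forests[[class]]
  base_scores <- stats::predict(forest, fm_holdout, type = "prob")[, "in"]
  base_acc <- mean((base_scores >= 0.5) == is_class)
  drops <- with_seed(model$cfg$seed + 13L, {
    vapply(colnames(fm_holdout), function(f) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- fm_holdout
        ord <- sample.int(nrow(perm))
        perm[groups[[f]]] <- perm[ord, groups[[f]], drop = FALSE]
        sc <- stats::predict(forest, perm, type = "prob")[, "in"]
        base_acc - mean((sc >= 0.5) == is_class)
      }, numeric(1)))
    }, numeric(1))
  })
  out <- tibble::tibble(motif = colnames(fm_holdout), vimp = unname(drops))
  out[order(-out$vimp, out$motif), , drop = FALSE]
}

#' Per-class ROC and AUC of a trained model
#'
#' @param model A `phase_forest`.
#' @return A tibble `class`, `threshold`, `fpr`, `tpr` with the per-class AUC
#'   in the `auc` attribute (also see [glance.phase_forest()]).
#' @export
roc_and_auc <- function(model) {
  stopifnot(inherits(model, "phase_forest"))
  out <- purrr::map_dfr(model$classes, function(cl) {
    dplyr::mutate(model$roc[[cl]]$points, class = cl, .before = 1L)
  })
  attr(out, "auc") <- model$auc
  out
}

#' Progressive presence/absence table of phase-classifying elements
#'
#' Marks a motif present for a phase class when it ranks in that class's
#' top-k by variable importance (or is explicitly requested through
#' `extra_motifs`) and shows a positive in-class association (its presence
#' rate inside the class exceeds the rate outside). Classes are emitted in
#' day order (dawn, noon, dusk, midnight) and double-plotted — each class row
#' appears twice — so the progressive cycling of element combinations reads
#' continuously across the day boundary.
#'
#' @param model A `phase_forest`.
#' @param top_k VIMP rank cutoff per class (default 10).
#' @param extra_motifs Motifs to include beyond the top-k (still subject to
#'   the positive-association and noise-floor checks).
#' @param noise_floor Minimum VIMP for an `extra_motifs` entry (default 0).
#' @param grouped Rank by grouped permutation importance (see
#'   [variable_importance()]); recommended when the feature set contains
#'   correlated element families.
#' @param importance Optional named list (class -> importance tibble) of
#'   precomputed rankings, e.g. from [variable_importance()]; skips
#'   recomputation.
#' @return A tibble with `phase` (8 rows, classes double-plotted) and one
#'   logical column per retained motif, ordered by first phase of presence.
#' @export
progressive_table <- function(model, top_k = 10L, extra_motifs = NULL,
                              noise_floor = 0, grouped = FALSE,
                              importance = NULL) {
  stopifnot(inherits(model, "phase_forest"))
  day_order <- intersect(c("dawn", "noon", "dusk", "midnight"), model$classes)
  if (length(day_order) == 0L) day_order <- model$classes
  fm <- model$features[match(model$labels$gene_id, model$features$gene_id), -1L,
                       drop = FALSE]
  present_for <- function(cl) {
    v <- if (!is.null(importance)) importance[[cl]]
         else variable_importance(model, cl, grouped = grouped)
    chosen <- utils::head(v$motif, min(top_k, nrow(v)))
    extras <- intersect(extra_motifs, v$motif[v$vimp > noise_floor])
    cand <- union(chosen, extras)
    inside <- model$labels$class == cl
    keep <- vapply(cand, function(mo) {
      mean(fm[[mo]][inside] > 0) > mean(fm[[mo]][!inside] > 0)
    }, logical(1))
    cand[keep]
  }
  sets <- stats::setNames(lapply(day_order, present_for), day_order)
  motifs <- unique(unlist(sets, use.names = FALSE))
  if (length(motifs) == 0L) {
    return(tibble::tibble(phase = rep(day_order, 2L)))
  }
  first_phase <- vapply(motifs, function(mo) {
    which(vapply(day_order, function(cl) mo %in% sets[[cl]], logical(1)))[1L]
  }, integer(1))
  motifs <- motifs[order(first_phase, motifs)]
  rows <- rep(day_order, 2L)  # double plot
  cols <- lapply(motifs, function(mo) vapply(rows, function(cl) mo %in% sets[[cl]],
                                             logical(1)))
  out <- tibble::as_tibble(stats::setNames(cols, motifs))
  dplyr::bind_cols(tibble::tibble(phase = rows), out)
}

#' Mean projection of genes carrying an element combination
#'
#' Averages the `(q1, q2)` projection coordinates over circadian genes whose
#' binary motif features contain every motif of the combination. When the
#' combination truly drives a phase, the mean vector points along that
#' phase's component axis.
#'
#' @param proj A `circadian_projection` with circadian calls.
#' @param features A `motif_feature_matrix`.
#' @param combination Character vector of motifs, all required.
#' @return A tibble with `q1`, `q2`, `n_genes`, `angle_rad`, `phase_h`.
#' @export
mean_phase_of_combination <- function(proj, features, combination) {
  stopifnot(inherits(proj, "circadian_projection"),
            inherits(features, "motif_feature_matrix"))
  if (length(combination) == 0L) stop("combination must be nonempty", call. = FALSE)
  missing <- setdiff(combination, names(features))
  if (length(missing)) {
    stop("motif(s) absent from the feature matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  circ <- proj[which(proj$is_circadian), , drop = FALSE]
  fm <- features[match(circ$gene_id, features$gene_id), , drop = FALSE]
  carries <- rep(TRUE, nrow(fm))
  for (mo in combination) carries <- carries & !is.na(fm[[mo]]) & fm[[mo]] > 0
  if (!any(carries)) {
    stop("no circadian gene carries the full combination", call. = FALSE)
  }
  q1 <- mean(circ$q1[carries]); q2 <- mean(circ$q2[carries])
  ang <- atan2(q2, q1)
  tibble::tibble(q1 = q1, q2 = q2, n_genes = sum(carries),
                 angle_rad = ang, phase_h = (ang %% (2 * pi)) / (2 * pi) * 24)
}

#' @export
print.phase_forest <- function(x, ...) {
  cat("<phase_forest> ", length(x$classes), " one-vs-rest forests (",
      x$cfg$n_trees, " trees, mtry ", x$mtry, ")\n", sep = "")
  cat("  holdout AUC: ",
      paste(sprintf("%s %.3f", x$classes, x$auc), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a phase forest: per-class VIMP rankings
#'
#' @param x A `phase_forest`.
#' @param ... Unused.
#' @return A tibble `class`, `motif`, `vimp`, `rank`.
#' @export
tidy.phase_forest <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    v <- x$vimp[[cl]]
    tibble::tibble(class = cl, motif = v$motif, vimp = v$vimp,
                   rank = seq_len(nrow(v)))
  })
}

#' Summarize a phase forest: per-class AUC
#'
#' @param x A `phase_forest`.
#' @param ... Unused.
#' @return A tibble `class`, `auc` (plus mean/sd over repeated splits when
#'   the config requested them), `n_train`, `n_holdout`.
#' @export
glance.phase_forest <- function(x, ...) {
  out <- tibble::tibble(class = x$classes, auc = unname(x$auc),
                        n_train = length(x$train_ids),
                        n_holdout = length(x$holdout_ids))
  if (!is.null(x$auc_repeats)) {
    out$auc_mean <- rowMeans(x$auc_repeats)
    out$auc_sd <- apply(x$auc_repeats, 1L, stats::sd)
  }
  out
}

#' ROC curves of a phase forest
#'
#' @param object A `phase_forest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_forest <- function(object, ...) {
  df <- roc_and_auc(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate") +
    ggplot2::theme_minimal()
}
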