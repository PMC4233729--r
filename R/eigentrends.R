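#' Extract averaged ICA eigentrends
#'
#' Runs FastICA `n_runs` times on a normalized expression matrix, aligns the
#' runs (components matched by maximal absolute correlation and sign-flipped),
#' averages them, renormalizes each averaged time profile to unit Euclidean
#' norm, and recomputes gene loadings as `X %*% t(S)`. Averaging across
#' restarts tames the run-to-run instability of FastICA's random
#' initialization. Components are ranked by the kurtosis of their gene-loading
#' distributions (see `order_by`).
#'
#' @param x A normalized `expression_matrix` (see [preprocess()]).
#' @param n_components Number of components to extract (at most the number of
#'   timepoints).
#' @param n_runs Number of independent FastICA restarts averaged (default 100).
#' @param seed Integer seed controlling all restarts.
#' @param order_by `"abs"` ranks components by descending absolute excess
#'   kurtosis of the loading distribution (non-Gaussianity as interestingness);
#'   `"ascending"` ranks most-negative kurtosis first, the ordering suited to
#'   broadly rhythmic data where circadian loadings are bimodal.
#' @param fun Contrast nonlinearity: `"kurtosis"` (classical pow3, the
#'   default, matching the kurtosis-as-interestingness framing) or
#'   `"logcosh"`.
#' @param average `"consensus"` (default) clusters restarts by frame
#'   similarity and averages the basin concordant with the variance
#'   structure; `"all"` is the straight aligned average of every restart,
#'   deliberately sensitive to restart instability (used by the empirical
#'   component-count test).
#' @param max_iter,tol FastICA iteration controls.
#'
#' @return An `eigentrend_decomposition`: list with `components` (d x m, unit
#'   rows), `loadings` (n x d), `kurtosis`, `order`, `method`, `n_runs`,
#'   `seed`.
#' @export
run_ica <- function(x, n_components, n_runs = 100L, seed = 1L,
                    order_by = c("abs", "ascending"),
                    fun = c("kurtosis", "logcosh"),
                    average = c("consensus", "all"),
                    max_iter = 1000L, tol = 1e-4) {
  order_by <- match.arg(order_by)
  fun <- match.arg(fun)
  average <- match.arg(average)
  check_normalized(x)
  m <- ncol(x$values)
  if (n_components < 1L || n_components > m) {
    stop("`n_components` must be between 1 and the number of timepoints (", m, ")",
         call. = FALSE)
  }
  s <- averaged_ica(x$values, n_components, n_runs, as.integer(seed),
                    max_iter = max_iter, tol = tol, fun = fun, average = average)
  new_decomposition(x, s, method = "ICA", n_runs = as.integer(n_runs),
                    seed = as.integer(seed), order_by = order_by)
}

#' Principal-component eigentrends
#'
#' The PCA counterpart of [run_ica()]: components are right singular vectors
#' of the normalized matrix, ordered by explained variance, with
#' explained-variance fractions recorded. Loading kurtosis is computed for
#' comparison with the ICA ordering.
#'
#' @inheritParams run_ica
#' @return An `eigentrend_decomposition` with `method = "PCA"` and an
#'   `explained_variance` field.
#' @export
run_pca <- function(x, n_components) {
  check_normalized(x)
  m <- ncol(x$values)
  if (n_components < 1L || n_components > m) {
    stop("`n_components` must be between 1 and the number of timepoints (", m, ")",
         call. = FALSE)
  }
  sv <- svd(x$values)
  s <- t(sv$v[, seq_len(n_components), drop = FALSE])
  dec <- new_decomposition(x, s, method = "PCA", n_runs = 1L, seed = NA_integer_,
                           order_by = "variance")
  dec$order <- seq_len(n_components)  # PCA keeps its own variance ordering
  dec$explained_variance <- sv$d[seq_len(n_components)]^2 / sum(sv$d^2)
  dec
}

new_decomposition <- function(x, s, method, n_runs, seed, order_by) {
  loadings <- x$values %*% t(s)
  kur <- apply(loadings, 2L, excess_kurtosis)
  ord <- switch(order_by,
    abs = order(-abs(kur)),
    ascending = order(kur),
    variance = order(-colMeans(loadings^2))
  )
  structure(
    list(components = s, loadings = loadings, kurtosis = kur, order = ord,
         method = method, n_runs = n_runs, seed = seed,
         time_hours = x$time_hours, gene_ids = x$gene_ids),
    class = "eigentrend_decomposition"
  )
}

excess_kurtosis <- function(v) {
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 == 0) stop("zero variance of projections", call. = FALSE)
  mean((v - mu)^4) / m2^2 - 3
}

#' Excess kurtosis of gene projections along a component
#'
#' Projects every gene profile onto a unit-norm component and returns the
#' excess kurtosis (fourth central moment over squared variance, minus 3,
#' population moments) of the projection distribution. Strongly bimodal
#' loading distributions (many genes positively or negatively correlated with
#' the trend) give negative values; sparse heavy-tailed ones give positive
#' values.
#'
#' @param x An `expression_matrix`.
#' @param component Numeric vector of length `ncol(x)`, unit Euclidean norm.
#' @return A single number.
#' @export
projection_kurtosis <- function(x, component) {
  stopifnot(inherits(x, "expression_matrix"))
  component <- as.numeric(component)
  if (length(component) != ncol(x$values)) {
    stop("`component` must have one value per timepoint", call. = FALSE)
  }
  if (abs(sum(component^2) - 1) > 1e-6) {
    stop("`component` must have unit Euclidean norm", call. = FALSE)
  }
  excess_kurtosis(as.vector(x$values %*% component))
}

#' Pick the two circadian components
#'
#' Regresses each component's time profile on a free-phase cosine of the given
#' period (cos + sin + intercept) and returns the indices of the two
#' components with the highest R-squared. Intended to identify the sine/cosine
#' pair of circadian eigentrends after kurtosis ordering.
#'
#' @param dec An `eigentrend_decomposition`.
#' @param period_h Oscillation period in hours (default 24).
#' @param r2_floor Minimum R-squared for a component to count as circadian
#'   (default 0.5).
#' @param override Optional integer pair; returned unconditionally, bypassing
#'   the fit (manual selection).
#' @return Integer vector of length 2 (component indices into `dec`).
#' @export
select_circadian_components <- function(dec, period_h = 24, r2_floor = 0.5,
                                        override = NULL) {
  stopifnot(inherits(dec, "eigentrend_decomposition"))
  if (!is.null(override)) {
    override <- as.integer(override)
    stopifnot(length(override) == 2L)
    return(override)
  }
  d <- nrow(dec$components)
  if (d < 2L) stop("need at least two components", call. = FALSE)
  r2 <- cosine_r2(dec$components, dec$time_hours, period_h)
  ok <- which(r2 >= r2_floor)
  if (length(ok) < 2L) {
    stop("fewer than two components fit a ", period_h, " h cosine with R^2 >= ",
         r2_floor, "; inspect the decomposition and pass `override`", call. = FALSE)
  }
  ok[order(-r2[ok])][1:2]
}

#' Orient the two circadian components as canonical phase axes
#'
#' Fits each selected component with a free-phase cosine, estimates its peak
#' (acrophase) in hours, and returns the pair ordered and sign-flipped so the
#' first axis peaks near `noon_peak` (mid-day, the `+q1` module axis) and the
#' second near `dawn_peak` (the `+q2` axis). This fixes the rotation/sign
#' convention left free by ICA so module labels are comparable across runs.
#'
#' @param dec An `eigentrend_decomposition`.
#' @param indices Integer pair of component indices (e.g. from
#'   [select_circadian_components()]).
#' @param period_h Period in hours (default 24).
#' @param dawn_peak,noon_peak Anchors of the two axes in hours.
#' @return A list with unit vectors `v1` (noon axis) and `v2` (dawn axis).
#' @export
orient_axes <- function(dec, indices, period_h = 24, dawn_peak = 0, noon_peak = 6) {
  stopifnot(inherits(dec, "eigentrend_decomposition"), length(indices) == 2L)
  w <- 2 * pi * dec$time_hours / period_h
  basis <- cbind(cos(w), sin(w))
  peak_of <- function(v) {
    b <- stats::lm.fit(cbind(1, basis), v)$coefficients[-1L]
    (atan2(b[2L], b[1L]) %% (2 * pi)) / (2 * pi) * period_h
  }
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% period_h
    pmin(d, period_h - d)
  }
  comps <- dec$components[indices, , drop = FALSE]
  peaks <- apply(comps, 1L, peak_of)
  # candidate orientations: each component, possibly sign-flipped, peaks at
  # its fitted hour or 12 h opposite
  orient_to <- function(v, peak, target) {
    if (circ_dist(peak, target) <= circ_dist((peak + period_h / 2) %% period_h, target)) v
    else -v
  }
  # choose the assignment (which component is the noon axis) minimizing the
  # total circular mismatch
  mis <- function(i, j) {
    min(circ_dist(peaks[i], noon_peak),
        circ_dist((peaks[i] + 12) %% period_h, noon_peak)) +
      min(circ_dist(peaks[j], dawn_peak),
          circ_dist((peaks[j] + 12) %% period_h, dawn_peak))
  }
  if (mis(1L, 2L) <= mis(2L, 1L)) {
    list(v1 = orient_to(comps[1L, ], peaks[1L], noon_peak),
         v2 = orient_to(comps[2L, ], peaks[2L], dawn_peak))
  } else {
    list(v1 = orient_to(comps[2L, ], peaks[2L], noon_peak),
         v2 = orient_to(comps[1L, ], peaks[1L], dawn_peak))
  }
}

cosine_r2 <- function(components, time_hours, period_h) {
  w <- 2 * pi * time_hours / period_h
  basis <- cbind(1, cos(w), sin(w))
  apply(components, 1L, function(p) {
    fit <- stats::lm.fit(basis, p)
    1 - sum(fit$residuals^2) / sum((p - mean(p))^2)
  })
}

check_normalized <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$normalized) {
    stop("expression matrix must be normalized; run preprocess() first", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.eigentrend_decomposition <- function(x, ...) {
  cat("<eigentrend_decomposition> ", x$method, ", ", nrow(x$components),
      " components, ", length(x$gene_ids), " genes\n", sep = "")
  cat("  kurtosis (ranked): ",
      paste(sprintf("%.2f", x$kurtosis[x$order]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an eigentrend decomposition
#'
#' @param x An `eigentrend_decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per component per timepoint: `component`
#'   (index in the original extraction), `rank` (kurtosis rank), `kurtosis`,
#'   `time_hours`, `value`, plus `r2_24h` from a free-phase 24 h cosine fit.
#' @export
tidy.eigentrend_decomposition <- function(x, ...) {
  d <- nrow(x$components)
  m <- length(x$time_hours)
  r2 <- cosine_r2(x$components, x$time_hours, 24)
  tibble::tibble(
    component = rep(seq_len(d), each = m),
    rank = rep(match(seq_len(d), x$order), each = m),
    kurtosis = rep(x$kurtosis, each = m),
    r2_24h = rep(r2, each = m),
    time_hours = rep(x$time_hours, times = d),
    value = as.vector(t(x$components))
  )
}

#' One-line summary of a decomposition
#'
#' @param x An `eigentrend_decomposition`.
#' @param ... Unused.
#' @return A one-row tibble: method, number of components, runs, seed, and the
#'   kurtosis range.
#' @export
glance.eigentrend_decomposition <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_components = nrow(x$components),
    n_genes = length(x$gene_ids),
    n_runs = x$n_runs,
    seed = x$seed,
    min_kurtosis = min(x$kurtosis),
    max_kurtosis = max(x$kurtosis)
  )
}

#' Plot eigentrend time profiles
#'
#' @param object An `eigentrend_decomposition`.
#' @param components Which components to draw (default: all, in kurtosis rank
#'   order).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eigentrend_decomposition <- function(object, components = NULL, ...) {
  df <- tidy(object)
  if (!is.null(components)) df <- dplyr::filter(df, .data$component %in% components)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_hours, .data$value,
                                   colour = factor(.data$rank))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time since subjective dawn (h)", y = "component profile",
                  colour = "kurtosis rank") +
    ggplot2::theme_minimal()
}
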