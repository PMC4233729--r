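#' Project genes onto the two circadian eigentrends
#'
#' Rescales every gene profile to unit Euclidean norm and takes dot products
#' with the two unit-norm component profiles, giving per-gene coordinates
#' `(q1, q2)`, a radius, a projection angle and a phase in hours. With
#' orthonormal components the radius is bounded by 1 and acts as a
#' correlation-like measure of cyclicity, so the conventional 0.8 cutoff is
#' meaningful.
#'
#' @param x A normalized `expression_matrix`.
#' @param v1,v2 Unit-norm component profiles (length = number of timepoints).
#'   `v1` anchors phase 0; angles are measured towards `v2`.
#' @return A `circadian_projection`: a tibble with columns `gene_id`, `q1`,
#'   `q2`, `radius`, `angle_rad` in (-pi, pi], `phase_h` in [0, 24),
#'   `is_circadian` (NA until [classify_circadian()]), `module` (NA until
#'   [assign_modules()]).
#' @export
project_genes <- function(x, v1, v2) {
  check_normalized(x)
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  m <- ncol(x$values)
  if (length(v1) != m || length(v2) != m) {
    stop("components must have one value per timepoint", call. = FALSE)
  }
  if (abs(sum(v1^2) - 1) > 1e-6 || abs(sum(v2^2) - 1) > 1e-6) {
    stop("components must have unit Euclidean norm", call. = FALSE)
  }
  if (abs(sum(v1 * v2)) >= 0.05) {
    warning("components are not near-orthogonal (|v1.v2| = ",
            sprintf("%.3f", abs(sum(v1 * v2))), "); radii may exceed 1")
  }
  norms <- sqrt(rowSums(x$values^2))
  if (any(norms == 0)) {
    stop("zero-norm gene profile(s): ",
         paste(utils::head(x$gene_ids[norms == 0], 5L), collapse = ", "), call. = FALSE)
  }
  unit <- x$values / norms
  q1 <- as.vector(unit %*% v1)
  q2 <- as.vector(unit %*% v2)
  angle <- atan2(q2, q1)
  out <- tibble::tibble(
    gene_id = x$gene_ids,
    q1 = q1, q2 = q2,
    radius = sqrt(q1^2 + q2^2),
    angle_rad = angle,
    phase_h = (angle %% (2 * pi)) / (2 * pi) * 24,
    is_circadian = NA,
    module = NA_integer_
  )
  class(out) <- c("circadian_projection", class(out))
  out
}

#' Call circadian genes by radial cutoff
#'
#' A gene is circadian when its projection radius reaches the cutoff
#' (boundary inclusive). The stringent default of 0.8 mirrors the cutoff
#' conventionally applied to Pearson correlation screens.
#'
#' @param proj A `circadian_projection` from [project_genes()].
#' @param cutoff Radial cutoff in (0, 1] (default 0.8).
#' @return The projection with `is_circadian` filled; non-circadian genes get
#'   `module = NA`.
#' @export
classify_circadian <- function(proj, cutoff = 0.8) {
  stopifnot(inherits(proj, "circadian_projection"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  proj$is_circadian <- proj$radius >= cutoff
  proj$module[!proj$is_circadian] <- NA_integer_
  message(sum(proj$is_circadian), " of ", nrow(proj),
          " genes called circadian at radius >= ", cutoff)
  proj
}

# module labels in class order 1..4 (1 dawn, 2 dusk, 3 noon, 4 midnight)
module_labels <- c("dawn", "dusk", "noon", "midnight")

#' Assign the four phase modules
#'
#' Each circadian gene joins the module of the signed component axis with the
#' largest dot product: `+q1` is class 3 (mid-day), `-q1` class 4 (midnight),
#' `+q2` class 1 (subjective dawn), `-q2` class 2 (subjective dusk). Ties are
#' broken by the fixed precedence `+q1, -q1, +q2, -q2`.
#'
#' @param proj A `circadian_projection` with `is_circadian` set.
#' @return The projection with `module` (1-4) and `module_label` filled for
#'   circadian genes.
#' @export
assign_modules <- function(proj) {
  stopifnot(inherits(proj, "circadian_projection"))
  if (anyNA(proj$is_circadian)) {
    stop("run classify_circadian() before assign_modules()", call. = FALSE)
  }
  scores <- cbind(proj$q1, -proj$q1, proj$q2, -proj$q2)  # precedence order
  module_for <- c(3L, 4L, 1L, 2L)
  pick <- module_for[max.col(scores, ties.method = "first")]
  proj$module <- ifelse(proj$is_circadian, pick, NA_integer_)
  proj$module_label <- factor(module_labels[proj$module], levels = module_labels)
  proj
}

#' Order circadian genes by projection angle
#'
#' Sorts circadian genes by their angular position, the ordering used for the
#' circular heat-map export: phase runs continuously around the projection
#' plane, so angular order is phase order.
#'
#' @param proj A `circadian_projection`.
#' @return A tibble of circadian genes sorted by `angle_rad` ascending.
#' @export
circular_order <- function(proj) {
  stopifnot(inherits(proj, "circadian_projection"))
  out <- proj[which(proj$is_circadian), , drop = FALSE]
  out <- out[order(out$angle_rad), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Projection scatter plot
#'
#' The classic projection scatter: genes in the plane of the two circadian
#' eigentrends, the radial cutoff circle, circadian genes coloured by module.
#'
#' @param object A `circadian_projection`.
#' @param cutoff Cutoff circle to draw (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circadian_projection <- function(object, cutoff = 0.8, ...) {
  df <- tibble::as_tibble(object)
  df$group <- if (all(is.na(df$module))) {
    factor(ifelse(is.na(df$is_circadian) | !df$is_circadian, "background", "circadian"))
  } else {
    factor(ifelse(is.na(df$module), "background", module_labels[df$module]),
           levels = c(module_labels, "background"))
  }
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(df, ggplot2::aes(.data$q1, .data$q2, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(cutoff * cos(.data$theta), cutoff * sin(.data$theta)),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "q1 (component 1)", y = "q2 (component 2)", colour = NULL) +
    ggplot2::theme_minimal()
}
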