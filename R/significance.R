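#' Reconstruction error of a d-component eigentrend model
#'
#' Fits a d-component averaged ICA decomposition (see [run_ica()]) and returns
#' the Frobenius distance between the data and the reconstruction `A %*% S`,
#' where `S` holds the unit-normalized averaged component profiles and
#' `A = X %*% t(S)` the recomputed loadings. Because the averaged profiles are
#' not exactly orthogonal, the reconstruction honestly inherits any
#' run-to-run instability of the decomposition: unstable components inflate
#' the error, which is what the empirical component-count test exploits.
#'
#' @param x A normalized `expression_matrix`.
#' @param d Number of components, `0 <= d <= m`. `d = 0` returns `||X||_F`.
#' @param seed Seed passed to the ICA restarts.
#' @param n_runs FastICA restarts averaged per fit (default 10; raise towards
#'   100 for final analyses, lower only for quick looks).
#' @param average Restart-averaging mode passed to [run_ica()]; the default
#'   `"all"` (straight aligned average) is what the empirical test relies on.
#' @return The reconstruction error (a single non-negative number).
#' @export
reconstruction_error <- function(x, d, seed = 1L, n_runs = 10L,
                                 average = c("all", "consensus")) {
  average <- match.arg(average)
  check_normalized(x)
  if (d < 0L || d > ncol(x$values)) {
    stop("`d` must be between 0 and the number of timepoints", call. = FALSE)
  }
  if (d == 0L) return(sqrt(sum(x$values^2)))
  dec <- run_ica(x, n_components = d, n_runs = n_runs, seed = seed,
                 average = average)
  sqrt(sum((x$values - dec$loadings %*% dec$components)^2))
}

#' Randomize an expression matrix
#'
#' Two null-generating schemes: `row_permute` shuffles the values within every
#' gene profile independently (destroying all between-gene covariation while
#' keeping each gene's value multiset); `swap_discretized` discretizes the
#' matrix into equal-frequency bins and applies checkerboard swap moves that
#' preserve every row's and every column's bin-count histogram, carrying the
#' undiscretized values with their bins.
#'
#' @param x A normalized `expression_matrix`.
#' @param method `"row_permute"` (default) or `"swap_discretized"`.
#' @param seed Integer seed.
#' @param n_bins Bins for `swap_discretized` (default 10).
#' @param n_swaps Attempted swap moves (default `10 * n * m`).
#' @return An `expression_matrix` (flagged non-normalized: the randomized
#'   rows keep their value multisets, so row moments survive `row_permute`
#'   but the object is treated as raw data downstream).
#' @export
randomize_matrix <- function(x, method = c("row_permute", "swap_discretized"),
                             seed = 1L, n_bins = 10L, n_swaps = NULL) {
  method <- match.arg(method)
  check_normalized(x)
  v <- x$values
  n <- nrow(v); m <- ncol(v)
  out <- with_seed(as.integer(seed), {
    if (method == "row_permute") {
      t(apply(v, 1L, sample))
    } else {
      swap_discretized(v, n_bins = n_bins,
                       n_swaps = if (is.null(n_swaps)) 10L * n * m else n_swaps)
    }
  })
  y <- expression_matrix(out, x$gene_ids, x$time_hours, normalized = FALSE)
  attr(y, "randomized") <- method
  y
}

# Checkerboard swaps on the bin-discretized matrix: choose rows r1 != r2 and
# columns c1 != c2 with bin(r1,c1) == bin(r2,c2), bin(r1,c2) == bin(r2,c1) and
# the two bins distinct, then swap within each row across the two columns.
# Row and column bin-count histograms are invariant under this move.
swap_discretized <- function(v, n_bins, n_swaps) {
  n <- nrow(v); m <- ncol(v)
  q <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1L))
  q[1L] <- -Inf; q[n_bins + 1L] <- Inf
  b <- array(findInterval(v, q, rightmost.closed = TRUE), dim = dim(v))
  r1 <- sample.int(n, n_swaps, replace = TRUE)
  r2 <- sample.int(n, n_swaps, replace = TRUE)
  c1 <- sample.int(m, n_swaps, replace = TRUE)
  c2 <- sample.int(m, n_swaps, replace = TRUE)
  for (s in seq_len(n_swaps)) {
    i <- r1[s]; j <- r2[s]; a <- c1[s]; z <- c2[s]
    if (i == j || a == z) next
    if (b[i, a] == b[j, z] && b[i, z] == b[j, a] && b[i, a] != b[i, z]) {
      tmp <- v[i, a]; v[i, a] <- v[i, z]; v[i, z] <- tmp
      tmp <- v[j, a]; v[j, a] <- v[j, z]; v[j, z] <- tmp
      tmp <- b[i, a]; b[i, a] <- b[i, z]; b[i, z] <- tmp
      tmp <- b[j, a]; b[j, a] <- b[j, z]; b[j, z] <- tmp
    }
  }
  v
}

#' Empirical significance test for the number of components
#'
#' Compares the observed d-component reconstruction error (r.e.) with the
#' errors of randomized matrices (r.r.e.): the empirical p-value is the
#' frequency with which randomized errors fall below the observed one. A
#' small p-value says the d-component model describes the real data better
#' than it describes data with the same margins but no between-gene structure.
#'
#' @inheritParams reconstruction_error
#' @param n_randomizations Number of randomized matrices (default 1000).
#' @param method Randomizer passed to [randomize_matrix()].
#' @param add_one Apply the (k+1)/(N+1) correction instead of the plain
#'   frequency (default `FALSE`, matching the plain-frequency definition; the
#'   corrected version never returns exactly 0).
#' @return A `component_count_test`: list with `d`, `observed_error`,
#'   `randomized_errors`, `p_value`, `n_randomizations`, `randomizer`.
#' @export
empirical_component_test <- function(x, d, n_randomizations = 1000L,
                                     method = c("row_permute", "swap_discretized"),
                                     seed = 1L, n_runs = 10L, add_one = FALSE) {
  method <- match.arg(method)
  if (n_randomizations < 1L) stop("`n_randomizations` must be >= 1", call. = FALSE)
  re <- reconstruction_error(x, d, seed = seed, n_runs = n_runs)
  sub_seeds <- with_seed(as.integer(seed) + 1L,
                         sample.int(.Machine$integer.max - 1L, n_randomizations))
  rre <- vapply(seq_len(n_randomizations), function(i) {
    r <- randomize_matrix(x, method = method, seed = sub_seeds[i])
    # randomized rows keep mean 0 / unit SD under row_permute; swap moves
    # perturb row moments only at bin resolution -- treat as normalized
    r$normalized <- TRUE
    reconstruction_error(r, d, seed = sub_seeds[i] %% 1000000L, n_runs = n_runs)
  }, numeric(1))
  k <- sum(rre < re)
  p <- if (add_one) (k + 1) / (n_randomizations + 1) else k / n_randomizations
  structure(
    list(d = as.integer(d), observed_error = re, randomized_errors = rre,
         p_value = p, n_randomizations = as.integer(n_randomizations),
         randomizer = method),
    class = "component_count_test"
  )
}

#' @export
print.component_count_test <- function(x, ...) {
  cat("<component_count_test> d = ", x$d, ", randomizer = ", x$randomizer, "\n",
      "  r.e. = ", sprintf("%.4f", x$observed_error),
      ", r.r.e. mean = ", sprintf("%.4f", mean(x$randomized_errors)),
      ", p = ", format(x$p_value), " (", x$n_randomizations, " randomizations)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.component_count_test <- function(x, ...) {
  tibble::tibble(randomization = seq_along(x$randomized_errors),
                 randomized_error = x$randomized_errors)
}

#' @export
glance.component_count_test <- function(x, ...) {
  tibble::tibble(d = x$d, observed_error = x$observed_error,
                 null_mean = mean(x$randomized_errors),
                 null_sd = stats::sd(x$randomized_errors),
                 p_value = x$p_value,
                 n_randomizations = x$n_randomizations,
                 randomizer = x$randomizer)
}

#' Plot the randomized-error distribution against the observed error
#'
#' @param object A `component_count_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_count_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$randomized_error)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_error, colour = "red") +
    ggplot2::labs(x = "reconstruction error (randomized)", y = "count",
                  title = paste0("d = ", object$d, ", p = ", format(object$p_value))) +
    ggplot2::theme_minimal()
}
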