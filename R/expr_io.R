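#' Construct an expression matrix container
#'
#' Bundles a genes-by-timepoints numeric matrix with gene identifiers and
#' sampling times. This is the input container for the whole eigentrend
#' pipeline; most users will obtain one from [read_expression_table()] or
#' [simulate_expression()] rather than calling this directly.
#'
#' @param values Numeric matrix, genes in rows, timepoints in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param time_hours Numeric vector of sampling times in hours since
#'   subjective dawn, one per column.
#' @param normalized Logical; `TRUE` only when rows are centred to mean 0 and
#'   scaled to unit (population) standard deviation, as [preprocess()] leaves
#'   them.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids, time_hours, normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix", call. = FALSE)
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("an expression matrix needs at least 2 genes", call. = FALSE)
  if (m < 3L) stop("an expression matrix needs at least 3 timepoints", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n) {
    stop("`gene_ids` length (", length(gene_ids), ") does not match row count (", n, ")",
         call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene ids: ", paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  time_hours <- as.numeric(time_hours)
  if (length(time_hours) != m) {
    stop("`time_hours` length (", length(time_hours), ") does not match column count (", m, ")",
         call. = FALSE)
  }
  if (anyNA(values)) stop("`values` contains missing values", call. = FALSE)
  dimnames(values) <- list(gene_ids, format_hours(time_hours))
  if (isTRUE(normalized)) {
    mu <- rowMeans(values)
    sdv <- row_pop_sd(values)
    if (max(abs(mu)) > 1e-9 || max(abs(sdv - 1)) > 1e-9) {
      stop("`normalized = TRUE` but rows are not mean-0 / unit-SD", call. = FALSE)
    }
  }
  structure(
    list(values = values, gene_ids = gene_ids, time_hours = time_hours,
         normalized = isTRUE(normalized)),
    class = "expression_matrix"
  )
}

format_hours <- function(h) paste0("t", sub("\\.?0+$", "", formatC(h, format = "f", digits = 3)))

# population moments: divide by the count, not count - 1
row_pop_sd <- function(x) sqrt(rowMeans((x - rowMeans(x))^2))
col_pop_sd <- function(x) sqrt(colMeans(sweep(x, 2L, colMeans(x))^2))

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values), " timepoints",
      if (x$normalized) " (normalized)" else "", "\n", sep = "")
  cat("  time (h): ", paste(x$time_hours, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Tidy an expression matrix into long format
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `time_hours`, `value`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = length(x$time_hours)),
    time_hours = rep(x$time_hours, each = length(x$gene_ids)),
    value = as.vector(x$values)
  )
}

#' Read a genes-by-timepoints expression table
#'
#' Expects a tab-separated file whose header row carries time labels (hours,
#' parseable as numbers, with or without a leading "t"), whose first column
#' holds gene identifiers, and whose body is numeric. No transformation is
#' applied on read; run [preprocess()] afterwards.
#'
#' @param path Path to the TSV file.
#' @param log_transformed Logical flag recording whether the stored values are
#'   already on a log2 scale (controls the default of `apply_log2` downstream);
#'   purely declarative, nothing is transformed here.
#'
#' @return An [expression_matrix()] with `normalized = FALSE`.
#' @export
read_expression_table <- function(path, log_transformed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )  # cell-level validation below reports problems with row/column context
  if (ncol(raw) < 4L) stop("expected a gene id column plus at least 3 timepoints", call. = FALSE)
  header <- names(raw)[-1L]
  times <- suppressWarnings(as.numeric(sub("^[tT]", "", header)))
  if (anyNA(times)) {
    stop("time labels not parseable as hours: ",
         paste(header[is.na(times)], collapse = ", "), call. = FALSE)
  }
  gene_ids <- raw[[1L]]
  body <- as.matrix(raw[-1L])
  if (anyNA(body)) {
    idx <- which(is.na(body), arr.ind = TRUE)[1L, ]
    stop("ragged row: gene '", gene_ids[idx[["row"]]], "' is missing a value in column '",
         header[idx[["col"]]], "'", call. = FALSE)
  }
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", body[idx[1L], idx[2L]], "' for gene '", gene_ids[idx[1L]],
         "' in column '", header[idx[2L]], "'", call. = FALSE)
  }
  x <- expression_matrix(num, gene_ids, times, normalized = FALSE)
  attr(x, "log_transformed") <- isTRUE(log_transformed)
  x
}

#' Write an expression matrix as TSV
#'
#' Emits the same dialect [read_expression_table()] consumes: a `gene_id`
#' column followed by one column per timepoint labelled `t<hours>`.
#'
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- tibble::as_tibble(as.data.frame(x$values))
  names(df) <- format_hours(x$time_hours)
  df <- dplyr::bind_cols(tibble::tibble(gene_id = x$gene_ids), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Pre-process an expression matrix for eigentrend extraction
#'
#' Applies, in this order: optional log2 transform, column centring, column
#' scaling to unit population SD, row centring, row scaling to unit population
#' SD. The result has every gene profile at mean 0 and unit standard
#' deviation, the form the ICA/PCA decompositions and the projection geometry
#' assume.
#'
#' @param x An `expression_matrix`.
#' @param apply_log2 Take log2 of the values first (requires all values
#'   positive unless `pseudocount` is set).
#' @param pseudocount Added before the log2 transform (default 0; the package
#'   adds nothing silently).
#'
#' @return A normalized `expression_matrix`.
#' @export
preprocess <- function(x, apply_log2 = FALSE, pseudocount = 0) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (apply_log2) {
    v <- v + pseudocount
    if (any(v <= 0)) {
      bad <- unique(x$gene_ids[which(v <= 0, arr.ind = TRUE)[, 1L]])
      stop("log2 requested but non-positive values present (genes: ",
           paste(utils::head(bad, 5L), collapse = ", "), "); consider `pseudocount`",
           call. = FALSE)
    }
    v <- log2(v)
  }
  rsd0 <- row_pop_sd(v)
  if (any(rsd0 == 0)) {
    stop("constant gene profile(s): ",
         paste(utils::head(x$gene_ids[rsd0 == 0], 5L), collapse = ", "), call. = FALSE)
  }
  csd <- col_pop_sd(v)
  if (any(csd == 0)) {
    stop("constant column(s) at t = ",
         paste(x$time_hours[csd == 0], collapse = ", "), call. = FALSE)
  }
  v <- sweep(v, 2L, colMeans(v))
  v <- sweep(v, 2L, col_pop_sd(v), "/")
  rsd <- row_pop_sd(v)
  if (any(rsd == 0)) {
    stop("constant gene profile(s) after column normalization: ",
         paste(utils::head(x$gene_ids[rsd == 0], 5L), collapse = ", "), call. = FALSE)
  }
  v <- v - rowMeans(v)
  v <- v / row_pop_sd(v)
  expression_matrix(v, x$gene_ids, x$time_hours, normalized = TRUE)
}
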