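#' Read promoter sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased; the alphabet is restricted to A, C, G, T, N.
#' Lengths other than the conventional 1 kb upstream window are reported as a
#' warning, not an error.
#'
#' @param path FASTA file path.
#' @param expected_length Expected promoter length (default 1000; `NULL`
#'   disables the length check).
#' @return A named [Biostrings::DNAStringSet] keyed by gene id.
#' @export
read_promoter_fasta <- function(path, expected_length = 1000L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate record ids: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- ids
  chars <- as.character(seqs)
  chars <- toupper(chars)
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("illegal characters (outside ACGTN) in record(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(expected_length)) {
    off <- nchar(chars) != expected_length
    if (any(off)) {
      warning(sum(off), " sequence(s) deviate from the expected ", expected_length,
              " bp (e.g. ", utils::head(ids[off], 1L), ": ",
              utils::head(nchar(chars)[off], 1L), " bp)")
    }
  }
  Biostrings::DNAStringSet(stats::setNames(chars, ids))
}

#' Write promoters as FASTA
#'
#' @param promoters A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  if (!methods::is(promoters, "DNAStringSet")) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

check_motif <- function(motif) {
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 5L || nchar(motif) > 8L) {
    stop("motif '", motif, "' outside the 5-8 bp range", call. = FALSE)
  }
  if (grepl("[^ACGT]", motif)) {
    stop("motif '", motif, "' contains characters outside ACGT", call. = FALSE)
  }
  motif
}

#' Count overlapping motif occurrences on one strand
#'
#' Exact matching of a 5-8 bp ACGT motif against the given strand, counting
#' overlapping occurrences; windows containing N never match. Promoters are
#' taken as already oriented, so only the given strand is scanned unless
#' `both_strands = TRUE` adds the reverse complement.
#'
#' @param sequence A DNA string (character or `DNAString`).
#' @param motif Motif of length 5-8 over ACGT.
#' @param both_strands Also count the reverse-complement motif.
#' @return Integer count.
#' @export
count_motif <- function(sequence, motif, both_strands = FALSE) {
  motif <- check_motif(motif)
  subj <- if (methods::is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  n <- Biostrings::countPattern(motif, subj, fixed = TRUE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (rc != motif) n <- n + Biostrings::countPattern(rc, subj, fixed = TRUE)
  }
  as.integer(n)
}

# Presence counts (number of sequences containing each k-mer at least once)
# for all k-mers of one width, computed in chunks to bound memory.
presence_counts_k <- function(seqs, k, chunk = 200L) {
  total <- NULL
  idx <- split(seq_along(seqs), ceiling(seq_along(seqs) / chunk))
  for (i in idx) {
    f <- Biostrings::oligonucleotideFrequency(seqs[i], width = k)
    p <- colSums(f > 0L)
    total <- if (is.null(total)) p else total + p
  }
  total
}

#' Rank k-mer motifs by over-representation in target promoters
#'
#' Enumerates every 5-8 bp motif, counts in how many target and background
#' promoters it occurs at least once, scores one-sided hypergeometric
#' enrichment of presence in the target set, and returns the `top_n` motifs
#' ranked by score (ties broken lexicographically). This is the screen whose
#' leaders feed the combinatorial random-forest analysis.
#'
#' @param target Promoters of the gene set of interest (`DNAStringSet`).
#' @param background Promoters of the comparison set.
#' @param k_min,k_max Motif length range (defaults 5 and 8).
#' @param top_n Number of motifs to return (default 21).
#' @param distinct When `TRUE`, walk the ranked list greedily and drop any
#'   motif sharing a common subword of 4 bp or more with an already-kept one,
#'   so the returned set keeps one non-redundant representative per motif
#'   family. Overlapping k-mers of one element otherwise crowd the list and
#'   split downstream importance across near-duplicate features.
#' @return A tibble `motif`, `k`, `target_hits`, `background_hits`,
#'   `p_value`, `rank`, sorted by rank.
#' @export
enrichment_rank <- function(target, background, k_min = 5L, k_max = 8L, top_n = 21L,
                            distinct = FALSE) {
  if (length(target) == 0L || length(background) == 0L) {
    stop("target and background must be nonempty", call. = FALSE)
  }
  if (top_n == 0L) {
    return(tibble::tibble(motif = character(), k = integer(), target_hits = integer(),
                          background_hits = integer(), p_value = numeric(),
                          rank = integer()))
  }
  overlap <- intersect(names(target), names(background))
  if (length(overlap)) {
    warning("target and background share ", length(overlap),
            " promoter(s); enrichment scores will be conservative")
  }
  nt <- length(target); nb <- length(background)
  res <- purrr::map_dfr(seq.int(k_min, k_max), function(k) {
    th <- presence_counts_k(target, k)
    bh <- presence_counts_k(background, k)
    keep <- th > 0L
    tibble::tibble(motif = names(th)[keep], k = k,
                   target_hits = unname(th[keep]),
                   background_hits = unname(bh[names(th)[keep]]))
  })
  if (top_n > nrow(res)) {
    stop("top_n (", top_n, ") exceeds the number of distinct motifs present (",
         nrow(res), ")", call. = FALSE)
  }
  # one-sided hypergeometric: P(target presence >= observed) drawing nt
  # promoters from the pooled collection
  res$p_value <- stats::phyper(res$target_hits - 1L,
                               res$target_hits + res$background_hits,
                               nt + nb - res$target_hits - res$background_hits,
                               nt, lower.tail = FALSE)
  res <- res[order(res$p_value, res$motif), , drop = FALSE]
  if (distinct) {
    subwords <- function(m, k = 4L) {
      if (nchar(m) < k) return(m)
      vapply(seq_len(nchar(m) - k + 1L), function(i) substr(m, i, i + k - 1L),
             character(1))
    }
    keep <- logical(nrow(res))
    seen <- character()
    for (i in seq_len(nrow(res))) {
      sw <- subwords(res$motif[i])
      if (!any(sw %in% seen)) { keep[i] <- TRUE; seen <- c(seen, sw) }
      if (sum(keep) >= top_n) break
    }
    res <- res[keep, , drop = FALSE]
    if (nrow(res) < top_n) {
      stop("fewer than top_n (", top_n, ") non-redundant motifs available",
           call. = FALSE)
    }
  }
  res$rank <- seq_len(nrow(res))
  res[seq_len(top_n), , drop = FALSE]
}

#' Build a genes-by-motifs feature matrix
#'
#' One row per promoter, one column per motif. Binary mode (the default)
#' records presence (count >= 1); count mode records overlapping occurrence
#' counts.
#'
#' @param promoters A named `DNAStringSet`.
#' @param motifs Character vector of 5-8 bp ACGT motifs.
#' @param mode `"binary"` or `"count"`.
#' @param genes Optional gene ids the matrix must cover; promoters missing
#'   for any of them is an error.
#' @return A `motif_feature_matrix` tibble: `gene_id` plus one integer column
#'   per motif.
#' @export
build_feature_matrix <- function(promoters, motifs, mode = c("binary", "count"),
                                 genes = NULL) {
  mode <- match.arg(mode)
  motifs <- vapply(motifs, check_motif, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(motifs)) stop("duplicate motifs", call. = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(promoters))
    if (length(missing)) {
      stop("no promoter for gene(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    promoters <- promoters[genes]
  }
  counts <- if (length(motifs)) {
    vapply(motifs, function(mo) Biostrings::vcountPattern(mo, promoters, fixed = TRUE),
           integer(length(promoters)))
  } else {
    matrix(integer(), nrow = length(promoters), ncol = 0L)
  }
  if (length(promoters) == 1L) counts <- matrix(counts, nrow = 1L)
  if (mode == "binary") counts <- (counts >= 1L) * 1L
  out <- tibble::as_tibble(as.data.frame(counts, optional = TRUE))
  names(out) <- motifs
  out <- dplyr::bind_cols(tibble::tibble(gene_id = names(promoters)), out)
  class(out) <- c("motif_feature_matrix", class(out))
  attr(out, "mode") <- mode
  out
}
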