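#' Specification for a synthetic circadian expression study
#'
#' Describes a free-running time course whose variance is dominated by two
#' orthogonal 24 h trends: a 12-timepoint, 4 h-interval design in which a
#' subset of genes cycles with class-specific peak phases (dawn 0 h, noon
#' 6 h, dusk 12 h, midnight 18 h), optionally with an exponentially damped
#' subset emulating a rhythm that decays after transfer to constant
#' conditions, on a background of non-rhythmic noise genes.
#'
#' @param n_genes Total genes (default 2000).
#' @param n_circadian Number of cycling genes (default 200).
#' @param time_hours Sampling times (default `seq(0, 44, by = 4)`).
#' @param period_h Oscillation period (default 24).
#' @param phase_peaks Named vector of class peak hours.
#' @param class_weights Sampling weights of the phase classes (default
#'   `c(0.38, 0.12, 0.38, 0.12)` for dawn/noon/dusk/midnight: circadian
#'   transcripts cluster unevenly around the day with dawn and dusk phases
#'   dominant, which keeps the two latent trends identifiable — a phase
#'   density with four comparable modes leaves the component frame
#'   statistically unpinned).
#' @param phase_jitter_sd SD (hours) of per-gene Gaussian spread around the
#'   class peak (default 1.5): realized peak phases form a continuum around
#'   the clock rather than four spikes. The truth class of a gene is the
#'   class whose peak is circularly nearest its realized peak.
#' @param amp_range Uniform amplitude range for cyclers (default 1-2, in
#'   log2 units against `noise_sd`, i.e. signal-to-noise at least
#'   `amp_range[1] / noise_sd`). May also be a named list with one range per
#'   class; the default boosts the sparser noon/midnight classes to
#'   1.5-2.5 so the weaker latent trend stays above the background
#'   eigenvalue floor.
#' @param baseline_range Uniform range of per-gene constant baselines
#'   (log2-scale abundance; removed by preprocessing).
#' @param noise_sd Gaussian noise SD (default 0.35).
#' @param damping_fraction Fraction of cyclers carrying an exponential
#'   damping envelope (default 0).
#' @param damping_rate Envelope decay rate per hour (default `1/24`).
#' @param damping_classes Classes whose cyclers may be damped (default all);
#'   restricting to one class plants a coherent third trend of known rank.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 2000L, n_circadian = 200L,
                            time_hours = seq(0, 44, by = 4), period_h = 24,
                            phase_peaks = c(dawn = 0, noon = 6, dusk = 12,
                                            midnight = 18),
                            class_weights = c(0.38, 0.12, 0.38, 0.12),
                            amp_range = list(dawn = c(1, 2), noon = c(1.5, 2.5),
                                             dusk = c(1, 2), midnight = c(1.5, 2.5)),
                            phase_jitter_sd = 1.5,
                            baseline_range = c(6, 10),
                            noise_sd = 0.35, damping_fraction = 0,
                            damping_rate = 1 / 24, damping_classes = NULL,
                            seed = 1L) {
  if (n_circadian > n_genes) stop("`n_circadian` cannot exceed `n_genes`", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (damping_fraction < 0 || damping_fraction > 1) {
    stop("`damping_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(phase_peaks))) stop("`phase_peaks` must be named", call. = FALSE)
  if (length(class_weights) != length(phase_peaks)) {
    stop("`class_weights` must match `phase_peaks` in length", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), n_circadian = as.integer(n_circadian),
                 time_hours = as.numeric(time_hours), period_h = period_h,
                 phase_peaks = phase_peaks,
                 class_weights = class_weights / sum(class_weights),
                 amp_range = amp_range, phase_jitter_sd = phase_jitter_sd,
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 damping_fraction = damping_fraction, damping_rate = damping_rate,
                 damping_classes = damping_classes, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a circadian expression study with ground truth
#'
#' Cycling genes follow `amplitude * cos(2*pi*(t - peak)/period)`, optionally
#' multiplied by `exp(-damping_rate * t)` for the damped subset, plus a
#' per-gene baseline and Gaussian noise. Background genes are baseline plus
#' noise. Values are on a log2-like scale, so downstream preprocessing is
#' run with `apply_log2 = FALSE`.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `expr` (an `expression_matrix`, not normalized) and
#'   `truth` (tibble `gene_id`, `is_circadian`, `class`, `peak_h`,
#'   `amplitude`, `damped`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  t <- spec$time_hours
  m <- length(t)
  n <- spec$n_genes
  nc <- spec$n_circadian
  classes <- names(spec$phase_peaks)
  with_seed(spec$seed, {
    gene_ids <- sprintf("G%05d", seq_len(n))
    cls <- rep(NA_character_, n)
    peak <- rep(NA_real_, n)
    amp <- rep(NA_real_, n)
    damped <- rep(FALSE, n)
    if (nc > 0L) {
      drawn <- sample(classes, nc, replace = TRUE, prob = spec$class_weights)
      peak[seq_len(nc)] <- (spec$phase_peaks[drawn] +
                              stats::rnorm(nc, 0, spec$phase_jitter_sd)) %% spec$period_h
      # truth class follows the realized peak (nearest class peak, circular)
      cls[seq_len(nc)] <- vapply(peak[seq_len(nc)], function(p) {
        delta <- abs((p - spec$phase_peaks + spec$period_h / 2) %% spec$period_h -
                       spec$period_h / 2)
        classes[which.min(delta)]
      }, character(1))
      amp[seq_len(nc)] <- vapply(seq_len(nc), function(i) {
        rng <- if (is.list(spec$amp_range)) spec$amp_range[[drawn[i]]] else spec$amp_range
        stats::runif(1L, rng[1L], rng[2L])
      }, numeric(1))
      eligible <- if (is.null(spec$damping_classes)) seq_len(nc)
                  else which(cls[seq_len(nc)] %in% spec$damping_classes)
      n_damp <- round(spec$damping_fraction * nc)
      if (n_damp > length(eligible)) n_damp <- length(eligible)
      if (n_damp > 0L) damped[sample(eligible, n_damp)] <- TRUE
    }
    baseline <- stats::runif(n, spec$baseline_range[1L], spec$baseline_range[2L])
    values <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m) + baseline
    if (nc > 0L) {
      for (i in seq_len(nc)) {
        w <- amp[i] * cos(2 * pi * (t - peak[i]) / spec$period_h)
        if (damped[i]) w <- w * exp(-spec$damping_rate * t)
        values[i, ] <- values[i, ] + w
      }
    }
    list(
      expr = expression_matrix(values, gene_ids, t, normalized = FALSE),
      truth = tibble::tibble(gene_id = gene_ids,
                             is_circadian = !is.na(cls),
                             class = cls, peak_h = peak, amplitude = amp,
                             damped = damped)
    )
  })
}

#' Specification for synthetic promoters with planted phase motifs
#'
#' Four phase classes carry progressively overlapping motif sets (the default
#' scheme walks five motifs around the day: dawn {M1,M2,M3}, noon {M2,M3,M4},
#' dusk {M3,M4,M5}, midnight {M4,M5,M1}), planted into i.i.d. background
#' sequence with class-dependent probabilities.
#'
#' @param genes Data frame with `gene_id` and `class` (phase class per gene).
#' @param class_motifs Named list: class -> character vector of motifs. The
#'   default uses 8-mers built around known circadian/light element cores —
#'   the evening element (AATATC), the I-box (GATAA) and CDA-1 (CAAAA) —
#'   padded to keep base composition balanced enough that chance occurrences
#'   in AT-rich background sequence stay rare. A class with no motifs (e.g. a
#'   background set) maps to `character(0)`.
#' @param p_in Planting probability for in-class motifs (default 0.9).
#' @param p_out Planting probability for out-of-class motifs (default 0.1).
#' @param promoter_length Sequence length (default 1000).
#' @param base_freq Background base composition (default AT-rich, as in plant
#'   promoters).
#' @param seed Integer seed.
#' @return A `promoter_sim_spec` list.
#' @export
promoter_sim_spec <- function(genes,
                              class_motifs = NULL,
                              p_in = 0.9, p_out = 0.1,
                              promoter_length = 1000L,
                              base_freq = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33),
                              seed = 1L) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "class") %in% names(genes)))
  if (is.null(class_motifs)) {
    ring <- c("AATATCGC", "GATAAGCG", "CAAAAGTG", "AGGCCATG", "GTCGTTGC")
    class_motifs <- list(
      dawn = ring[c(1, 2, 3)], noon = ring[c(2, 3, 4)],
      dusk = ring[c(3, 4, 5)], midnight = ring[c(4, 5, 1)]
    )
  }
  lapply(unlist(class_motifs), check_motif)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("planting probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(base_freq) - 1) > 1e-6) stop("`base_freq` must sum to 1", call. = FALSE)
  structure(list(genes = genes, class_motifs = class_motifs, p_in = p_in,
                 p_out = p_out, promoter_length = as.integer(promoter_length),
                 base_freq = base_freq, seed = as.integer(seed)),
            class = "promoter_sim_spec")
}

#' Simulate promoters with planted motifs and ground truth
#'
#' Backgrounds are i.i.d. draws from `base_freq`; planted motifs are written
#' at uniformly random, mutually non-overlapping positions.
#'
#' @param spec A [promoter_sim_spec()].
#' @return A list: `promoters` (named `DNAStringSet`) and `truth` (tibble
#'   `gene_id`, `class`, `motif` — one row per planted occurrence).
#' @export
simulate_promoters <- function(spec) {
  stopifnot(inherits(spec, "promoter_sim_spec"))
  all_motifs <- unique(unlist(spec$class_motifs, use.names = FALSE))
  len <- spec$promoter_length
  if (sum(nchar(all_motifs)) > len / 2L) {
    stop("motif payload too large for the promoter length", call. = FALSE)
  }
  bases <- names(spec$base_freq)
  with_seed(spec$seed, {
    rows <- vector("list", nrow(spec$genes))
    seqs <- character(nrow(spec$genes))
    for (g in seq_len(nrow(spec$genes))) {
      cl <- spec$genes$class[g]
      in_class <- spec$class_motifs[[cl]]
      plant <- all_motifs[stats::runif(length(all_motifs)) <
                            ifelse(all_motifs %in% in_class, spec$p_in, spec$p_out)]
      s <- sample(bases, len, replace = TRUE, prob = spec$base_freq)
      taken <- rep(FALSE, len)
      for (mo in plant) {
        k <- nchar(mo)
        pos <- place_motif(taken, k, max_tries = 200L)
        if (is.na(pos)) stop("could not place motif '", mo, "' without overlap",
                             call. = FALSE)
        s[pos:(pos + k - 1L)] <- strsplit(mo, "")[[1L]]
        taken[pos:(pos + k - 1L)] <- TRUE
      }
      seqs[g] <- paste(s, collapse = "")
      rows[[g]] <- if (length(plant)) {
        tibble::tibble(gene_id = spec$genes$gene_id[g], class = cl, motif = plant)
      } else NULL
    }
    list(
      promoters = Biostrings::DNAStringSet(
        stats::setNames(seqs, spec$genes$gene_id)),
      truth = dplyr::bind_rows(rows)
    )
  })
}

place_motif <- function(taken, k, max_tries) {
  len <- length(taken)
  for (try in seq_len(max_tries)) {
    pos <- sample.int(len - k + 1L, 1L)
    if (!any(taken[pos:(pos + k - 1L)])) return(pos)
  }
  NA_integer_
}

#' Simulate a pair of studies sharing latent circadian structure
#'
#' Study A is drawn from `spec`; study B regenerates a conserved fraction of
#' genes from the same latent parameters (class, peak, amplitude, damping)
#' with independent noise, while non-conserved cyclers are re-randomized
#' (fresh uniform peak phase and amplitude) and non-conserved background
#' genes stay pure noise. The ortholog map is the identity.
#'
#' @param spec A [simulation_spec()] for study A.
#' @param study_noise_sd Noise SD of study B (default: same as A).
#' @param conserved_fraction Fraction of genes keeping their latent
#'   parameters in B (default 1).
#' @param seed Integer seed (independent of `spec$seed`).
#' @return A list: `xa`, `xb` (expression matrices), `map` (identity
#'   ortholog tibble), `truth_a`, `truth_b`, `conserved` (logical by gene).
#' @export
simulate_study_pair <- function(spec, study_noise_sd = NULL,
                                conserved_fraction = 1, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(study_noise_sd)) study_noise_sd <- spec$noise_sd
  a <- simulate_expression(spec)
  t <- spec$time_hours
  m <- length(t)
  n <- spec$n_genes
  with_seed(as.integer(seed), {
    conserved <- stats::runif(n) < conserved_fraction
    truth_b <- a$truth
    redraw <- which(!conserved & truth_b$is_circadian)
    amp_rng <- range(unlist(spec$amp_range))
    truth_b$peak_h[redraw] <- stats::runif(length(redraw), 0, spec$period_h)
    truth_b$amplitude[redraw] <- stats::runif(length(redraw), amp_rng[1L], amp_rng[2L])
    baseline <- stats::runif(n, spec$baseline_range[1L], spec$baseline_range[2L])
    vb <- matrix(stats::rnorm(n * m, 0, study_noise_sd), n, m) + baseline
    for (i in which(truth_b$is_circadian)) {
      w <- truth_b$amplitude[i] * cos(2 * pi * (t - truth_b$peak_h[i]) / spec$period_h)
      if (truth_b$damped[i]) w <- w * exp(-spec$damping_rate * t)
      vb[i, ] <- vb[i, ] + w
    }
    list(
      xa = a$expr,
      xb = expression_matrix(vb, a$expr$gene_ids, t, normalized = FALSE),
      map = tibble::tibble(gene_a = a$expr$gene_ids, gene_b = a$expr$gene_ids),
      truth_a = a$truth, truth_b = truth_b, conserved = conserved
    )
  })
}
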