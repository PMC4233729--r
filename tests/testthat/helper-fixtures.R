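# shared fixture builders; everything is generated in code at test time

fixture_times <- seq(0, 44, by = 4)

# small raw positive matrix with known shape
tiny_matrix <- function(n = 5, m = 4, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(stats::runif(n * m, 1, 10), n, m),
                    sprintf("g%02d", seq_len(n)), seq(0, by = 4, length.out = m))
}

# normalized matrix built from exactly two orthogonal 24 h profiles (rank 2):
# continuous phases concentrated on one antipodal mode pair, so both the
# variance frame and the kurtosis frame sit on the planted axes
two_trend_matrix <- function(n = 300, seed = 1, noise_sd = 0) {
  set.seed(seed)
  t <- fixture_times
  phase <- stats::rnorm(n, 0, 3) + sample(c(0, 12), n, replace = TRUE,
                                          prob = c(0.75, 0.25))
  amp <- stats::runif(n, 0.8, 2)
  x <- t(sapply(seq_len(n), function(i) amp[i] * cos(2 * pi * (t - phase[i]) / 24)))
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(n * length(t), 0, noise_sd), n)
  out <- preprocess(expression_matrix(x + 8, sprintf("g%04d", seq_len(n)), t))
  # the column-scaling step of preprocessing rescales timepoints, so the
  # effective planted profiles are the rescaled (then renormalized) sinusoids
  s <- sqrt(colMeans(sweep(x, 2, colMeans(x))^2))
  pl <- rbind(cos(2 * pi * t / 24) / s, sin(2 * pi * t / 24) / s)
  attr(out, "planted") <- pl / sqrt(rowSums(pl^2))
  out
}

planted_trends <- function(t = fixture_times) {
  pl <- rbind(cos(2 * pi * t / 24), sin(2 * pi * t / 24))
  pl / sqrt(rowSums(pl^2))
}

# write a small expression TSV and return its path
write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_fasta_fixture <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

ring_motifs <- c("AATATCGC", "GATAAGCG", "CAAAAGTG", "AGGCCATG", "GTCGTTGC")

ring_class_motifs <- function(ring = ring_motifs) {
  list(dawn = ring[c(1, 2, 3)], noon = ring[c(2, 3, 4)],
       dusk = ring[c(3, 4, 5)], midnight = ring[c(4, 5, 1)],
       background = character(0))
}
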