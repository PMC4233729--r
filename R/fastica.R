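# FastICA engine for eigentrend extraction.
#
# Orientation: for X (n genes x m timepoints) the model is X = A S with S
# (d x m) holding component time profiles in rows and A (n x d) the gene
# loadings. Independence is sought across genes, i.e. the loading columns are
# the "sources": FastICA runs on t(X), treating the m timepoint profiles as
# mixed signals observed over n genes.

# Single symmetric FastICA fit (logcosh contrast, PCA whitening to d dims).
# Returns the d x m matrix of unit-norm component time profiles, or NULL when
# the iteration fails to converge within max_iter.
fastica_once <- function(values, d, seed, max_iter = 1000L, tol = 1e-4,
                         fun = c("kurtosis", "logcosh")) {
  fun <- match.arg(fun)
  xt <- t(values)                       # m x n
  n <- ncol(xt)
  xt <- xt - rowMeans(xt)
  sv <- svd(xt, nu = d, nv = 0L)
  rank <- sum(sv$d > 1e-9 * sv$d[1L])
  if (d > rank) {
    stop("n_components (", d, ") exceeds the numerical rank (", rank,
         ") of the matrix; note that row centring caps the rank at m - 1",
         call. = FALSE)
  }
  k <- (t(sv$u[, seq_len(d), drop = FALSE]) / sv$d[seq_len(d)]) * sqrt(n)
  z <- k %*% xt                         # d x n, whitened
  w <- with_seed(seed, matrix(stats::rnorm(d * d), d, d))
  w <- orthonormalize(w)
  # keep the tightest approximate fixed point visited: kurtosis extrema can
  # be weakly unstable under the fixed-point map, so the iterate may pass
  # through a solution and drift off again
  best_w <- NULL
  best_delta <- Inf
  for (i in seq_len(max_iter)) {
    wz <- w %*% z
    w1 <- if (fun == "kurtosis") {
      (wz^3) %*% t(z) / n - 3 * w
    } else {
      g <- tanh(wz)
      g %*% t(z) / n - diag(rowMeans(1 - g^2), d) %*% w
    }
    w1 <- orthonormalize(w1)
    delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    if (delta < best_delta) { best_delta <- delta; best_w <- w1 }
    w <- w1
    if (delta < tol) break
  }
  # the fixed-point map can enter a limit cycle tightly orbiting a frame; the
  # best iterate is then still a consistent, accurate solution, so accept it
  # under a looser threshold and reserve NULL for genuinely lost iterations
  if (best_delta >= max(tol, 0.02)) return(NULL)
  w <- best_w
  wk <- w %*% k                         # d x m, unmixing in original space
  mix <- t(wk) %*% solve(wk %*% t(wk))  # m x d mixing (time profiles in columns)
  s <- t(mix)
  s / sqrt(rowSums(s^2))
}

orthonormalize <- function(w) {
  sv <- svd(w)
  sv$u %*% t(sv$v)
}

# Greedy alignment of one run's components to a reference set: match by
# largest absolute row correlation (rows are unit-norm, so the dot product is
# the correlation up to centring), flip signs to positive agreement.
align_components <- function(ref, s) {
  d <- nrow(ref)
  cc <- ref %*% t(s)
  out <- matrix(0, d, ncol(ref))
  used <- rep(FALSE, d)
  for (i in order(-apply(abs(cc), 1L, max))) {
    j <- which.max(ifelse(used, -Inf, abs(cc[i, ])))
    out[i, ] <- s[j, ] * sign(cc[i, j])
    used[j] <- TRUE
  }
  out
}

# Run FastICA n_runs times with distinct sub-seeds and average the dominant
# consensus basin: restarts can converge to genuinely different local optima
# (frames), and a blind average of rotated frames is meaningless, so runs are
# clustered by frame similarity (min matched |dot| after greedy alignment),
# the modal cluster is kept, its members are aligned to the cluster's
# representative and averaged, and the averaged rows renormalized.
# Non-convergent runs are retried with fresh sub-seeds up to max_retries
# times each before erroring.
averaged_ica <- function(values, d, n_runs, seed, max_iter = 1000L, tol = 1e-4,
                         fun = "kurtosis", max_retries = 5L,
                         average = c("consensus", "all"), consensus_min = 0.9) {
  average <- match.arg(average)
  fit_with_retry <- function(sub_seed) {
    for (r in 0:max_retries) {
      s <- fastica_once(values, d, sub_seed + r * 7919L, max_iter = max_iter,
                        tol = tol, fun = fun)
      if (!is.null(s)) return(s)
    }
    stop("FastICA failed to converge after ", max_retries, " retries", call. = FALSE)
  }
  runs <- lapply(seq_len(n_runs), function(run) {
    fit_with_retry(seed + (run - 1L) * 1009L)
  })
  if (n_runs == 1L) return(runs[[1L]])
  if (average == "all") {
    # straight average of every restart aligned to the first: deliberately
    # sensitive to restart instability (an unstable set of components
    # averages into a degraded, non-orthogonal model) -- the property the
    # empirical component-count test measures
    ref <- runs[[1L]]
    acc <- Reduce(`+`, lapply(runs, function(b) align_components(ref, b)))
    s <- acc / n_runs
    return(s / sqrt(rowSums(s^2)))
  }
  frame_sim <- function(a, b) min(abs(diag(a %*% t(align_components(a, b)))))
  neighbours <- lapply(seq_len(n_runs), function(i) {
    which(vapply(runs, function(b) frame_sim(runs[[i]], b) >= consensus_min,
                 logical(1)))
  })
  # restarts may populate several genuine local-optimum frames; keep the one
  # concordant with the variance structure (the PCA frame), the concordance
  # the eigentrend analysis itself leans on, breaking ties by basin size
  sv <- svd(scale(values, scale = FALSE), nu = 0L, nv = d)
  pca_frame <- t(sv$v)
  pca_sim <- vapply(runs, function(b) frame_sim(pca_frame, b), numeric(1))
  score <- rank(pca_sim) + rank(lengths(neighbours)) / (2 * n_runs)
  rep_idx <- which.max(score)
  ref <- runs[[rep_idx]]
  members <- neighbours[[rep_idx]]
  acc <- Reduce(`+`, lapply(runs[members], function(b) align_components(ref, b)))
  s <- acc / length(members)
  s / sqrt(rowSums(s^2))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
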