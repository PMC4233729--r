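---
title: "Eigentrend analysis of circadian transcriptomes: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigentrend analysis of circadian transcriptomes: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A free-running expression time course — organisms entrained to light/dark
cycles, then sampled every 4 h for two days under constant conditions — varies
mostly because of the endogenous clock. Pattern-matching detectors (cosine
regression, COSOPT-style template fits) presuppose a waveform. circatrend
implements the unbiased alternative: extract the dominant latent time profiles
("eigentrends") from the matrix itself, ask how many of them are statistically
real, and describe every gene by its projection onto the two circadian ones.
The projection radius is the evidence that a gene is clock-driven; the
projection angle is its phase; the four signed half-axes define four phase modules
(dawn, dusk, mid-day, midnight). Downstream, conservation of this organisation
across studies and species is scored with the integrative correlation
coefficient and Jaccard module-preservation z-scores, and a random-forest
classifier asks whether combinations of short promoter elements are sufficient
to predict a gene's phase module.

## Pre-processing

`preprocess()` applies, in order: optional log2, column centring, column
scaling to unit population SD, row centring, row scaling to unit population SD.
Every gene ends at mean 0 and SD 1, so genes contribute equal weight and the
projection geometry below is scale-free. Population moments (divide by the
count) are used throughout, which also makes the sinusoid kurtosis closed form
(-3/2) exact. Constant genes are a hard error naming the offending ids: silent
dropping would make reported circadian counts irreproducible. No pseudocount is
added silently; `pseudocount` exists for data with zeros. Note two consequences
we verified numerically and lean on in the tests: row centring caps the matrix
rank at m − 1, and column scaling slightly warps any planted low-rank structure
unless a large non-rhythmic background flattens the column variances.

## Averaged ICA eigentrends

The model is X = AS with X the n × m normalized matrix, S (d × m) component
time profiles, A (n × d) gene loadings; independence is sought across genes, so
FastICA runs on the transposed matrix. The engine whitens to the top-d
principal subspace and iterates the classical kurtosis (pow3) contrast with
symmetric decorrelation; `fun = "logcosh"` is available. Two numerical
behaviours matter at this scale and shaped the implementation:

* The fixed-point map can enter a limit cycle that tightly orbits a frame. The
  engine records the best iterate and accepts it when its fixed-point residual
  is below 0.02 — orbiting iterates agree with each other to ~1e-3, so this is
  a solution, not a failure. Runs that never get near a fixed point are retried
  with fresh sub-seeds and finally error.
* Restarts can populate two genuinely different local optima: the frame aligned
  with the phase-density modes and its 45° rotation. A straight average across
  frames is meaningless, so `run_ica()` clusters runs by frame similarity and
  averages the basin concordant with the PCA frame (`average = "consensus"`),
  breaking ties by basin size. The concordance of circadian eigentrends with
  the leading principal components is itself a finding the analysis validates,
  which is what justifies using it to disambiguate. The straight aligned
  average of every restart remains available (`average = "all"`) and is used by
  the significance test below, deliberately: its degradation under restart
  instability is the signal.

Components are ranked by the excess kurtosis of their loading distributions.
The interestingness ordering is descending |kurtosis| by default: a trend is
structured when its loadings are far from Gaussian in either direction. In
broadly rhythmic data most genes correlate with the circadian pair and the
loadings are bimodal (negative kurtosis), so the classical most-negative-first
ordering (`order_by = "ascending"`) coincides; when only a minority of genes
cycle, circadian loadings are heavy-tailed (positive kurtosis) and the
absolute ordering is the one that still ranks them first.

After averaging, profiles are renormalized to unit norm and loadings are
recomputed as `X %*% t(S)`. Because averaged profiles are not exactly
orthogonal, the implied reconstruction `A %*% S` is not a least-squares
projection; it degrades when the component set is unstable. This is a feature,
not an approximation error — see the next section.

## How many components? The empirical test

`reconstruction_error(x, d)` fits a d-component averaged decomposition and
returns ||X − AS||~F~. `empirical_component_test()` compares it with the same
quantity on randomized matrices (within-gene permutation by default, the
margin-preserving `swap_discretized` scheme as an alternative) and reports the
frequency with which randomized errors fall below the observed one.

Why does this detect the number of real components? A capture-based argument
says it cannot: a matrix with genuine low-rank structure reconstructs better
than its randomization at *every* d under any optimal rank-d model, so
significance would never switch off above the true rank. We verified this with
an SVD oracle. What switches off is *stability*: beyond the true rank the
extra components differ from restart to restart, the straight average of
restarts collapses toward a degenerate, non-orthogonal set, and the
`X %*% t(S)` reconstruction degrades — while randomized matrices, having no
preferred directions at any d, degrade equally at all d. At the true rank the
observed error beats essentially every randomization; above it the
randomizations win often. Reconstruction error therefore *decreases* up to the
true rank and *rises* beyond it, and the p-value flags exactly the models the
data can support. The unit tests assert this minimized-at-the-rank shape, and
the acceptance suite runs the full design: 400 genes, 80 cyclers in four
classes, an exponentially damped subset (fraction 0.3, rate 1/24 h) as the
third trend, noise SD 0.35, 200 randomizations, 10 restarts per fit.

The p-value is the plain frequency and can be exactly 0; `add_one` applies the
(k+1)/(N+1) correction when a strictly positive p is needed downstream.

## Projection, the 0.8 radius, and phase modules

Gene profiles are rescaled to unit Euclidean norm before projection, so with
orthonormal components the radius is bounded by 1 and behaves like a
correlation — which is what makes the conventional stringent cutoff of 0.8
meaningful. The cutoff is inclusive (radius ≥ 0.8). Modules follow the signed
axis with the largest dot product — mid-day (+q1), midnight (−q1), dawn (+q2),
dusk (−q2) — with ties broken by the fixed precedence +q1, −q1, +q2, −q2.
Phase is the projection angle rescaled to hours, anchored at +q1; with the
canonical orientation (`orient_axes()` anchors +q1 at a 6 h peak and +q2 at
0 h) phase decreases as planted peak time increases, a pure convention, so
phase-recovery checks use the magnitude of the circular correlation.

## Cross-study statistics

The integrative correlation of an ortholog pair is the Pearson correlation
between the gene's correlation profiles in the two studies, computed over the
mapped universe only; pairs with a constant vector are excluded from both the
scores and the profiles, with a warning. The null shuffles values within every
gene of study B. Module preservation builds co-expression graphs (one-sided
r ≥ 0.8 by default; `absolute = TRUE` exists) over ortholog-aligned nodes,
scores edge-set Jaccard similarity (TP/(TP+FP+FN); two empty sets count as 1),
and normalizes against random same-size gene sets from the mapped universe —
the scheme chosen here for the "equivalent randomized module structures" null.

## Promoter elements and the phase classifier

All 5–8-mers are screened by one-sided hypergeometric enrichment of
presence/absence in circadian versus background promoters, and the top 21
become binary features. Overlapping k-mers of one element form families with
near-identical presence patterns; `distinct = TRUE` keeps one representative
per family (greedy walk of the ranked list, dropping motifs that share a 4 bp
subword with a kept one). Without it the screen is still correct, but the list
fills with shifted variants of the strongest elements.

Classification uses one one-vs-rest random forest per class (2000 trees, mtry
= floor(sqrt(p)) = 4 for 21 features): class-specific importance rankings are
the object of interest, and a single multiclass forest does not provide them
cleanly. Training uses a stratified two-thirds split with equal class counts
(downsampled to the smallest class); the held-out third provides vote-fraction
scores, ROC curves by threshold sweep, trapezoid AUC (equal to the normalized
Mann–Whitney U, asserted in tests against an independent implementation), and
permutation importance. Two importance estimators exist: per-feature
permutation (the default) and grouped permutation (`grouped = TRUE`), which
permutes a feature jointly with the features it correlates with. The grouped
form matters whenever elements co-occur across classes — in a progressive
architecture adjacent elements share two of three classes, the forest leans on
one member of a correlated pair, and the other's single-feature importance
collapses to zero although the family clearly drives the classification.

The progressive table marks an element present for a class when it is in that
class's top-k by importance (or is an explicitly supplied element of interest
above the noise floor) *and* shows positive in-class association (higher
presence rate inside the class than outside). Importance is unsigned — an
element whose absence marks a class would otherwise enter that class's row —
and the table is meant to list elements contributing to a phase. Classes are
emitted dawn → noon → dusk → midnight and double-plotted so the progressive
cycling reads continuously across the day boundary. Mean-phase vectors average
(q1, q2) over circadian genes carrying a full element combination.

## The synthetic-data generators

`simulate_expression()` emulates a 12-timepoint, 4 h free-running design:
cyclers follow amplitude·cos(2π(t − peak)/24), optionally damped by
exp(−t/24 h) to emulate a rhythm decaying under constant conditions, on a
per-gene baseline with Gaussian noise; background genes are baseline plus
noise. The defaults are the reference study used throughout: 2000 genes, 200
cyclers, noise SD 0.35, amplitudes 1–2 (dawn/dusk) and 1.5–2.5
(noon/midnight), class weights 0.38/0.12/0.38/0.12 for dawn/noon/dusk/midnight,
Gaussian phase jitter of 1.5 h around the class peaks, truth classes assigned
by the circularly nearest peak. These choices are not cosmetic:

* Real circadian phase distributions are continuous and uneven, dominated by
  dawn- and dusk-phased transcripts. That unevenness is also what makes the
  latent frame identifiable: with four equal, discrete classes the 45°-rotated
  view of the loadings is a two-point distribution — the global kurtosis
  minimum — and *no* kurtosis-seeking method can prefer the planted axes; with
  a dominant antipodal mode pair plus spread, the noise floor breaks the
  scale-invariance and pins the optimum to the axes.
* The sparser noon/midnight classes carry higher amplitudes so the weaker
  latent trend stays above the background eigenvalue floor.

What passing tests show — and what they do not: with 200 cyclers among 2000
genes the second trend's eigen-gap over the 1800-gene background floor, plus
finite-sample wobble of fourth moments, bounds per-component recovery at about
|r| ≈ 0.94–0.99 depending on the draw; at a 10 000-gene scale the same
pipeline recovers |r| ≥ 0.995 routinely. Calling performance (recall, FPR,
module accuracy) is insensitive to the residual frame wobble. The generators
do not model probe effects, saturation, heteroscedastic platform noise, or
sequence evolution; conclusions about real arrays rest on the method, not on
these fixtures.

`simulate_promoters()` plants progressively overlapping motif sets — dawn
{M1,M2,M3}, noon {M2,M3,M4}, dusk {M3,M4,M5}, midnight {M4,M5,M1} — into
i.i.d. AT-rich background (A/T 0.33, C/G 0.17) at probability 0.9 in-class and
0.1 out-of-class, at non-overlapping random positions. The default elements
are subword-distinct 8-mers built around known circadian/light cores — the
evening element (AATATC → AATATCGC), the I-box (GATAA → GATAAGCG), CDA-1
(CAAAA → CAAAAGTG) — padded to keep chance occurrence in AT-rich sequence
near 1–2%, so planted signal is not swamped by background hits.
`simulate_study_pair()` regenerates conserved genes from the same latent
parameters with fresh noise and re-randomizes the rest, with an identity
ortholog map.

## Problem sizes used by the packaged studies

The test-suite and acceptance studies run at: reference study 2000 × 12 with
100 ICA restarts; component-count study 400 × 12, 200 randomizations, 10
restarts per fit; cross-study 500 genes, 20 null permutations, 100
module-preservation permutations; classifier study 4 × 250 genes with 1000
background promoters, 21 features, 2000 trees. These sizes keep each study's
statistics in the regime the method targets while remaining comfortable on a
single CPU.

## Known limitations

* Per-component trend recovery at the 2000/200 reference scale is bounded near
  |r| ≈ 0.95–0.99 by the background eigenvalue floor (see above); the
  concordance checks and calling metrics are the robust quantities there.
* The empirical component-count test depends on the straight-average
  reconstruction convention; with least-squares loadings it would reduce to a
  capture comparison and lose its ability to reject over-modelling.
* `swap_discretized` preserves margins only at bin resolution.
* The enrichment screen is presence/absence with exact matching; degenerate
  (IUPAC) motifs and PWMs are out of scope, as is promoter extraction from
  annotation — promoters arrive as FASTA.
* The classifier reports a single stratified split by default; repeated-split
  AUC summaries are available through `forest_config(n_repeats = ...)`.
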