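---
title: "Recurrence plots and automatic cross detection for interaction-count dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence plots and automatic cross detection for interaction-count dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpcross)
```

## The problem

Molecular-dynamics simulations of aggregating biomolecules — here, the model
system is a mix of cellulose, hemicellulose and pectin chains in water —
produce long, equally spaced series of interaction counts: numbers of
intermolecular hydrogen bonds (HBo), polysaccharide–water hydrogen bonds
(PW HBo), and hydrophobic–polar (HP) contacts, saved every 100 ps over a
100 ns run (1000 points). The counts themselves are dominated by a monotone
aggregation trend; their per-step increments `dN/dt` are a noisy,
quasi-stationary signal in which changes of the aggregation dynamics hide.
`rpcross` turns such an increment series into a recurrence plot, quantifies
it with the Shannon entropy of diagonal recurrent lines, and automatically
flags *dark crosses* (windows whose dynamics differ from the rest of the
series) and *white crosses* (windows of locally stabilized oscillation).

## The procedure

1. **Increments.** A count series `N(t)` becomes `x_i = (N(i+1) - N(i))/dt`
   (`increments()`). The pipeline is invariant to the `1/dt` scaling, and to
   any affine transform of `x`, because the recurrence threshold is set by
   rate targeting (below).

2. **Delay embedding.** The series is compressed into sub-series
   `y_i = (x_i, x_{i+tau}, ..., x_{i+d*tau})`, `i = 1, ..., L - d*tau`
   (`embed_series()`). Note the convention: sub-series have `d + 1` points,
   so this `d` is one less than the embedding dimension `m` of the
   phase-space-reconstruction literature.
   - `tau` is the first lag whose sample autocorrelation falls inside the
     white-noise band `±z_{1-alpha/2}/sqrt(L)` (`select_delay()`,
     `alpha = 0.05`). The underlying method reference only names "first
     non-significant autocorrelation"; the large-sample band is our reading,
     with `alpha` exposed.
   - `d` comes from the Cao method (`cao_dimension()`): `E1(m) =
     E(m+1)/E(m)` from mean nearest-neighbour distance ratios under the
     maximum norm; the smallest `m` with `|E1(m) - 1|` and `|E1(m+1) - 1|`
     within `e1_tol = 0.05` is the conventional dimension, and the pipeline
     uses `d = m - 1`. `E2` is reported as Cao's stochasticity diagnostic;
     the `noise` flag is raised when `E1` never saturates within
     `max_dim = 10` *or* all `|E2 - 1| <= 0.1` — on white noise `E1` can
     drift into the saturation band near `max_dim`, while the `E2` criterion
     separates cleanly (measured: noise deviations `<= 0.07`, sine
     `E2(1) ~ 0.003`, logistic map `E2(1) ~ 2`).
   - Across several series, one `(tau, d)` is fixed by majority vote
     (`majority_vote()`), ties toward the smaller value — the less
     compressive choice.

3. **Recurrence matrix.** `m[i, i'] = 0` if `||y_i - y_i'|| <= lambda`, 1
   otherwise (`recurrence_matrix()`). Zero marks recurrence — inverted
   relative to most recurrence-plot software, and rendered white (ones are
   black). The norm is Euclidean by default (`"maximum"` available); the
   worked 5-point example cannot distinguish the two. The *recurrence rate*
   is the fraction of zeros, main diagonal included (forced by the worked
   example: 5 zeros of 9 at `lambda = 0.1` count the 3 diagonal zeros).
   `lambda_for_rate()` maps a target rate to the smallest distance value
   whose empirical cumulative fraction (over the full entry multiset,
   diagonal included) reaches the target.

4. **Diagonal-line entropy.** Maximal runs of zeros along all diagonals
   parallel to the main diagonal — the main diagonal itself (line of
   identity) excluded — are histogrammed and `S = -sum p_j log p_j` is
   computed in nats (`diagonal_runs()`, `shannon_entropy()`). Three
   conventions are forced by the worked example: the line of identity is
   excluded (else a length-3 run would contradict the printed `j in {1}`),
   length-1 runs are counted (unlike the common `l_min = 2`), and the
   logarithm is natural (`0.693 = log 2`).

5. **Working recurrence rate.** `entropy_scan()` computes `S` on a grid of
   target rates (default 30 log-spaced points in `[0.01, 1]`);
   `select_rate()` fits, in `(log rate, log S)`, every continuous
   two-segment piecewise-linear model with the hinge at an interior grid
   point, keeps the breakpoint minimizing the squared error, and majority
   votes the grid index across series. The original analysis selected this
   edge-of-linearity point manually and suggested exactly this kind of
   change-point automation; the two need not coincide on data we cannot
   access. A scan whose two-segment fit improves on a single line by less
   than 1% is flagged `no_edge`.

6. **Cross detection.** `detect_crosses()` implements the weight-based
   detector: column sums of the matrix (ones for dark polarity, zeros for
   white), simple moving average of width `k`, standardization to z-scores
   (population SD), width selection `k = argmax_k max(z)`, then centers as
   local maxima above `threshold_sigma` (default 2.5), greedily thinned so
   surviving centers are at least `k` apart.

## Numerical and design choices

* **SMA edges:** centered windows truncated to available points, so the
  output keeps the input length and index–time alignment; even `k` spans
  `k` points right-biased by one.
* **Plateau maxima:** a flat local maximum contributes its midpoint; edge
  points qualify against their single neighbour (an anomaly near the start
  or end of a run is still locatable).
* **`k` grid:** `1 .. floor(side/4)`. The width argmax has no stated search
  range and is ill-posed unbounded; capping at a quarter of the plot keeps
  the moving average from spanning unrelated regions.
* **Population SD** (divisor `n`) in standardization: the convention is not
  stated; the choice rescales all z-scores per vector monotonically, so it
  cannot change the width argmax, only marginal threshold crossings.
* **Quantile threshold:** `lambda_for_rate` subtracts `1e-9 * side^2`
  before the ceiling so exact rational targets (e.g. `5/9` on a 3×3
  matrix) are not pushed past the attaining entry by float rounding.
* **Degenerate inputs:** constant weight vectors (e.g. the all-recurrent
  matrix) yield an empty detection result flagged `no_structure`, not an
  error; an empty run histogram makes the entropy *undefined* (classed
  error), which is distinct from `S = 0` (a single run-length class).
* **Tie-breaks:** majority votes and the width/breakpoint argmaxes all
  resolve ties toward the smaller value.

## The synthetic generator

MD trajectories behind the original study are not deposited, so
`synth_series()` provides seeded fixtures with the statistical shape the
pipeline assumes (Mersenne-Twister, inversion normals; the seeding
discipline is part of the contract and the caller's RNG state is restored):

* `md_like_counts` — non-negative integer counts with a saturating
  aggregation trend (exponential rise over ~10% of the series, then
  plateau) plus Gaussian integer noise; presets match the three observed
  count magnitudes (plateau means ~115, ~9000, ~67 with SDs ~10, ~80, ~7
  for the HBo-, PW-HBo- and HP-like regimes). Its increments pass a
  Spearman rank stationarity check after the rise.
* `regime_change` — stationary Gaussian increments with one contiguous
  window (default 10% of a 1000-point series) whose mean is shifted by
  `shift` background SDs (default 4) and/or variance inflated: the
  dark-cross mechanism, with ground truth attached.
* `oscillation_window` — a low-variance periodic segment inside noise: the
  white-cross mechanism.
* `sine` — default period `13*pi` samples. An *integer* period makes
  delayed copies exact float duplicates, collapsing nearest-neighbour
  distances to `~1e-15` and turning Cao's distance ratios into rounding
  noise; an irrational period keeps the orbit densely and distinctly
  sampled. This is a geometric requirement of the fixture, chosen once.
* `iid_noise`, `ar1` (`phi = 0` reproduces `iid_noise` bit-for-bit),
  `logistic_map` (`r = 4`: deterministic chaos), `toy` (the worked 5-point
  vector).

What the generator does *not* emulate: the physics of aggregation —
temperature dependence, bond-count autocorrelation structure, or any
coupling between the three interaction types. A green detection test
establishes that the detector finds the kind of anomaly it is designed for
at the stated effect size, not that MD data contain such anomalies.

## Known limitations and honest calibration

* **Null false-positive rate.** The width selector maximizes the maximum
  standardized weight over all `k`; on a null (stationary iid) series of
  ~1000 columns the selected peak is therefore an extreme-value statistic,
  typically ~3.3 sigma, and some local maximum clears the default 2.5 sigma
  almost surely. Measured over 200 seeded null series: a cross is reported
  in 100% of runs. The detector is a *pattern locator* — given that a
  recurrence plot has band structure, it says where and how wide — not a
  significance test; thresholding at 2.5 sigma ranks candidates but does
  not control a false-alarm rate. (The original study likewise reports
  detected crosses in every plot shown.) A stated acceptance bound of <20%
  false positives is kept in the test suite as documentation and fails by
  design.
* **Entropy–rate direction.** With the run-length entropy the worked
  example forces, `S` *increases* with the recurrence rate: the example
  itself rises from `S = 0` at rate 5/9 to `S = 0.693` at rate 1, and the
  all-recurrent matrix attains the maximum `log(side - 1)` (one run per
  diagonal, uniform over `side - 1` lengths). The accompanying narrative
  claim of a monotone *decrease* cannot be reproduced under any reading
  consistent with the printed example (counting runs of ones instead gives
  `S = 0` and an undefined value on the example, not 0 and 0.693). The
  log–log breakpoint selection of the working rate is unaffected: it only
  needs piecewise log-linearity, which holds in either direction.
* Embedding-parameter selection assumes a quasi-stationary increment
  series; applying the pipeline to raw monotone counts is not supported
  (inputs declare `is_increment`; nothing is auto-detected).
* At recurrence rate 1 the weight vector is constant and detection
  degenerates (`no_structure`); working rates near the grid top are only
  useful for the entropy scan.

## A worked fit

```{r}
fit <- rpa(toy_vector(), tau = 2, dim = 1, rate = 5/9,
           threshold_sigma = 1.0, k_grid = 1, scan = FALSE)
print(fit)
```

```{r}
s <- synth_series("regime_change", length = 1000, seed = 7)
attr(s, "truth")
fit <- rpa(s, tau = 2, dim = 1, rate = 0.09, scan = FALSE)
fit$crosses$dark$centers
fit$crosses$dark$k
```

The detected center falls inside the injected window and the selected width
approximates the true window width (100).
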