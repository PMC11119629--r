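# rpcross

Recurrence-plot analysis with automatic cross detection for univariate,
equally spaced time series of molecular interaction counts — e.g. numbers of
intermolecular hydrogen bonds or hydrophobic–polar contacts saved along a
molecular-dynamics trajectory. The package is aimed at simulators who want
to locate *when* the dynamics of an aggregating system change, without
staring at recurrence plots by eye.

## What it computes

Given an increment series `x_i = (N(i+1) − N(i))/Δt` of length `L`:

- **Delay embedding** into sub-series
  `y_i = (x_i, x_{i+τ}, …, x_{i+dτ})`, `i = 1…L − dτ`, with `τ` chosen as
  the first lag whose sample autocorrelation enters the white-noise band
  `±z_{1−α/2}/√L`, and `d` from the Cao method (`E1` saturation, maximum
  norm; `E2 ≈ 1` flags stochastic series). One `(τ, d)` is fixed across
  series by majority vote.
- **Recurrence matrix** `m_{ii'} = 0` if `‖y_i − y_i'‖ ≤ λ`, else 1
  (0 = recurrent, rendered white — note the inverted colour convention).
  `λ` is set by targeting a **recurrence rate** (fraction of zeros,
  diagonal included), making the whole pipeline invariant under affine
  transforms of the input.
- **Diagonal-line entropy** `S = −Σ_j p_j log p_j` (nats) over the lengths
  of maximal recurrent runs along diagonals parallel to the line of
  identity (excluded), scanned over a rate grid; the working rate is
  selected at the breakpoint of log–log linearity by an exact two-segment
  piecewise-linear fit, majority-voted across series.
- **Cross detection**: column weights `w_i = Σ_{i'} m_{ii'}`, SMA smoothing
  of width `k`, z-scoring, `k = argmax_k max(z)` (the cross width), centers
  as local maxima above a threshold standard score (default 2.5σ; dark
  polarity counts ones, white counts zeros).

A seeded synthetic generator (`synth_series()`) supplies MD-like count
series, regime-change and oscillation-window fixtures with ground truth,
plus classical test signals (logistic map, sine, AR(1)).

## Worked example

The 5-point vector `(1, ½, 1, ½, 1)` embedded with `τ = 2`, `d = 1` gives
three sub-series; at recurrence rate 5/9 the recurrence matrix has zeros
exactly where sub-series repeat, the run-length histogram is `{1: 2}`, and
the odd sub-series `(½, ½)` shows up as a width-1 dark cross:

```r
library(rpcross)
fit <- rpa(toy_vector(), tau = 2, dim = 1, rate = 5/9,
           threshold_sigma = 1.0, k_grid = 1, scan = FALSE)
print(fit)
#> Recurrence-plot analysis of 'toy'
#>   L = 5 increments, dt = 1
#>   embedding: tau = 2, d = 1 (sub-series length 2)
#>   recurrence: rate = 0.5556 (achieved 0.5556), lambda = 0 [euclidean]
#>   diagonal-line entropy S = 0 nats
#>   dark crosses (>1 sigma): center 2 (width k = 1)
```

`S = 0` says all recurrent diagonal runs have one length (here: length 1);
at rate 1 the same chain gives `S = 0.693 = log 2` (two equally frequent
run lengths). On a 1000-point synthetic increment series with a 4σ mean
shift injected at indices 400–499:

```r
s <- synth_series("regime_change", length = 1000, seed = 7)
fit <- rpa(s, tau = 2, dim = 1, rate = 0.09, scan = FALSE)
print(fit)
#> Recurrence-plot analysis of 'regime_change'
#>   L = 1000 increments, dt = 1
#>   embedding: tau = 2, d = 1 (sub-series length 2)
#>   recurrence: rate = 0.09 (achieved 0.09), lambda = 0.6728 [euclidean]
#>   diagonal-line entropy S = 0.3648 nats
#>   dark crosses (>2.5 sigma): center 448 (width k = 102)
```

The detected center (448) sits at the true window midpoint (449.5) and the
selected width (102) matches the injected window (100). `plot(fit)` draws
the recurrence plot with green cross bounds; `render_rp()` writes it as a
PNG, one pixel per matrix entry.

See the methods vignette
(`vignettes/recurrence-cross-detection.Rmd`) for the model, parameter
defaults, the synthetic generator's scope, and honest calibration notes
(what the 2.5σ threshold does and does not control).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the analytically
fixed quantities of the worked example — the diagonal-line entropies of the
5-point vector's recurrence matrices at `λ = 0.1` and `λ = 0.9` (nats) and
the center index of the dark cross detected at threshold 1.0σ with `k = 1`
— and writes them as JSON.
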