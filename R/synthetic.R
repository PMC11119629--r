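#' The 5-point worked-example vector
#'
#' The artificial input `(1, 1/2, 1, 1/2, 1)` used throughout the
#' documentation: with `tau = 2`, `d = 1` it embeds into three 2-point
#' sub-series, yields diagonal-line entropies 0 (at `lambda = 0.1`) and
#' `log 2 = 0.693` (at `lambda = 0.9`), and carries a single dark cross of
#' width 1 centered at `i = 2`.
#'
#' @return An [rp_series()] with `dt = 1`, labelled `"toy"`.
#' @export
toy_vector <- function() {
  rp_series(c(1, 1/2, 1, 1/2, 1), dt = 1, label = "toy", is_increment = TRUE)
}

#' Seeded synthetic series emulating MD interaction-count data
#'
#' Reproducible fixtures with the statistical structure the recurrence
#' pipeline assumes, so every stage is testable without MD trajectories.
#' All randomness uses R's Mersenne-Twister generator seeded with `seed`
#' (inversion normals); the caller's RNG state is left untouched. Identical
#' arguments give bit-identical output — the seeding discipline is part of
#' the public contract.
#'
#' Kinds:
#' \describe{
#'   \item{`toy`}{The worked-example vector, see [toy_vector()].}
#'   \item{`iid_noise`}{Gaussian white noise, `mean + sd * rnorm(L)`;
#'     already an increment series.}
#'   \item{`ar1`}{AR(1) `x_t = phi * x_{t-1} + sd * eps_t`; `phi = 0`
#'     reproduces `iid_noise` bit-for-bit at the same seed.}
#'   \item{`logistic_map`}{Deterministic orbit `x_{n+1} = r x_n (1 - x_n)`;
#'     defaults `r = 4`, `x0 = 0.2` (chaotic regime).}
#'   \item{`sine`}{Clean sinusoid with optional additive noise. The default
#'     period `13 * pi` samples is irrational, so no two samples are exact
#'     duplicates — an integer period collapses nearest-neighbour distances
#'     to float noise and breaks distance-ratio diagnostics.}
#'   \item{`regime_change`}{Stationary Gaussian increments with one
#'     contiguous anomalous window: mean shifted by `shift` background
#'     standard deviations and variance inflated by `var_factor`. Ground
#'     truth is attached as attribute `truth` (window start, end inclusive,
#'     midpoint). Defaults: length 1000, window 400..499 (10% of the
#'     series), shift 4, matching the dynamics a dark cross marks.}
#'   \item{`oscillation_window`}{Gaussian increments with one window of
#'     low-variance stable oscillation around the mean (the white-cross /
#'     white-square mechanism); ground truth attached as for
#'     `regime_change`.}
#'   \item{`md_like_counts`}{Non-negative integer counts with a saturating
#'     aggregation trend (rapid early rise, then plateau) plus integer
#'     fluctuation noise, so the increments resemble observed MD interaction
#'     count dynamics. `regime` presets set plateau mean and noise SD to the
#'     magnitudes of the three interaction types: `"hbo"` (~115 bonds,
#'     SD ~10), `"pw_hbo"` (~9000, SD ~80), `"hp"` (~67, SD ~7). `dt`
#'     defaults to 0.1 (ns between saved states).}
#' }
#'
#' @param kind One of `"toy"`, `"iid_noise"`, `"ar1"`, `"logistic_map"`,
#'   `"sine"`, `"regime_change"`, `"oscillation_window"`,
#'   `"md_like_counts"`.
#' @param length Series length (ignored for `toy`).
#' @param seed Integer RNG seed.
#' @param dt Sample spacing; defaults to 1 (0.1 for `md_like_counts`).
#' @param label Series label; a kind-derived default is used if `NULL`.
#' @param ... Kind-specific parameters, see Details.
#' @return An [rp_series()]; `regime_change` and `oscillation_window` carry
#'   a `truth` attribute.
#' @examples
#' s <- synth_series("regime_change", length = 1000, seed = 7)
#' attr(s, "truth")
#' @export
synth_series <- function(kind, length = 1000L, seed = 1L, dt = NULL,
                         label = NULL, ...) {
  kinds <- c("toy", "iid_noise", "ar1", "logistic_map", "sine",
             "regime_change", "oscillation_window", "md_like_counts")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds)
    stop_rp("rp_config_error",
            sprintf("unknown kind '%s' (one of: %s)", kind[1L],
                    paste(kinds, collapse = ", ")))
  if (kind == "toy") return(toy_vector())
  if (!is_count(length)) stop_rp("rp_config_error", "'length' must be a positive integer")
  L <- as.integer(length)
  p <- list(...)
  grab <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  if (is.null(dt)) dt <- if (kind == "md_like_counts") 0.1 else 1
  if (is.null(label)) label <- kind

  if (kind == "iid_noise") {
    sd <- grab("sd", 1); mean <- grab("mean", 0)
    v <- with_seed(seed, mean + sd * stats::rnorm(L))
    return(rp_series(v, dt, label, is_increment = TRUE))
  }
  if (kind == "ar1") {
    sd <- grab("sd", 1); phi <- grab("phi", 0.5)
    eps <- with_seed(seed, sd * stats::rnorm(L))
    v <- numeric(L); v[1L] <- eps[1L]
    for (t in seq_len(L - 1L)) v[t + 1L] <- phi * v[t] + eps[t + 1L]
    return(rp_series(v, dt, label, is_increment = TRUE))
  }
  if (kind == "logistic_map") {
    r <- grab("r", 4); x0 <- grab("x0", 0.2)
    v <- numeric(L); v[1L] <- x0
    for (t in seq_len(L - 1L)) v[t + 1L] <- r * v[t] * (1 - v[t])
    return(rp_series(v, dt, label, is_increment = TRUE))
  }
  if (kind == "sine") {
    period <- grab("period", 13 * pi); amp <- grab("amplitude", 1)
    phase <- grab("phase", 0); noise_sd <- grab("noise_sd", 0)
    v <- amp * sin(2 * pi * seq_len(L) / period + phase)
    if (noise_sd > 0) v <- v + with_seed(seed, noise_sd * stats::rnorm(L))
    return(rp_series(v, dt, label, is_increment = TRUE))
  }
  if (kind %in% c("regime_change", "oscillation_window")) {
    sd <- grab("sd", 1)
    start <- grab("window_start", max(1L, round(0.4 * L)))
    width <- grab("window_width", max(1L, round(0.1 * L)))
    if (!is_count(start) || !is_count(width) || start + width - 1L > L)
      stop_rp("rp_config_error", "anomaly window must fit inside the series")
    start <- as.integer(start); width <- as.integer(width)
    win <- start:(start + width - 1L)
    v <- with_seed(seed, sd * stats::rnorm(L))
    if (kind == "regime_change") {
      shift <- grab("shift", 4); var_factor <- grab("var_factor", 1)
      v[win] <- v[win] * sqrt(var_factor) + shift * sd
    } else {
      osc_amp <- grab("osc_amplitude", 0.3 * sd)
      osc_period <- grab("osc_period", 10)
      resid_sd <- grab("resid_sd", 0.1 * sd)
      v[win] <- osc_amp * sin(2 * pi * seq_along(win) / osc_period) +
        resid_sd / sd * v[win]
    }
    out <- rp_series(v, dt, label, is_increment = TRUE)
    attr(out, "truth") <- list(window_start = start,
                               window_end = start + width - 1L,
                               midpoint = start + (width - 1L) / 2)
    return(out)
  }
  # md_like_counts
  regime <- grab("regime", "hbo")
  preset <- switch(regime,
    hbo    = list(n_inf = 115, noise_sd = 10),
    pw_hbo = list(n_inf = 9000, noise_sd = 80),
    hp     = list(n_inf = 67, noise_sd = 7),
    stop_rp("rp_config_error",
            sprintf("unknown regime '%s' (hbo, pw_hbo, hp)", regime)))
  n_inf <- grab("n_inf", preset$n_inf)
  noise_sd <- grab("noise_sd", preset$noise_sd)
  rise_frac <- grab("rise_frac", 0.5)   # starting level, fraction of plateau
  t_rise <- grab("t_rise", 0.1 * L)     # rise time constant, samples
  t <- seq_len(L)
  trend <- n_inf * (1 - rise_frac * exp(-t / t_rise))
  v <- with_seed(seed, pmax(0, round(trend + noise_sd * stats::rnorm(L))))
  rp_series(v, dt, paste0(label, "_", regime), is_increment = FALSE)
}
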