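#' Delay-embed a series into sub-series
#'
#' Compresses an `L`-long series into `L - d*tau` sub-series
#' `y_i = (x_i, x_{i+tau}, ..., x_{i+d*tau})`, each of length `d + 1`
#' (both endpoints included). Note the off-by-one relative to the common
#' embedding-literature convention, where the "embedding dimension" `m` is
#' the vector length: here `m = d + 1`. [cao_dimension()] returns the
#' conventional `m`; the pipeline converts with `d = m - 1`.
#'
#' @param series An [rp_series()].
#' @param tau Positive integer delay, in sample steps.
#' @param dim Non-negative integer embedding dimension `d`; sub-series have
#'   `dim + 1` points. `dim = 0` is the degenerate identity embedding.
#' @return An object of class `rp_embedding`: list with `Y` (matrix, one
#'   sub-series per row), `tau`, `dim`, `source_length`, `dt`, `label`.
#' @examples
#' embed_series(rp_series(c(1, 1/2, 1, 1/2, 1)), tau = 2, dim = 1)$Y
#' @export
embed_series <- function(series, tau, dim) {
  stopifnot(inherits(series, "rp_series"))
  if (!is_count(tau))
    stop_rp("rp_config_error", "'tau' must be a positive integer")
  if (!(length(dim) == 1L && is.finite(dim) && dim >= 0 && dim == floor(dim)))
    stop_rp("rp_config_error", "'dim' must be a non-negative integer")
  x <- series$values
  L <- length(x)
  n <- L - dim * tau
  if (n < 2L)
    stop_rp("rp_embedding_length_error",
            sprintf("series of length %d too short for dim=%d, tau=%d (need L - dim*tau >= 2)",
                    L, dim, tau))
  Y <- vapply(0:dim, function(j) x[seq_len(n) + j * tau], numeric(n))
  if (is.null(base::dim(Y))) Y <- matrix(Y, nrow = n)
  structure(
    list(Y = Y, tau = as.integer(tau), dim = as.integer(dim),
         source_length = L, dt = series$dt, label = series$label),
    class = "rp_embedding"
  )
}

#' @export
print.rp_embedding <- function(x, ...) {
  cat(sprintf("<rp_embedding> %s: %d sub-series of length %d (tau=%d, d=%d, L=%d)\n",
              x$label, nrow(x$Y), ncol(x$Y), x$tau, x$dim, x$source_length))
  invisible(x)
}

#' Delay time by the first non-significant autocorrelation
#'
#' Returns the smallest lag `h >= 1` whose sample autocorrelation falls
#' inside the large-sample white-noise band `+/- z_{1-alpha/2} / sqrt(L)`.
#' If no lag up to `floor(L/2)` qualifies, `floor(L/2)` is returned with
#' attribute `saturated = TRUE` and a warning.
#'
#' @param series An [rp_series()] with at least 10 points and nonzero
#'   variance.
#' @param alpha Significance level for the white-noise band (default 0.05).
#' @return Integer delay `tau`, with attributes `band` (the significance
#'   band), `acf` (sample autocorrelations at lags `1..max_lag`) and
#'   `saturated`.
#' @export
select_delay <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "rp_series"))
  x <- series$values
  L <- length(x)
  if (L < 10L)
    stop_rp("rp_insufficient_data_error", "need at least 10 points to estimate the ACF")
  if (stats::var(x) == 0)
    stop_rp("rp_degenerate_series_error", "series has zero variance")
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop_rp("rp_config_error", "'alpha' must be in (0, 1)")
  max_lag <- L %/% 2L
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  band <- stats::qnorm(1 - alpha / 2) / sqrt(L)
  inside <- which(abs(rho) < band)
  saturated <- length(inside) == 0L
  tau <- if (saturated) max_lag else inside[1L]
  if (saturated)
    warn_rp("rp_delay_saturated",
            sprintf("no non-significant autocorrelation up to lag %d; returning %d",
                    max_lag, max_lag))
  structure(as.integer(tau), band = band, acf = rho, saturated = saturated)
}

#' Minimum embedding dimension by the Cao method
#'
#' Computes Cao's `E1(m) = E(m+1)/E(m)`, where `E(m)` averages, over all
#' reconstructed vectors of length `m`, the ratio of the maximum-norm
#' distance between a vector and its nearest neighbour at length `m + 1` to
#' the same distance at length `m`. The returned dimension is the smallest
#' `m` with `|E1(m) - 1| <= e1_tol` and `|E1(m+1) - 1| <= e1_tol`. This is
#' the conventional embedding dimension (vector length); the corresponding
#' sub-series parameter for [embed_series()] is `d = m - 1`.
#'
#' Cao's stochasticity diagnostic `E2(m)` is reported alongside: for
#' deterministic series `E2` departs from 1 at some `m`, for noise it stays
#' near 1 for all `m`. The `noise` attribute is `TRUE` when `E1` never
#' saturates within `max_dim` or when `max |E2 - 1| <= e2_tol`.
#'
#' Nearest neighbours at zero distance (duplicate points) are excluded; an
#' error is raised only if every distance is zero.
#'
#' @param series An [rp_series()].
#' @param tau Positive integer delay (see [select_delay()]).
#' @param max_dim Largest dimension scanned (default 10).
#' @param e1_tol Saturation tolerance on `|E1 - 1|` (default 0.05).
#' @param e2_tol Stochasticity tolerance on `max |E2 - 1|` (default 0.1).
#' @return Integer dimension with attributes `E1`, `E2`, `E` and `noise`.
#' @export
cao_dimension <- function(series, tau, max_dim = 10L, e1_tol = 0.05,
                          e2_tol = 0.1) {
  stopifnot(inherits(series, "rp_series"))
  if (!is_count(tau)) stop_rp("rp_config_error", "'tau' must be a positive integer")
  if (!is_count(max_dim) || max_dim < 2)
    stop_rp("rp_config_error", "'max_dim' must be an integer >= 2")
  x <- series$values
  L <- length(x)
  # E1(max_dim) and its successor need vectors up to length max_dim + 2
  if (L - (max_dim + 1L) * tau < 2L)
    stop_rp("rp_embedding_length_error",
            sprintf("series of length %d too short for max_dim=%d at tau=%d",
                    L, max_dim, tau))
  nd <- max_dim + 1L              # E(m) computed for m = 1..max_dim+1
  E <- numeric(nd)
  Estar <- numeric(nd)
  for (m in seq_len(nd)) {
    n1 <- L - m * tau             # vectors that extend to length m + 1
    idx <- seq_len(n1)
    # max-norm distance matrix among length-m vectors, built incrementally
    D <- matrix(0, n1, n1)
    for (j in 0:(m - 1L)) {
      cj <- x[idx + j * tau]
      D <- pmax(D, abs(outer(cj, cj, "-")))
    }
    diag(D) <- Inf
    D[D == 0] <- Inf              # exclude duplicate points
    if (all(!is.finite(D)))
      stop_rp("rp_degenerate_series_error",
              "all pairwise distances are zero; cannot run the Cao method")
    nn <- max.col(-D, ties.method = "first")
    dm <- D[cbind(idx, nn)]
    ext <- abs(x[idx + m * tau] - x[nn + m * tau])
    dm1 <- pmax(dm, ext)
    ok <- is.finite(dm)
    E[m] <- mean(dm1[ok] / dm[ok])
    Estar[m] <- mean(ext[ok])
  }
  E1 <- E[-1L] / E[-nd]           # E1(m), m = 1..max_dim
  E2 <- Estar[-1L] / Estar[-nd]
  sat <- abs(E1 - 1) <= e1_tol
  hit <- which(sat[-length(sat)] & sat[-1L])   # E1(m) and E1(m+1) both flat
  saturated <- length(hit) > 0L
  m_sel <- if (saturated) hit[1L] else as.integer(max_dim)
  noise <- !saturated || max(abs(E2 - 1)) <= e2_tol
  structure(as.integer(m_sel), E1 = E1, E2 = E2, E = E, noise = noise,
            saturated = saturated)
}

#' Majority vote over per-series parameter candidates
#'
#' Modal value; ties are broken toward the smallest value (biasing toward
#' less compression).
#'
#' @param candidates Non-empty vector of integers.
#' @return The winning integer.
#' @examples
#' majority_vote(c(2, 2, 3, 1, 2))  # 2
#' majority_vote(c(1, 2))           # 1
#' @export
majority_vote <- function(candidates) {
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L || anyNA(candidates))
    stop_rp("rp_empty_input_error", "'candidates' must be a non-empty integer vector")
  tab <- table(candidates)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}
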