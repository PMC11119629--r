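#' Column weights of a recurrence matrix
#'
#' Step (a) of cross detection: `w_i` sums the entries of column `i`. With
#' `polarity = "dark"` the ones (non-recurrent pixels) are counted, so a
#' dark cross — a full-height black band — shows up as a bump in `w`. With
#' `polarity = "white"` the zeros are counted instead (the stated
#' generalization to white crosses). Dark and white weights sum to the
#' matrix side elementwise.
#'
#' @param M An [recurrence_matrix()] result.
#' @param polarity `"dark"` or `"white"`.
#' @return Numeric weight vector with attribute `polarity`.
#' @export
column_weights <- function(M, polarity = c("dark", "white")) {
  stopifnot(inherits(M, "rp_matrix"))
  polarity <- match.arg(polarity)
  w <- colSums(M$M)
  if (polarity == "white") w <- nrow(M$M) - w
  structure(as.numeric(w), polarity = polarity)
}

#' Simple moving average with truncated edge windows
#'
#' Centered window of `k` points; near the edges the window is truncated to
#' the available points, so the output length equals the input length and
#' index/time alignment survives. For even `k` the window spans `k` points
#' right-biased by one (offsets `-(k/2 - 1) .. k/2`).
#'
#' @param w Numeric vector.
#' @param k Window size, `1 <= k <= length(w)`.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_sma <- function(w, k) {
  w <- as.numeric(w)
  n <- length(w)
  if (!is_count(k) || k > n)
    stop_rp("rp_config_error", sprintf("'k' must be an integer in 1..%d", n))
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  cs <- cumsum(c(0, w))
  lo <- pmax(1L, seq_len(n) - left)
  hi <- pmin(n, seq_len(n) + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Standardize a weight vector to z-scores
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor `n`). A constant vector is a degenerate signal: detection
#' should report no crosses rather than fail, so this raises a classed
#' error (`rp_degenerate_vector`) that [detect_crosses()] converts into an
#' empty result.
#'
#' @param w Numeric vector with nonzero variance.
#' @return Standardized vector (mean 0, population SD 1).
#' @export
standardize_weights <- function(w) {
  w <- as.numeric(w)
  s <- sqrt(mean((w - mean(w))^2))
  if (!is.finite(s) || s == 0)
    stop_rp("rp_degenerate_vector", "constant weight vector: no structure to standardize")
  (w - mean(w)) / s
}

#' Cross width selection by maximizing the peak standardized weight
#'
#' Picks the smoothing window `k = argmax_k max( standardized SMA_k(w) )`
#' over the candidate grid; the selected `k` is interpreted as the cross
#' width. Ties break toward the smallest `k`. The argmax has no stated
#' search range; the pipeline default caps the grid at a quarter of the plot
#' side so the moving average cannot span unrelated regions.
#'
#' @param w Weight vector (see [column_weights()]).
#' @param k_grid Candidate window sizes, all within `1..length(w)`.
#' @return Selected `k`, with attribute `objective` (the per-candidate
#'   maxima).
#' @export
select_k <- function(w, k_grid) {
  w <- as.numeric(w)
  if (!length(k_grid))
    stop_rp("rp_config_error", "'k_grid' must be non-empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L | k_grid > length(w)))
    stop_rp("rp_config_error", "'k_grid' values must lie in 1..length(w)")
  obj <- vapply(k_grid, function(k) {
    z <- tryCatch(standardize_weights(smooth_sma(w, k)),
                  rp_degenerate_vector = function(e) NULL)
    if (is.null(z)) -Inf else max(z)
  }, numeric(1))
  if (all(!is.finite(obj)))
    stop_rp("rp_no_structure_error", "all candidate windows give constant weights")
  k <- k_grid[which.max(obj)]             # first maximum = smallest k on ties
  structure(k, objective = stats::setNames(obj, k_grid))
}

# Local maxima of a vector: strict maxima, plateaus contribute their
# midpoint, edges qualify against their single neighbour.
local_maxima <- function(z) {
  n <- length(z)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && z[j + 1L] == z[i]) j <- j + 1L
    lower_l <- i == 1L || z[i - 1L] < z[i]
    lower_r <- j == n || z[j + 1L] < z[i]
    if (lower_l && lower_r && !(i == 1L && j == n))
      out <- c(out, (i + j) %/% 2L)
    i <- j + 1L
  }
  out
}

#' Detect dark or white crosses on a recurrence plot
#'
#' Automates the visual identification of cross patterns: (a) column
#' weights for the requested polarity, (b) simple-moving-average smoothing,
#' (c) standardization to z-scores, (d) width selection `k` by
#' [select_k()], then cross centers as local maxima of the standardized
#' smoothed vector exceeding `threshold_sigma`, greedily thinned in
#' descending score order so surviving centers are at least `k` apart.
#'
#' A dark cross marks a time window whose dynamics differ from the rest of
#' the series (the embedded states there are far from everything else); a
#' white cross marks a window of locally stabilized dynamics. Detecting
#' white crosses on `M` is identical to detecting dark crosses on the
#' elementwise-complemented matrix.
#'
#' @param M An [recurrence_matrix()] result.
#' @param threshold_sigma Positive detection threshold in standard scores
#'   (default 2.5; 2 and 3 are reasonable alternatives).
#' @param polarity `"dark"` or `"white"`.
#' @param k_grid Candidate widths; default `1:max(1, floor(side/4))`.
#' @return An object of class `rp_crosses`: list with `k`, `centers`
#'   (column indices, in embedded sub-series space), `center_scores`,
#'   `threshold_sigma`, `polarity`, `side`, `zscores` (the standardized
#'   smoothed vector at the selected `k`), `no_structure`, plus `dt` and
#'   `label` carried from the matrix.
#' @export
detect_crosses <- function(M, threshold_sigma = 2.5,
                           polarity = c("dark", "white"), k_grid = NULL) {
  stopifnot(inherits(M, "rp_matrix"))
  polarity <- match.arg(polarity)
  if (!is.numeric(threshold_sigma) || length(threshold_sigma) != 1L ||
      !is.finite(threshold_sigma) || threshold_sigma <= 0)
    stop_rp("rp_config_error", "'threshold_sigma' must be a positive scalar")
  n <- nrow(M$M)
  if (is.null(k_grid)) k_grid <- seq_len(max(1L, n %/% 4L))
  w <- column_weights(M, polarity)
  empty <- function(flag) structure(
    list(k = NA_integer_, centers = integer(0), center_scores = numeric(0),
         threshold_sigma = threshold_sigma, polarity = polarity, side = n,
         zscores = NULL, no_structure = flag, dt = M$dt, label = M$label),
    class = "rp_crosses")
  k <- tryCatch(select_k(w, k_grid),
                rp_no_structure_error = function(e) NULL)
  if (is.null(k)) return(empty(TRUE))
  z <- standardize_weights(smooth_sma(w, k))
  cand <- local_maxima(z)
  cand <- cand[z[cand] > threshold_sigma]
  cand <- cand[order(-z[cand], cand)]     # score-descending, index tie-break
  keep <- integer(0)
  for (ce in cand)
    if (!length(keep) || all(abs(keep - ce) >= k)) keep <- c(keep, ce)
  keep <- sort(keep)
  structure(
    list(k = as.integer(k), centers = keep, center_scores = z[keep],
         threshold_sigma = threshold_sigma, polarity = polarity, side = n,
         zscores = z, no_structure = FALSE, dt = M$dt, label = M$label),
    class = "rp_crosses"
  )
}

#' @export
print.rp_crosses <- function(x, ...) {
  cat(sprintf("<rp_crosses> %s: %s polarity, threshold %.2f sigma\n",
              x$label, x$polarity, x$threshold_sigma))
  if (isTRUE(x$no_structure)) {
    cat("  no structure (degenerate weights)\n")
  } else if (!length(x$centers)) {
    cat(sprintf("  no crosses (width k = %d)\n", x$k))
  } else {
    cat(sprintf("  %d cross(es), width k = %d:\n", length(x$centers), x$k))
    print(as.data.frame(x))
  }
  invisible(x)
}

#' @describeIn detect_crosses Tabulate detected crosses (center index,
#'   center time, width, z-score, polarity) for delimited-text export.
#' @param x An `rp_crosses` result.
#' @param ... Ignored.
#' @export
as.data.frame.rp_crosses <- function(x, ...) {
  data.frame(
    center = x$centers,
    time = (x$centers - 1) * (if (is.null(x$dt)) 1 else x$dt),
    width_k = rep(if (length(x$centers)) x$k else integer(0), length(x$centers)),
    zscore = as.numeric(x$center_scores),
    polarity = rep(x$polarity, length(x$centers))
  )
}
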