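#' Histogram of diagonal recurrent-run lengths
#'
#' Collects, for every diagonal of the recurrence matrix parallel to the
#' main diagonal — excluding the main diagonal itself (the line of identity,
#' where every state trivially recurs) — the lengths of maximal runs of
#' consecutive zeros (recurrent entries). Both triangles are counted; the
#' matrix is symmetric, so every off-diagonal run appears twice.
#'
#' @param M An [recurrence_matrix()] result.
#' @return An object of class `rp_runs`: list with `counts` (named integer
#'   vector, names are run lengths), `total` and `excluded_loi = TRUE`. The
#'   histogram may be empty when no off-diagonal zeros exist.
#' @export
diagonal_runs <- function(M) {
  stopifnot(inherits(M, "rp_matrix"))
  m <- M$M
  n <- nrow(m)
  # gather upper-triangle entries grouped by diagonal offset, in order
  lens <- integer(0)
  for (off in seq_len(n - 1L)) {
    i <- seq_len(n - off)
    v <- m[cbind(i, i + off)]
    r <- rle(v == 0L)
    lens <- c(lens, r$lengths[r$values])
  }
  counts <- integer(0)
  if (length(lens)) {
    tab <- table(lens)
    counts <- as.integer(tab) * 2L          # symmetric: both triangles
    names(counts) <- names(tab)
  }
  structure(
    list(counts = counts, total = sum(counts), excluded_loi = TRUE),
    class = "rp_runs"
  )
}

#' @export
print.rp_runs <- function(x, ...) {
  if (x$total == 0L) {
    cat("<rp_runs> empty histogram (no off-diagonal recurrent runs)\n")
  } else {
    cat("<rp_runs> run lengths (line of identity excluded):\n")
    print(x$counts)
  }
  invisible(x)
}

#' Shannon entropy of diagonal-line lengths
#'
#' `S = -sum_j p_j log(p_j)` in nats, where `p_j` is the normalized
#' frequency of recurrent runs of length `j`. An empty histogram has no
#' defined entropy (distinct from `S = 0`, which means a single run-length
#' class) and raises an error.
#'
#' @param hist An [diagonal_runs()] result, or a bare vector of counts.
#' @return Non-negative entropy in nats.
#' @examples
#' shannon_entropy(c(`1` = 2, `2` = 2))  # log(2)
#' @export
shannon_entropy <- function(hist) {
  counts <- if (inherits(hist, "rp_runs")) hist$counts else hist
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) == 0)
    stop_rp("rp_undefined_entropy_error",
            "empty run histogram: entropy undefined (not zero)")
  p <- counts / sum(counts)
  max(0, -sum(p * log(p)))   # max() guards the -0 of a single class
}

#' Default recurrence-rate grid
#'
#' 30 logarithmically spaced target rates from 0.01 to 1.
#' @param n Number of grid points.
#' @param lo,hi Grid end points in (0, 1].
#' @return Increasing numeric vector.
#' @export
default_rate_grid <- function(n = 30L, lo = 0.01, hi = 1) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Scan diagonal-line entropy over the recurrence rate
#'
#' For each target recurrence rate in the grid: derive the threshold with
#' [lambda_for_rate()], build the recurrence matrix, histogram diagonal
#' runs, and compute the Shannon entropy. Rates whose histogram is empty are
#' recorded with `NA` entropy.
#'
#' @param series An [rp_series()] (typically increments).
#' @param tau,dim Embedding parameters (sub-series length `dim + 1`, see
#'   [embed_series()]).
#' @param rate_grid Increasing vector of target rates in (0, 1].
#' @param norm Distance norm, see [pairwise_distances()].
#' @return An object of class `rp_scan`: a data frame with columns
#'   `target_rate`, `achieved_rate`, `lambda`, `entropy`, plus attribute
#'   `label`.
#' @export
entropy_scan <- function(series, tau, dim, rate_grid = default_rate_grid(),
                         norm = "euclidean") {
  stopifnot(inherits(series, "rp_series"))
  if (length(rate_grid) < 1L || any(!is.finite(rate_grid)) ||
      any(rate_grid <= 0 | rate_grid > 1) || is.unsorted(rate_grid, strictly = TRUE))
    stop_rp("rp_config_error",
            "'rate_grid' must be strictly increasing within (0, 1]")
  emb <- embed_series(series, tau, dim)
  dst <- pairwise_distances(emb, norm)
  rows <- lapply(rate_grid, function(r) {
    lam <- suppressWarnings(lambda_for_rate(dst, r))
    M <- recurrence_matrix(dst, lam)
    h <- diagonal_runs(M)
    S <- if (h$total > 0) shannon_entropy(h) else NA_real_
    data.frame(target_rate = r, achieved_rate = attr(lam, "achieved_rate"),
               lambda = as.numeric(lam), entropy = S)
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- series$label
  class(out) <- c("rp_scan", "data.frame")
  out
}

#' @describeIn entropy_scan Log–log plot of entropy against achieved
#'   recurrence rate, with an optional selected working rate marked by a
#'   dashed line.
#' @param x An `rp_scan`.
#' @param selected_rate Optional rate to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rp_scan <- function(x, selected_rate = NULL, ...) {
  ok <- is.finite(x$entropy) & x$entropy > 0
  graphics::plot(x$achieved_rate[ok], x$entropy[ok], log = "xy",
                 xlab = "recurrence rate", ylab = "entropy S (nats)",
                 type = "b", ...)
  if (!is.null(selected_rate))
    graphics::abline(v = selected_rate, lty = 2)
  invisible(x)
}

# Continuous two-segment least-squares fit in log-log space with the hinge
# at interior grid point j; returns total SSE.
hinge_sse <- function(lx, ly, j) {
  X <- cbind(1, lx, pmax(lx - lx[j], 0))
  fit <- stats::lm.fit(X, ly)
  sum(fit$residuals^2)
}

#' Select the working recurrence rate at the edge of log–log linearity
#'
#' Per scan, on the `(log achieved_rate, log S)` points, fits every
#' continuous two-segment piecewise-linear model with the breakpoint at an
#' interior grid point and keeps the breakpoint minimizing the total squared
#' error (ties toward the smaller rate). Across several scans, the final
#' working rate is chosen by majority vote on the breakpoint grid index
#' (ties toward the smaller rate). Points with missing or non-positive
#' entropy are excluded from the logs with a warning.
#'
#' When the best two-segment fit improves on a single straight line by less
#' than 1% of its SSE, the scan is flagged `no_edge` (degenerate: the
#' breakpoint is then just the SSE tie-break).
#'
#' @param scans An `rp_scan` or a list of them, sharing a rate grid.
#' @return Working rate (numeric), with attributes `index` (grid index of
#'   the vote winner), `per_scan` (per-scan breakpoint indices) and
#'   `no_edge` (per-scan logical).
#' @export
select_rate <- function(scans) {
  if (inherits(scans, "rp_scan")) scans <- list(scans)
  if (!length(scans) || !all(vapply(scans, inherits, TRUE, "rp_scan")))
    stop_rp("rp_config_error", "'scans' must be rp_scan objects")
  picks <- integer(0)
  no_edge <- logical(0)
  for (sc in scans) {
    ok <- is.finite(sc$entropy) & sc$entropy > 0 & sc$achieved_rate > 0
    if (sum(!ok) > 0)
      warn_rp("rp_scan_dropped_points",
              sprintf("%d scan point(s) with undefined or non-positive entropy excluded",
                      sum(!ok)))
    if (sum(ok) < 5L)
      stop_rp("rp_insufficient_scan_error",
              "need at least 5 valid scan points for breakpoint selection")
    idx_ok <- which(ok)
    lx <- log(sc$achieved_rate[ok])
    ly <- log(sc$entropy[ok])
    nn <- length(lx)
    cand <- 2:(nn - 1L)
    sse <- vapply(cand, function(j) hinge_sse(lx, ly, j), numeric(1))
    best <- cand[which.min(sse)]          # which.min takes the first minimum
    sse_line <- sum(stats::lm.fit(cbind(1, lx), ly)$residuals^2)
    flat <- sse_line <= 1e-12 || (sse_line - min(sse)) / sse_line < 0.01
    picks <- c(picks, idx_ok[best])
    no_edge <- c(no_edge, flat)
  }
  win <- majority_vote(picks)
  rate <- scans[[1L]]$target_rate[win]
  structure(rate, index = win, per_scan = picks, no_edge = no_edge)
}
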