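#' Pairwise distances between embedded sub-series
#'
#' Square symmetric matrix of distances between all pairs of delay
#' sub-series. The Euclidean norm is the default; the maximum norm is
#' available. The original method statement leaves the norm open — the two
#' cannot be distinguished on the worked 5-point example — so this follows
#' the common default of recurrence-plot software.
#'
#' @param emb An [embed_series()] result.
#' @param norm `"euclidean"` or `"maximum"`.
#' @return An object of class `rp_dist`: list with `D` (matrix), `norm`,
#'   plus embedding metadata carried through.
#' @export
pairwise_distances <- function(emb, norm = c("euclidean", "maximum")) {
  stopifnot(inherits(emb, "rp_embedding"))
  if (!is.character(norm) || !norm[1L] %in% c("euclidean", "maximum"))
    stop_rp("rp_config_error", "'norm' must be \"euclidean\" or \"maximum\"")
  norm <- norm[1L]
  if (nrow(emb$Y) < 2L)
    stop_rp("rp_embedding_length_error", "need at least 2 sub-series")
  D <- as.matrix(stats::dist(emb$Y, method = norm))
  dimnames(D) <- NULL
  structure(
    list(D = D, norm = norm, tau = emb$tau, dim = emb$dim,
         dt = emb$dt, label = emb$label),
    class = "rp_dist"
  )
}

#' Threshold a distance matrix into a binary recurrence matrix
#'
#' Entry `m[i, i'] = 0` if the distance between sub-series `i` and `i'` is
#' at most `lambda`, and 1 elsewhere. Note the inverted convention relative
#' to most recurrence-quantification literature: here **0 marks recurrence**
#' (rendered white), 1 marks non-recurrence (rendered black). The recurrence
#' rate is the fraction of zeros over all entries, main diagonal included.
#'
#' @param dist An [pairwise_distances()] result.
#' @param lambda Non-negative threshold.
#' @return An object of class `rp_matrix`: list with `M` (integer matrix),
#'   `lambda`, `recurrence_rate`, `norm`, and embedding metadata.
#' @export
recurrence_matrix <- function(dist, lambda) {
  stopifnot(inherits(dist, "rp_dist"))
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop_rp("rp_config_error", "'lambda' must be a finite scalar >= 0")
  M <- (dist$D > lambda) * 1L
  storage.mode(M) <- "integer"
  structure(
    list(M = M, lambda = as.numeric(lambda),
         recurrence_rate = mean(M == 0L),
         norm = dist$norm, tau = dist$tau, dim = dist$dim,
         dt = dist$dt, label = dist$label),
    class = "rp_matrix"
  )
}

#' @export
print.rp_matrix <- function(x, ...) {
  cat(sprintf("<rp_matrix> %s: %dx%d, lambda = %.4g, recurrence rate = %.4g (0 = recurrent)\n",
              x$label, nrow(x$M), ncol(x$M), x$lambda, x$recurrence_rate))
  invisible(x)
}

#' Threshold attaining a target recurrence rate
#'
#' Smallest distance value `q` such that the fraction of all matrix entries
#' (main diagonal included) at most `q` reaches `target_rate` — the
#' empirical quantile of the full entry multiset. The achieved rate is
#' reported as an attribute; it equals the target whenever the target is
#' attainable on the discrete distance multiset, and exceeds it otherwise.
#' Targets below the attainable minimum `side / side^2` (the always-zero
#' diagonal) are clamped to that minimum with a warning.
#'
#' @param dist An [pairwise_distances()] result.
#' @param target_rate Fraction in (0, 1].
#' @return Threshold `lambda`, with attribute `achieved_rate`.
#' @export
lambda_for_rate <- function(dist, target_rate) {
  stopifnot(inherits(dist, "rp_dist"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      !is.finite(target_rate) || target_rate <= 0 || target_rate > 1)
    stop_rp("rp_config_error", "'target_rate' must lie in (0, 1]")
  n <- nrow(dist$D)
  total <- as.numeric(n)^2
  if (target_rate < n / total) {
    warn_rp("rp_rate_clamped",
            sprintf("target rate %.4g below attainable minimum %.4g; clamped",
                    target_rate, n / total))
    target_rate <- n / total
  }
  # off-diagonal distances appear twice, the diagonal contributes n zeros.
  # The epsilon guards exact rational targets (e.g. 5/9 on a 3x3 matrix)
  # against upward float rounding of target * total.
  half <- sort(dist$D[upper.tri(dist$D)])
  need <- ceiling(target_rate * total - n - 1e-9 * total)  # count among 2*half
  if (need <= 0) {
    lambda <- 0
  } else {
    i <- ceiling(need / 2)
    lambda <- half[i]
  }
  cnt <- n + 2 * sum(half <= lambda)
  structure(lambda, achieved_rate = cnt / total)
}

# PNG image sizes are parsed back in tests; keep 1 entry = `scale` pixels.

#' Render a recurrence plot to a PNG file
#'
#' One pixel block per matrix entry: 1 (non-recurrent) is black, 0
#' (recurrent) is white — the inverted colour convention of this pipeline.
#' Row 1 sits at the top-left corner and the main diagonal runs to the
#' bottom-right. Detected crosses can be overlaid as green bounding lines.
#'
#' @param M An [recurrence_matrix()] result.
#' @param path Output PNG path.
#' @param crosses Optional [detect_crosses()] result to overlay.
#' @param scale Integer upscale factor (pixels per matrix entry).
#' @param invert If `TRUE`, flip the colour convention for rendering only;
#'   the analysis convention never changes.
#' @return `path`, invisibly.
#' @export
render_rp <- function(M, path, crosses = NULL, scale = 1L, invert = FALSE) {
  stopifnot(inherits(M, "rp_matrix"))
  if (!is_count(scale)) stop_rp("rp_config_error", "'scale' must be a positive integer")
  if (!dir.exists(dirname(path)))
    stop_rp("rp_io_error", sprintf("directory does not exist: %s", dirname(path)))
  n <- nrow(M$M)
  ok <- tryCatch({
    grDevices::png(path, width = n * scale, height = n * scale)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_rp("rp_io_error", sprintf("could not open PNG device for %s", path))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, n), ylim = c(0, n))
  draw_rp(M, crosses, invert)
  invisible(path)
}

# Shared raster drawing for render_rp() and plot methods. Coordinates:
# column i in [i-1, i], row 1 at the top.
draw_rp <- function(M, crosses = NULL, invert = FALSE) {
  m <- M$M
  cols <- if (invert) c("black", "white") else c("white", "black")
  ras <- grDevices::as.raster(matrix(cols[m + 1L], nrow = nrow(m)))
  n <- nrow(m)
  graphics::rasterImage(ras, 0, 0, n, n, interpolate = FALSE)
  if (!is.null(crosses) && length(crosses$centers)) {
    k <- crosses$k
    for (ce in crosses$centers) {
      lo <- max(0, ce - 1 - (k - 1) / 2)
      hi <- min(n, ce + (k - 1) / 2)
      graphics::abline(v = c(lo, hi), col = "green", lwd = 2)
      graphics::abline(h = c(n - lo, n - hi), col = "green", lwd = 2)
    }
  }
  invisible(NULL)
}

#' @describeIn recurrence_matrix Plot a recurrence matrix on the current
#'   device, optionally overlaying detected crosses.
#' @param x An `rp_matrix`.
#' @param crosses Optional [detect_crosses()] result.
#' @param invert Flip rendering colours only.
#' @param ... Ignored.
#' @export
plot.rp_matrix <- function(x, crosses = NULL, invert = FALSE, ...) {
  n <- nrow(x$M)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, n), ylim = c(0, n), asp = 1)
  draw_rp(x, crosses, invert)
  graphics::title(main = sprintf("%s  (RR = %.3g, lambda = %.3g)",
                                 x$label, x$recurrence_rate, x$lambda))
  invisible(x)
}
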