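#' Fit a recurrence-plot analysis to one series
#'
#' The end-to-end workflow on a single series: increment transformation
#' (unless the input already is increments), delay selection by the first
#' non-significant autocorrelation, embedding dimension by the Cao method,
#' delay embedding, entropy scan over the recurrence-rate grid, selection of
#' the working rate at the edge of log–log linearity, recurrence matrix at
#' that rate, diagonal-line entropy, and dark (optionally white) cross
#' detection. Any stage can be pinned by supplying its parameter.
#'
#' @param x An [rp_series()], or a numeric vector (wrapped with `dt = 1`).
#' @param tau Delay; `NULL` to select via [select_delay()].
#' @param dim Embedding dimension `d` (sub-series length `d + 1`); `NULL` to
#'   select via [cao_dimension()] (`d = m - 1` from the conventional Cao
#'   dimension `m`, floored at 1).
#' @param rate Working recurrence rate; `NULL` to select via
#'   [select_rate()] on the scan.
#' @param alpha Significance level for delay selection.
#' @param max_dim,e1_tol Cao method controls, see [cao_dimension()].
#' @param norm Distance norm, see [pairwise_distances()].
#' @param rate_grid Grid for the entropy scan, see [entropy_scan()].
#' @param threshold_sigma Cross-detection threshold in standard scores.
#' @param polarity Character vector of polarities to detect
#'   (`"dark"`, `"white"`).
#' @param k_grid Candidate cross widths; `NULL` for `1:floor(side/4)`.
#' @param scan If `FALSE`, skip the entropy scan (then `rate` must be
#'   given).
#' @return An object of class `rpa`: list with `series` (the analyzed
#'   increment series), `tau`, `dim`, `cao_noise`, `scan`, `rate`,
#'   `achieved_rate`, `lambda`, `matrix`, `entropy` (`NA` if the run
#'   histogram is empty), `crosses` (named list by polarity), `call`.
#' @examples
#' fit <- rpa(toy_vector(), tau = 2, dim = 1, rate = 5/9,
#'            threshold_sigma = 1.0, k_grid = 1)
#' fit$entropy                  # 0
#' fit$crosses$dark$centers     # 2
#' @export
rpa <- function(x, tau = NULL, dim = NULL, rate = NULL,
                alpha = 0.05, max_dim = 10L, e1_tol = 0.05,
                norm = "euclidean", rate_grid = default_rate_grid(),
                threshold_sigma = 2.5, polarity = "dark", k_grid = NULL,
                scan = TRUE) {
  cl <- match.call()
  if (is.numeric(x) && !inherits(x, "rp_series")) x <- rp_series(x)
  stopifnot(inherits(x, "rp_series"))
  s <- if (x$is_increment) x else increments(x)

  cao_noise <- NA
  if (is.null(tau)) tau <- as.integer(select_delay(s, alpha = alpha))
  if (is.null(dim)) {
    m <- cao_dimension(s, tau, max_dim = max_dim, e1_tol = e1_tol)
    cao_noise <- attr(m, "noise")
    dim <- max(1L, as.integer(m) - 1L)
  }

  sc <- NULL
  if (isTRUE(scan))
    sc <- entropy_scan(s, tau, dim, rate_grid = rate_grid, norm = norm)
  if (is.null(rate)) {
    if (is.null(sc))
      stop_rp("rp_config_error", "either run the scan or supply 'rate'")
    rate <- as.numeric(select_rate(sc))
  }

  emb <- embed_series(s, tau, dim)
  dst <- pairwise_distances(emb, norm)
  lam <- lambda_for_rate(dst, rate)
  M <- recurrence_matrix(dst, lam)
  h <- diagonal_runs(M)
  S <- if (h$total > 0) shannon_entropy(h) else NA_real_

  crosses <- lapply(stats::setNames(polarity, polarity), function(p)
    detect_crosses(M, threshold_sigma = threshold_sigma, polarity = p,
                   k_grid = k_grid))

  structure(
    list(series = s, input_label = x$label, tau = as.integer(tau),
         dim = as.integer(dim), cao_noise = cao_noise, scan = sc,
         rate = as.numeric(rate),
         achieved_rate = attr(lam, "achieved_rate"),
         lambda = as.numeric(lam), matrix = M, runs = h, entropy = S,
         crosses = crosses, call = cl),
    class = "rpa"
  )
}

#' @export
print.rpa <- function(x, ...) {
  cat(sprintf("Recurrence-plot analysis of '%s'\n", x$series$label))
  cat(sprintf("  L = %d increments, dt = %g\n", length(x$series$values),
              x$series$dt))
  cat(sprintf("  embedding: tau = %d, d = %d (sub-series length %d)\n",
              x$tau, x$dim, x$dim + 1L))
  cat(sprintf("  recurrence: rate = %.4g (achieved %.4g), lambda = %.4g [%s]\n",
              x$rate, x$achieved_rate, x$lambda, x$matrix$norm))
  cat(sprintf("  diagonal-line entropy S = %s nats\n",
              if (is.na(x$entropy)) "undefined" else sprintf("%.4g", x$entropy)))
  for (p in names(x$crosses)) {
    cr <- x$crosses[[p]]
    cat(sprintf("  %s crosses (>%g sigma): %s\n", p, cr$threshold_sigma,
                if (!length(cr$centers)) "none"
                else paste0("center ", paste(cr$centers, collapse = ", "),
                            " (width k = ", cr$k, ")")))
  }
  invisible(x)
}

#' @export
coef.rpa <- function(object, ...) {
  c(tau = object$tau, dim = object$dim, lambda = object$lambda,
    recurrence_rate = object$achieved_rate, entropy = object$entropy)
}

#' @export
summary.rpa <- function(object, ...) {
  structure(list(fit = object), class = "summary.rpa")
}

#' @export
print.summary.rpa <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$scan)) {
    ok <- is.finite(f$scan$entropy)
    cat(sprintf("  entropy scan: %d/%d rates with defined entropy, S range [%.3g, %.3g]\n",
                sum(ok), nrow(f$scan), min(f$scan$entropy[ok]),
                max(f$scan$entropy[ok])))
  }
  if (!is.na(f$cao_noise) && isTRUE(f$cao_noise))
    cat("  note: Cao E2 diagnostic flags this series as noise-like\n")
  for (p in names(f$crosses)) {
    df <- as.data.frame(f$crosses[[p]])
    if (nrow(df)) { cat(sprintf("  %s cross table:\n", p)); print(df) }
  }
  invisible(x)
}

#' @export
plot.rpa <- function(x, type = c("rp", "scan"), ...) {
  type <- match.arg(type)
  if (type == "rp") {
    plot(x$matrix, crosses = x$crosses[[1L]], ...)
  } else {
    if (is.null(x$scan)) stop_rp("rp_config_error", "fit has no entropy scan")
    plot(x$scan, selected_rate = x$rate, ...)
  }
  invisible(x)
}

#' Run the pipeline over several series with majority voting
#'
#' Orchestrates the multi-series workflow: per-series delay and dimension
#' estimates, majority voting to a single `(tau, d)`, per-series entropy
#' scans, majority-voted working recurrence rate, then a full [rpa()] fit of
#' every series at the voted parameters. With an output directory, writes
#' per-series recurrence-plot PNGs, scan and cross tables (CSV) and one
#' machine-readable JSON report; every voted parameter is echoed via
#' `message()` so a run is auditable.
#'
#' @param inputs List of [rp_series()] objects (convert files with
#'   [read_series()]); raw count series are differenced automatically.
#' @param rate Working rate override; `NULL` to vote via [select_rate()].
#' @param tau,dim Overrides for the voted embedding parameters.
#' @param white Also detect white crosses.
#' @param out_dir Optional output directory (created if missing).
#' @param ... Further arguments passed to [rpa()] (e.g. `alpha`,
#'   `threshold_sigma`, `norm`, `rate_grid`).
#' @return An object of class `rpa_report`: list with `tau`, `dim`, `rate`
#'   (voted values), `per_series` (per-series candidate parameters),
#'   `fits` (list of [rpa()] objects), `out_dir`.
#' @export
rpa_run <- function(inputs, rate = NULL, tau = NULL, dim = NULL,
                    white = FALSE, out_dir = NULL, ...) {
  if (inherits(inputs, "rp_series")) inputs <- list(inputs)
  if (!length(inputs) || !all(vapply(inputs, inherits, TRUE, "rp_series")))
    stop_rp("rp_config_error", "'inputs' must be a list of rp_series")
  dots <- list(...)
  alpha <- if (is.null(dots$alpha)) 0.05 else dots$alpha
  max_dim <- if (is.null(dots$max_dim)) 10L else dots$max_dim
  e1_tol <- if (is.null(dots$e1_tol)) 0.05 else dots$e1_tol
  norm <- if (is.null(dots$norm)) "euclidean" else dots$norm
  rate_grid <- if (is.null(dots$rate_grid)) default_rate_grid() else dots$rate_grid

  incr <- lapply(inputs, function(s) if (s$is_increment) s else increments(s))

  taus <- vapply(incr, function(s) as.integer(select_delay(s, alpha = alpha)),
                 integer(1))
  if (is.null(tau)) tau <- majority_vote(taus)
  message(sprintf("voted tau = %d (candidates: %s)", tau,
                  paste(taus, collapse = ", ")))
  dims <- vapply(incr, function(s)
    max(1L, as.integer(cao_dimension(s, tau, max_dim = max_dim,
                                     e1_tol = e1_tol)) - 1L), integer(1))
  if (is.null(dim)) dim <- majority_vote(dims)
  message(sprintf("voted d = %d (candidates: %s)", dim,
                  paste(dims, collapse = ", ")))

  scans <- lapply(incr, function(s)
    entropy_scan(s, tau, dim, rate_grid = rate_grid, norm = norm))
  if (is.null(rate)) rate <- as.numeric(select_rate(scans))
  message(sprintf("voted working recurrence rate = %.4g", rate))

  pol <- if (white) c("dark", "white") else "dark"
  fit_args <- dots[setdiff(names(dots),
                           c("alpha", "max_dim", "e1_tol", "norm", "rate_grid"))]
  fits <- lapply(seq_along(incr), function(i) {
    do.call(rpa, c(list(incr[[i]], tau = tau, dim = dim, rate = rate,
                        norm = norm, polarity = pol, scan = FALSE),
                   fit_args))
  })
  for (f in fits)
    message(sprintf("%s: lambda = %.4g, RR = %.4g, S = %.4g, dark crosses = %d",
                    f$series$label, f$lambda, f$achieved_rate, f$entropy,
                    length(f$crosses$dark$centers)))
  names(fits) <- vapply(fits, function(f) f$series$label, character(1))
  for (i in seq_along(fits)) fits[[i]]$scan <- scans[[i]]

  rep <- structure(
    list(tau = as.integer(tau), dim = as.integer(dim), rate = rate,
         per_series = list(tau = taus, dim = dims), fits = fits,
         out_dir = out_dir),
    class = "rpa_report"
  )
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.rpa_report <- function(x, ...) {
  cat(sprintf("<rpa_report> %d series; voted tau = %d, d = %d, rate = %.4g\n",
              length(x$fits), x$tau, x$dim, x$rate))
  for (f in x$fits)
    cat(sprintf("  %-24s S = %-8.4g dark crosses: %s\n", f$series$label,
                f$entropy, if (length(f$crosses$dark$centers))
                  paste(f$crosses$dark$centers, collapse = ", ") else "none"))
  invisible(x)
}

# Write images, tables and the JSON report for a finished multi-series run.
write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(s) gsub("[^A-Za-z0-9._-]+", "_", s)
  for (f in rep$fits) {
    base <- file.path(out_dir, safe(f$series$label))
    render_rp(f$matrix, paste0(base, "_rp.png"),
              crosses = f$crosses$dark, scale = 1L)
    if (!is.null(f$scan))
      utils::write.csv(as.data.frame(f$scan), paste0(base, "_scan.csv"),
                       row.names = FALSE)
    crs <- do.call(rbind, lapply(f$crosses, as.data.frame))
    utils::write.csv(crs, paste0(base, "_crosses.csv"), row.names = FALSE)
  }
  payload <- list(
    voted = list(tau = rep$tau, dim = rep$dim, rate = rep$rate),
    per_series = rep$per_series,
    series = lapply(rep$fits, function(f) list(
      label = f$series$label, length = length(f$series$values),
      dt = f$series$dt, lambda = f$lambda,
      achieved_rate = f$achieved_rate, entropy = f$entropy,
      crosses = lapply(f$crosses, function(cr) list(
        polarity = cr$polarity, k = cr$k, centers = cr$centers,
        zscores = as.numeric(cr$center_scores),
        threshold_sigma = cr$threshold_sigma))))
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
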