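# Independent brute-force oracles. Deliberately written as plain loops over
# definitions, sharing no code with the package internals.

naive_embed <- function(x, tau, d) {
  n <- length(x) - d * tau
  out <- matrix(NA_real_, n, d + 1)
  for (i in seq_len(n))
    for (j in 0:d)
      out[i, j + 1] <- x[i + j * tau]
  out
}

naive_recurrence_matrix <- function(Y, lambda, norm = "euclidean") {
  n <- nrow(Y)
  M <- matrix(1L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      diffs <- abs(Y[i, ] - Y[j, ])
      d <- if (norm == "euclidean") sqrt(sum(diffs^2)) else max(diffs)
      if (d <= lambda) M[i, j] <- 0L
    }
  M
}

# run-length histogram of zeros along each off-main diagonal, both triangles
naive_diagonal_runs <- function(M) {
  n <- nrow(M)
  lens <- integer(0)
  for (off in c(-(n - 1):-1, 1:(n - 1))) {
    cells <- integer(0)
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1 && j <= n) cells <- c(cells, M[i, j])
    }
    run <- 0L
    for (c0 in c(cells, 1L)) {     # sentinel closes a trailing run
      if (c0 == 0L) run <- run + 1L
      else { if (run > 0L) lens <- c(lens, run); run <- 0L }
    }
  }
  lens
}

naive_entropy <- function(lens) {
  tab <- table(lens)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p))
}

naive_sma <- function(w, k) {
  n <- length(w)
  left <- floor((k - 1) / 2)
  right <- k - 1 - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- max(1, i - left):min(n, i + right)
    out[i] <- mean(w[win])
  }
  out
}

naive_z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

naive_acf <- function(x, h) {
  xb <- mean(x)
  n <- length(x)
  sum((x[1:(n - h)] - xb) * (x[(1 + h):n] - xb)) / sum((x - xb)^2)
}

# steps (a)-(f) of cross detection, plain loops
naive_detect <- function(M, thr, polarity = "dark", k_grid = NULL) {
  n <- nrow(M)
  w <- numeric(n)
  for (i in seq_len(n))
    w[i] <- if (polarity == "dark") sum(M[, i]) else sum(M[, i] == 0)
  if (is.null(k_grid)) k_grid <- 1:max(1, floor(n / 4))
  best_k <- NA_integer_; best <- -Inf
  for (k in k_grid) {
    sm <- naive_sma(w, k)
    if (sqrt(mean((sm - mean(sm))^2)) == 0) next
    mz <- max(naive_z(sm))
    if (mz > best + 1e-12) { best <- mz; best_k <- k }
  }
  if (is.na(best_k)) return(list(k = NA_integer_, centers = integer(0)))
  z <- naive_z(naive_sma(w, best_k))
  # local maxima with plateau midpoints, edges against single neighbour
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && z[j + 1] == z[i]) j <- j + 1
    if ((i == 1 || z[i - 1] < z[i]) && (j == n || z[j + 1] < z[i]) &&
        !(i == 1 && j == n))
      cand <- c(cand, floor((i + j) / 2))
    i <- j + 1
  }
  cand <- cand[z[cand] > thr]
  cand <- cand[order(-z[cand], cand)]
  keep <- integer(0)
  for (ce in cand)
    if (length(keep) == 0 || min(abs(keep - ce)) >= best_k)
      keep <- c(keep, ce)
  list(k = best_k, centers = sort(keep), z = z)
}

# random symmetric binary matrix with zero diagonal-of-identity structure
random_rp_matrix <- function(n, p_zero = 0.3) {
  M <- matrix(1L, n, n)
  up <- which(upper.tri(M))
  M[up] <- ifelse(stats::runif(length(up)) < p_zero, 0L, 1L)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 0L
  M
}

# wrap a bare binary matrix as an rp_matrix for run/cross oracles
wrap_matrix <- function(M) {
  structure(list(M = M, lambda = NA_real_, recurrence_rate = mean(M == 0L),
                 norm = "euclidean", tau = 1L, dim = 1L, dt = 1,
                 label = "wrapped"),
            class = "rp_matrix")
}

toy_fit <- function(rate, threshold = 1.0) {
  rpa(toy_vector(), tau = 2, dim = 1, rate = rate,
      threshold_sigma = threshold, k_grid = 1, scan = FALSE)
}
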