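toy_m <- function(lambda)
  recurrence_matrix(pairwise_distances(embed_series(toy_vector(), 2, 1)), lambda)

test_that("column weights by polarity, and their partition identity", {
  M1 <- toy_m(0.1)
  expect_equal(as.numeric(column_weights(M1, "dark")), c(1, 2, 1))
  M9 <- toy_m(0.9)
  expect_equal(as.numeric(column_weights(M9, "dark")), c(0, 0, 0))
  expect_equal(as.numeric(column_weights(M9, "white")), c(3, 3, 3))
  set.seed(2)
  for (rep in 1:10) {
    M <- wrap_matrix(random_rp_matrix(sample(5:40, 1)))
    expect_equal(as.numeric(column_weights(M, "dark")) +
                   as.numeric(column_weights(M, "white")),
                 rep(nrow(M$M), nrow(M$M)))
  }
})

test_that("SMA smoothing: identity at k = 1, truncated edge windows", {
  expect_equal(smooth_sma(c(4, 1, 7, 2), 1), c(4, 1, 7, 2))
  expect_equal(smooth_sma(c(1, 2, 1), 3), c(1.5, 4/3, 1.5))
  expect_equal(smooth_sma(rep(5, 9), 4), rep(5, 9))
  # even k spans k points right-biased by one; hand-checked interior value
  expect_equal(smooth_sma(c(1, 2, 3, 4, 5, 6), 2)[3], mean(c(3, 4)))
  expect_equal(smooth_sma(c(1, 2, 3, 4, 5, 6), 4)[3], mean(c(2, 3, 4, 5)))
  expect_error(smooth_sma(1:5, 0), class = "rp_config_error")
  expect_error(smooth_sma(1:5, 6), class = "rp_config_error")
  set.seed(8)
  for (rep in 1:10) {
    w <- rnorm(sample(5:50, 1))
    k <- sample(seq_along(w), 1)
    expect_equal(smooth_sma(w, k), naive_sma(w, k))
  }
})

test_that("standardization: population convention, idempotent, degenerate", {
  z <- standardize_weights(c(1, 2, 1))
  expect_equal(z, c(-1, 2, -1) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(z, 4), c(-0.7071, 1.4142, -0.7071))
  expect_equal(standardize_weights(z), z)       # already standardized
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  expect_error(standardize_weights(rep(4, 10)), class = "rp_degenerate_vector")
})

test_that("width selection maximizes the peak standardized smoothed weight", {
  # isolated spike: smoothing only dilutes it, so k = 1 wins
  spike <- c(rep(0, 20), 9, rep(0, 20))
  expect_identical(as.integer(select_k(spike, 1:10)), 1L)
  # rectangular bump of width 7 in a flat background: brute force fixes k
  bump <- rep(0, 60); bump[25:31] <- 1
  grid <- 1:20
  brute <- grid[which.max(vapply(grid, function(k) {
    sm <- naive_sma(bump, k); mx <- max(naive_z(sm)); mx
  }, numeric(1)))]
  expect_identical(as.integer(select_k(bump, grid)), as.integer(brute))
  expect_lte(abs(as.integer(select_k(bump, grid)) - 7), 2)
  # argmax stability: a superset grid containing the winner picks the same k
  expect_identical(as.integer(select_k(bump, c(3, brute, 15))),
                   as.integer(select_k(bump, grid)))
  expect_error(select_k(rep(2, 10), integer(0)), class = "rp_config_error")
  expect_error(select_k(rep(2, 10), 1:3), class = "rp_no_structure_error")
})

test_that("worked-example cross: one dark cross at i = 2, width 1", {
  cr <- detect_crosses(toy_m(0.1), threshold_sigma = 1.0, k_grid = 1)
  expect_identical(cr$centers, 2L)
  expect_identical(cr$k, 1L)
  expect_equal(round(cr$center_scores, 3), 1.414)
  # at the default 2.5 sigma the 3x3 example has no crosses
  none <- detect_crosses(toy_m(0.1), threshold_sigma = 2.5, k_grid = 1)
  expect_length(none$centers, 0)
  # degenerate all-recurrent matrix: empty result, no error
  deg <- detect_crosses(toy_m(0.9), threshold_sigma = 2.5)
  expect_true(deg$no_structure)
  expect_length(deg$centers, 0)
})

test_that("detection agrees with the naive steps (a)-(f) oracle", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(8:60, 1)
    M <- wrap_matrix(random_rp_matrix(n, runif(1, 0.15, 0.7)))
    thr <- sample(c(1, 1.5, 2, 2.5), 1)
    pol <- sample(c("dark", "white"), 1)
    got <- detect_crosses(M, thr, pol)
    want <- naive_detect(M$M, thr, pol)
    expect_identical(as.integer(got$k), as.integer(want$k))
    expect_identical(as.integer(got$centers), as.integer(want$centers))
  }
})

test_that("dark detection equals white detection on the complemented matrix", {
  set.seed(37)
  for (rep in 1:15) {
    n <- sample(8:50, 1)
    M <- random_rp_matrix(n, runif(1, 0.2, 0.8))
    Mc <- 1L - M
    dark <- detect_crosses(wrap_matrix(M), 1.5, "dark")
    white <- detect_crosses(wrap_matrix(Mc), 1.5, "white")
    expect_identical(dark$centers, white$centers)
    expect_identical(dark$k, white$k)
    expect_equal(dark$center_scores, white$center_scores)
  }
})

test_that("cross detection output is invariant under affine input rescaling", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- rnorm(150)
    a <- runif(1, 0.2, 6) * sample(c(-1, 1), 1)
    b <- runif(1, -20, 20)
    mk <- function(v) {
      d <- pairwise_distances(embed_series(rp_series(v), 2, 1))
      recurrence_matrix(d, lambda_for_rate(d, 0.09))
    }
    c1 <- detect_crosses(mk(x), 2.5)
    c2 <- detect_crosses(mk(a * x + b), 2.5)
    expect_identical(c1$centers, c2$centers)
    expect_identical(c1$k, c2$k)
  }
})

test_that("an injected 4-sigma regime window is found near its midpoint", {
  for (s in 1:5) {
    ser <- synth_series("regime_change", length = 300, seed = 500 + s,
                        window_start = 120, window_width = 40, shift = 4)
    truth <- attr(ser, "truth")
    d <- pairwise_distances(embed_series(ser, 2, 1))
    M <- recurrence_matrix(d, lambda_for_rate(d, 0.09))
    cr <- detect_crosses(M, 2.5)
    expect_gte(length(cr$centers), 1)
    expect_lte(min(abs(cr$centers - truth$midpoint)), cr$k)
  }
})

test_that("cross tables export center, time, width, score and polarity", {
  cr <- detect_crosses(toy_m(0.1), 1.0, k_grid = 1)
  df <- as.data.frame(cr)
  expect_identical(names(df), c("center", "time", "width_k", "zscore", "polarity"))
  expect_identical(df$center, 2L)
  expect_identical(df$time, 1)      # (center - 1) * dt, dt = 1
  expect_identical(df$polarity, "dark")
})
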