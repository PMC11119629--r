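toy_matrix <- function(lambda)
  recurrence_matrix(pairwise_distances(embed_series(toy_vector(), 2, 1)), lambda)

test_that("diagonal runs on the worked example, line of identity excluded", {
  h1 <- diagonal_runs(toy_matrix(0.1))
  expect_identical(h1$counts, c(`1` = 2L))        # j in {1}, p1 = 1
  h9 <- diagonal_runs(toy_matrix(0.9))
  expect_identical(h9$counts, c(`1` = 2L, `2` = 2L))  # p1 = p2 = 1/2
  # all-ones matrix: no zeros anywhere off-diagonal
  h0 <- diagonal_runs(wrap_matrix(matrix(1L, 4, 4)))
  expect_identical(h0$total, 0L)
})

test_that("Shannon entropy of run histograms (natural log)", {
  expect_equal(shannon_entropy(diagonal_runs(toy_matrix(0.1))), 0)
  expect_equal(shannon_entropy(diagonal_runs(toy_matrix(0.9))), log(2))
  expect_equal(round(shannon_entropy(diagonal_runs(toy_matrix(0.9))), 3), 0.693)
  expect_equal(shannon_entropy(c(`1` = 1, `2` = 1, `3` = 1, `4` = 1)), log(4))
  expect_error(shannon_entropy(diagonal_runs(wrap_matrix(matrix(1L, 4, 4)))),
               class = "rp_undefined_entropy_error")
})

test_that("entropy is permutation-invariant and zero iff one class", {
  set.seed(3)
  for (rep in 1:10) {
    counts <- sample(1:9, sample(2:6, 1), replace = TRUE)
    names(counts) <- seq_along(counts)
    perm <- sample(counts)
    expect_equal(shannon_entropy(counts), shannon_entropy(perm))
    if (length(unique(counts / sum(counts))) > 1 || length(counts) > 1)
      expect_gt(shannon_entropy(counts), 0)
  }
  expect_equal(shannon_entropy(c(`5` = 17)), 0)
})

test_that("diagonal_runs agrees with the naive per-diagonal scanner", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(4:60, 1)
    M <- wrap_matrix(random_rp_matrix(n, runif(1, 0.1, 0.9)))
    got <- diagonal_runs(M)$counts
    lens <- naive_diagonal_runs(M$M)
    tab <- table(lens)
    expect_identical(got, structure(as.integer(tab), names = names(tab)))
    # transpose symmetry
    expect_identical(diagonal_runs(wrap_matrix(t(M$M)))$counts, got)
  }
})

test_that("the all-recurrent matrix has the closed-form diagonal entropy", {
  # at rate 1 every diagonal is one full run: lengths n-1, n-2, ..., 1,
  # each twice, so S = log(n - 1)
  for (n in c(4, 9, 23)) {
    M <- wrap_matrix(matrix(0L, n, n))
    h <- diagonal_runs(M)
    expect_identical(h$counts, structure(rep(2L, n - 1), names = 1:(n - 1)))
    expect_equal(shannon_entropy(h), log(n - 1))
  }
})

test_that("full toy chain reproduces S = 0 and S = 0.693 via rate targeting", {
  s <- toy_vector()
  d <- pairwise_distances(embed_series(s, 2, 1))
  S1 <- shannon_entropy(diagonal_runs(recurrence_matrix(d, lambda_for_rate(d, 5/9))))
  S2 <- shannon_entropy(diagonal_runs(recurrence_matrix(d, lambda_for_rate(d, 1))))
  expect_identical(round(S1, 3), 0)
  expect_identical(round(S2, 3), 0.693)
})

test_that("entropy scan: toy grid and the decreasing trend on a chaotic map", {
  sc <- entropy_scan(toy_vector(), 2, 1, rate_grid = c(5/9, 1))
  expect_s3_class(sc, "rp_scan")
  expect_equal(sc$entropy, c(0, log(2)))
  expect_equal(sc$achieved_rate, c(5/9, 1))
  # logistic map: the run-length entropy grows with the recurrence rate —
  # runs diversify as zeros fill in, up to the uniform histogram
  # (S = log(n-1)) of the all-recurrent matrix. The worked example shows the
  # same direction (0 at RR = 5/9, 0.693 at RR = 1).
  lo <- synth_series("logistic_map", length = 600)
  scl <- entropy_scan(lo, tau = 1, dim = 1, rate_grid = default_rate_grid())
  ok <- is.finite(scl$entropy) & scl$entropy > 0
  expect_gte(sum(ok), 10)
  expect_gt(cor(scl$achieved_rate[ok], scl$entropy[ok], method = "spearman"), 0)
  expect_equal(scl$entropy[nrow(scl)], log(nrow(embed_series(lo, 1, 1)$Y) - 1))
  expect_error(entropy_scan(toy_vector(), 2, 1, rate_grid = c(0.5, 0.2)),
               class = "rp_config_error")
})

test_that("select_rate recovers an exact two-segment log-log knee", {
  grid <- default_rate_grid()
  knee_idx <- 17L
  make_scan <- function(slope2) {
    lx <- log(grid)
    ly <- -0.4 * lx                     # first segment
    kink <- lx > lx[knee_idx]
    ly[kink] <- ly[knee_idx] + slope2 * (lx[kink] - lx[knee_idx])
    structure(data.frame(target_rate = grid, achieved_rate = grid,
                         lambda = NA_real_, entropy = exp(ly)),
              class = c("rp_scan", "data.frame"))
  }
  sel <- select_rate(make_scan(-2.1))
  expect_identical(attr(sel, "index"), knee_idx)
  expect_equal(as.numeric(sel), grid[knee_idx])
  expect_false(any(attr(sel, "no_edge")))
  # a perfect single line carries no edge; flagged, tie broken low
  line <- make_scan(-0.4)
  sl <- select_rate(line)
  expect_true(all(attr(sl, "no_edge")))
  expect_identical(attr(sl, "index"), 2L)
  # majority across scans: two knees at index 17 beat one elsewhere
  other <- make_scan(-2.1)
  other$entropy <- exp(-0.4 * log(grid) +
                         pmin(0, -3 * (log(grid) - log(grid[23]))))
  sel3 <- select_rate(list(make_scan(-2.1), make_scan(-3), other))
  expect_identical(attr(sel3, "index"), knee_idx)
  # fewer than 5 valid points is an error
  short <- make_scan(-2.1)[1:4, ]
  class(short) <- c("rp_scan", "data.frame")
  expect_error(select_rate(short), class = "rp_insufficient_scan_error")
})
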