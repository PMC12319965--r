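# Brute-force oracle: direct double loop over the defining sum.
naive_lagged_corr <- function(x, y, tau) {
  n <- length(x)
  s <- 0
  for (t in seq_len(n - tau)) s <- s + x[t] * y[t + tau]
  s / sqrt(sum(x^2) * sum(y^2))
}

test_that("lagged_corr matches a brute-force oracle on random input", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); x <- x - mean(x)
    y <- rnorm(n); y <- y - mean(y)
    tau <- sample(0:(n - 2), 1)
    expect_equal(lagged_corr(x, y, tau), naive_lagged_corr(x, y, tau),
                 tolerance = 1e-12)
  }
})

test_that("lagged_corr: autocorrelation at lag 0 is exactly 1", {
  set.seed(42)
  x <- rnorm(50); x <- x - mean(x)
  expect_equal(lagged_corr(x, x, 0), 1)
  expect_error(lagged_corr(rep(0, 10), x[1:10], 1), "zero-variance")
})

test_that("circular lagged_corr matches its rotation-sum definition", {
  set.seed(43)
  n <- 32
  x <- rnorm(n); x <- x - mean(x)
  y <- rnorm(n); y <- y - mean(y)
  for (tau in c(0, 1, 5, n - 1)) {
    direct <- sum(x * y[((seq_len(n) - 1 + tau) %% n) + 1]) /
      sqrt(sum(x^2) * sum(y^2))
    expect_equal(lagged_corr(x, y, tau, use = "circular"), direct,
                 tolerance = 1e-12)
  }
})

test_that("corr_matrices agrees with scalar lagged_corr entrywise", {
  set.seed(44)
  X <- matrix(rnorm(5 * 40), 5)
  X <- X - rowMeans(X)
  m <- corr_matrices(X, 3)
  for (i in 1:5) for (j in 1:5)
    expect_equal(m$Cf[i, j], lagged_corr(X[i, ], X[j, ], 3), tolerance = 1e-12)
})

test_that("explicit time reversal reproduces the transpose shortcut", {
  set.seed(45)
  for (rep in 1:10) {
    X <- matrix(rnorm(6 * 50), 6)
    tau <- sample(1:10, 1)
    m <- corr_matrices(X, tau)
    Cr_explicit <- corr_matrices_reversed(X, tau)
    expect_lt(max(abs(m$Cr - Cr_explicit)), 1e-12)
  }
})

test_that("irrev_matrix is symmetric, non-negative, zero diagonal", {
  set.seed(46)
  X <- matrix(rnorm(8 * 60), 8)
  R <- irrev_matrix(corr_matrices(X, 4))
  expect_true(all(R >= 0))
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(0, 8), ignore_attr = TRUE)
})

test_that("irreversibility vanishes for a statically coupled pair", {
  # y is an instantaneous copy of x: forward and reversed lagged
  # correlations coincide, so R is numerically tiny relative to C itself
  set.seed(47)
  x <- rnorm(500)
  X <- rbind(x, x + rnorm(500, sd = 1e-6))
  m <- corr_matrices(X, 5)
  R <- irrev_matrix(m)
  expect_lt(max(R), 1e-8)
})

test_that("regional_irrev matches the off-diagonal rows of irrev_matrix", {
  set.seed(48)
  X <- matrix(rnorm(6 * 40), 6)
  m <- corr_matrices(X, 2)
  R <- irrev_matrix(m)
  for (reg in 1:6)
    expect_equal(regional_irrev(m, reg), R[reg, -reg], tolerance = 1e-12)
})

test_that("thresholded_mean: enumerated survivors and sort oracle", {
  v <- c(rep(0, 95), rep(1, 5))
  expect_equal(thresholded_mean(v, 95), 1.0)
  expect_equal(thresholded_mean(rep(0.3, 10), 95), 0.3)  # constant fallback
  expect_error(thresholded_mean(numeric(0), 95), "empty")
  set.seed(49)
  for (rep in 1:20) {
    v <- runif(sample(20:200, 1))
    p <- sample(c(50, 75, 90, 95), 1)
    thr <- stats::quantile(v, p / 100, names = FALSE)
    surv <- sort(v)[sort(v) > thr]
    oracle <- if (length(surv)) mean(surv) else mean(v)
    expect_equal(thresholded_mean(v, p), oracle, tolerance = 1e-12)
  }
})

test_that("col_thresholded_means equals columnwise thresholded_mean", {
  set.seed(50)
  M <- matrix(runif(45 * 30), 45, 30)
  got <- insideout:::col_thresholded_means(M, 95)
  want <- apply(M, 2, thresholded_mean, percentile = 95)
  expect_equal(got, want, tolerance = 1e-12)
  # with heavy ties (fallback path exercised)
  M2 <- matrix(rep(0.5, 45 * 4), 45, 4)
  expect_equal(insideout:::col_thresholded_means(M2, 95), rep(0.5, 4))
})

test_that("dataset_irrev averages epoch values and is permutation-invariant", {
  set.seed(51)
  vals <- array(rnorm(4 * 5 * 80), dim = c(4, 5, 80))
  env <- envelope_epochs(vals, fs = 40)
  ir <- dataset_irrev(env, tau = 3)
  expect_equal(ir$r, mean(ir$r_epoch), tolerance = 1e-12)
  expect_length(ir$r_region, 5)
  # relabeling regions permutes r_region consistently
  perm <- c(3, 1, 5, 2, 4)
  env_p <- envelope_epochs(vals[, perm, , drop = FALSE], fs = 40)
  ir_p <- dataset_irrev(env_p, tau = 3)
  expect_equal(ir_p$r, ir$r, tolerance = 1e-12)
  expect_equal(unname(ir_p$r_region), unname(ir$r_region[perm]),
               tolerance = 1e-12)
})

test_that("unthresholded dataset_irrev equals the plain mean oracle", {
  set.seed(52)
  vals <- array(rnorm(2 * 4 * 60), dim = c(2, 4, 60))
  env <- envelope_epochs(vals, fs = 30)
  ir <- dataset_irrev(env, tau = 2, threshold = FALSE)
  ut <- upper.tri(matrix(0, 4, 4))
  manual <- mean(sapply(1:2, function(e)
    mean(irrev_matrix(corr_matrices(epoch_matrix(env, e), 2))[ut])))
  expect_equal(ir$r, manual, tolerance = 1e-12)
})

test_that("irrev_curve matches per-lag dataset_irrev and trapezoid oracle", {
  set.seed(53)
  vals <- array(rnorm(3 * 4 * 50), dim = c(3, 4, 50))
  env <- envelope_epochs(vals, fs = 25)
  grid <- c(1, 2, 5, 9, 14)
  cv <- irrev_curve(env, tau_grid = grid)
  direct <- vapply(grid, function(tau) dataset_irrev(env, tau)$r, numeric(1))
  expect_equal(cv$r, direct, tolerance = 1e-10)
  expect_true(all(cv$r >= 0))
  # trapezoid on a constant curve: total = c * span
  fake <- cv; fake$r <- rep(0.2, length(grid))
  total <- sum(diff(fake$tau_s) * 0.2)
  expect_equal(sum(diff(cv$tau_s) *
                   (head(fake$r, -1) + tail(fake$r, -1)) / 2),
               total, tolerance = 1e-12)
})

test_that("irrev_curve peaks near the simulated coupling delay", {
  g <- coupling_graph(6, kappa = 0.9, coupling_lag = 6, seed = 3)
  env <- simulate_network_timeseries(g, n_epochs = 12, fs = 50,
                                     epoch_length_s = 2, seed = 3)
  cv <- irrev_curve(env, tau_grid = 1:20)
  expect_lte(abs(cv$tau_samples[which.max(cv$r)] - 6), 3)
})

test_that("partial_corr_matrices removes a common-driver artifact", {
  set.seed(54)
  n <- 400
  c_drive <- rnorm(n)
  a <- c_drive + rnorm(n, sd = 0.05)
  b <- c(rnorm(3), c_drive[1:(n - 3)]) + rnorm(n, sd = 0.05)
  X <- rbind(a, b, c_drive)
  plain <- corr_matrices(X, 3)$Cf[1, 2]
  partial <- partial_corr_matrices(X, 3)$Cf[1, 2]
  expect_gt(abs(plain), 0.5)          # spurious lag-3 correlation a -> b
  expect_lt(abs(partial), abs(plain) / 3)
  # two regions: partialling is a no-op
  X2 <- X[1:2, ]
  expect_equal(partial_corr_matrices(X2, 3)$Cf, corr_matrices(X2, 3)$Cf,
               tolerance = 1e-12)
})
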