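#' Normalized lagged cross-correlation
#'
#' The building block of the irreversibility analysis: for demeaned series
#' `x` and `y`, the lagged correlation at lag `tau` is
#' \deqn{c_f(\tau) = \frac{\sum_{t=1}^{n-\tau} x(t)\,y(t+\tau)}
#'                       {\sqrt{\sum_t x(t)^2 \sum_t y(t)^2}}}
#' i.e. a truncated-overlap sum with a fixed full-series denominator, so
#' that the autocorrelation at zero lag is exactly 1. The time-reversed
#' counterpart \eqn{c_r(\tau)} is the same quantity on the reversed series
#' and equals \eqn{c_f} with the roles of `x` and `y` swapped — the
#' transpose identity exploited by [corr_matrices()].
#'
#' `use = "circular"` replaces the truncated sum by the circular (FFT)
#' convolution sum \eqn{\sum_{t=1}^{n} x(t) y(1 + (t+\tau-1 \bmod n))}.
#' The circular variant is exactly invariant under coherent phase
#' randomization; the truncated default matches the conventional estimator
#' and differs from it by edge terms of order \eqn{\tau/n}.
#'
#' @param x,y numeric vectors of equal length, demeaned per epoch.
#' @param tau integer lag in samples, `0 <= tau <= length(x) - 1`.
#' @param use `"truncated"` (default) or `"circular"` summation.
#' @return scalar in `[-1, 1]`.
#' @export
lagged_corr <- function(x, y, tau, use = c("truncated", "circular")) {
  use <- match.arg(use)
  n <- length(x)
  stopifnot(length(y) == n, tau >= 0, tau <= n - 1)
  ssx <- sum(x^2); ssy <- sum(y^2)
  if (ssx == 0 || ssy == 0)
    stop("zero-variance input: lagged correlation undefined")
  num <- if (use == "truncated") {
    if (tau == 0) sum(x * y)
    else sum(x[seq_len(n - tau)] * y[(tau + 1):n])
  } else {
    sum(x * y[((seq_len(n) - 1 + tau) %% n) + 1])
  }
  num / sqrt(ssx * ssy)
}

# Demean each row (region) of a regions x samples matrix.
demean_rows <- function(X) X - rowMeans(X)

#' Forward and time-reversed lagged correlation matrices
#'
#' For a demeaned epoch (regions x samples), computes `Cf` with
#' `Cf[i, j] = lagged_corr(region_i, region_j, tau)` — region *i* leading
#' region *j* by `tau` samples — and the time-reversed matrix `Cr`. Because
#' reversing both series and lagging the second is identical to lagging the
#' first series instead, `Cr` equals `t(Cf)` exactly under this estimator;
#' the transpose is how `Cr` is computed. [corr_matrices_reversed()] keeps
#' the explicit-reversal path as an independent cross-check.
#'
#' @param epoch numeric matrix, regions x samples, demeaned per region.
#' @param tau integer lag in samples.
#' @param use summation variant, see [lagged_corr()].
#' @param demean demean rows before computing (default TRUE; idempotent).
#' @return object of class `lagged_corr_matrices` with elements `Cf`, `Cr`,
#'   `tau_samples`.
#' @export
corr_matrices <- function(epoch, tau, use = c("truncated", "circular"),
                          demean = TRUE) {
  use <- match.arg(use)
  stopifnot(is.matrix(epoch))
  n <- ncol(epoch)
  stopifnot(tau >= 0, tau <= n - 1)
  if (demean) epoch <- demean_rows(epoch)
  ss <- rowSums(epoch^2)
  zero <- which(ss == 0)
  if (length(zero))
    stop("zero-variance region(s): ",
         paste(if (!is.null(rownames(epoch))) rownames(epoch)[zero] else zero,
               collapse = ", "))
  num <- if (use == "truncated") {
    if (tau == 0) tcrossprod(epoch)
    else tcrossprod(epoch[, seq_len(n - tau), drop = FALSE],
                    epoch[, (tau + 1):n, drop = FALSE])
  } else {
    idx <- ((seq_len(n) - 1 + tau) %% n) + 1
    tcrossprod(epoch, epoch[, idx, drop = FALSE])
  }
  Cf <- num / sqrt(outer(ss, ss))
  dimnames(Cf) <- list(rownames(epoch), rownames(epoch))
  structure(list(Cf = Cf, Cr = t(Cf), tau_samples = as.integer(tau)),
            class = "lagged_corr_matrices")
}

#' Time-reversed correlation matrix by explicit reversal
#'
#' Debug/oracle path: reverses every region's series in time and computes
#' the forward matrix of the reversed data. Must agree with `t(Cf)` of
#' [corr_matrices()] to floating-point tolerance; the package tests assert
#' this identity rather than assuming it.
#'
#' @inheritParams corr_matrices
#' @return N x N matrix `Cr` computed without the transpose shortcut.
#' @export
corr_matrices_reversed <- function(epoch, tau, use = c("truncated", "circular"),
                                   demean = TRUE) {
  use <- match.arg(use)
  rev_epoch <- epoch[, rev(seq_len(ncol(epoch))), drop = FALSE]
  corr_matrices(rev_epoch, tau, use = use, demean = demean)$Cf
}

#' Irreversibility matrix
#'
#' Element-wise squared difference between the forward and time-reversed
#' lagged correlation matrices, \eqn{R(\tau) = (C_f - C_r)^{\circ 2}}.
#' `R` is symmetric with an exactly zero diagonal: each entry measures the
#' directional asymmetry of one connection.
#'
#' @param m a `lagged_corr_matrices` object from [corr_matrices()].
#' @return N x N non-negative symmetric matrix.
#' @export
irrev_matrix <- function(m) {
  stopifnot(inherits(m, "lagged_corr_matrices"))
  R <- (m$Cf - m$Cr)^2
  diag(R) <- 0
  R
}

#' Regional irreversibility vector
#'
#' Squared difference between one region's forward and time-reversed
#' correlation rows, off-diagonal entries only — identical to the
#' corresponding off-diagonal row of [irrev_matrix()].
#'
#' @param m a `lagged_corr_matrices` object.
#' @param region region index.
#' @return numeric vector of length N - 1.
#' @export
regional_irrev <- function(m, region) {
  stopifnot(inherits(m, "lagged_corr_matrices"))
  N <- nrow(m$Cf)
  if (region < 1 || region > N) stop("region index out of range")
  d <- (m$Cf[region, ] - m$Cr[region, ])^2
  d[-region]
}

#' Percentile-thresholded mean
#'
#' Mean of the entries strictly above the empirical percentile
#' (linear-interpolation definition, `stats::quantile` type 7) of the
#' supplied values. Entries tied with the threshold are dropped. If nothing
#' survives (e.g. a constant input), falls back to the plain mean, so the
#' statistic is always defined.
#'
#' @param values non-empty numeric vector (non-negative in this pipeline).
#' @param percentile percentile in (0, 100); 95 in the standard analysis.
#' @return scalar.
#' @export
thresholded_mean <- function(values, percentile) {
  if (length(values) == 0L) stop("empty input")
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  thr <- stats::quantile(values, percentile / 100, names = FALSE, type = 7)
  surv <- values[values > thr]
  if (length(surv) == 0L) mean(values) else mean(surv)
}

# Vectorized column-wise thresholded means for an entries x columns matrix.
# One call replaces a loop of thresholded_mean() over columns; used by the
# curve and sliding-window paths where thousands of columns occur.
col_thresholded_means <- function(M, percentile) {
  nr <- nrow(M); nc <- ncol(M)
  if (nr == 1L) return(M[1L, ])
  o <- order(rep(seq_len(nc), each = nr), M)     # column-wise sort, one call
  S <- matrix(M[o], nr, nc)
  h <- (nr - 1) * percentile / 100 + 1           # type-7 quantile position
  lo <- floor(h); hi <- ceiling(h)
  thr <- S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
  keep <- M > rep(thr, each = nr)
  cnt <- colSums(keep)
  out <- ifelse(cnt > 0, colSums(M * keep) / pmax(cnt, 1L), colMeans(M))
  out
}

#' Dataset-level irreversibility
#'
#' The scalar irreversibility of an epoched dataset: per epoch, the lagged
#' correlation matrices give `R`; the thresholded mean of the upper
#' triangle of `R` gives the epoch value, and regional thresholded means
#' give per-region values; both are then averaged across epochs.
#'
#' @param env an [envelope_epochs()] dataset.
#' @param tau lag in samples (`< n_samples`).
#' @param percentile thresholding percentile; see [thresholded_mean()].
#' @param threshold FALSE computes plain means instead (the unthresholded
#'   variant of the analysis).
#' @param use summation variant, see [lagged_corr()].
#' @return object of class `irrev_result`: `r` (scalar), `r_region`
#'   (N-vector, named), `R` (epoch-mean irreversibility matrix),
#'   `tau_samples`, `percentile`.
#' @export
dataset_irrev <- function(env, tau, percentile = 95, threshold = TRUE,
                          use = c("truncated", "circular")) {
  use <- match.arg(use)
  stopifnot(inherits(env, "envelope_epochs"))
  ne <- n_epochs(env); N <- n_regions(env)
  if (ne < 1L) stop("at least one epoch is required")
  if (tau >= n_samples(env)) stop("tau_samples must be < n_samples")
  r_ep <- numeric(ne)
  rreg_ep <- matrix(0, ne, N)
  Rsum <- matrix(0, N, N)
  ut <- upper.tri(matrix(0, N, N))
  for (e in seq_len(ne)) {
    m <- corr_matrices(epoch_matrix(env, e), tau, use = use)
    R <- irrev_matrix(m)
    Rsum <- Rsum + R
    if (threshold) {
      r_ep[e] <- thresholded_mean(R[ut], percentile)
      offdiag <- matrix(R[row(R) != col(R)], nrow = N - 1L)  # col = region
      rreg_ep[e, ] <- col_thresholded_means(offdiag, percentile)
    } else {
      r_ep[e] <- mean(R[ut])
      rreg_ep[e, ] <- (rowSums(R)) / (N - 1L)
    }
  }
  r_region <- colMeans(rreg_ep)
  names(r_region) <- env$region_labels
  structure(list(r = mean(r_ep), r_region = r_region,
                 r_epoch = r_ep, R = Rsum / ne,
                 tau_samples = as.integer(tau), percentile = percentile),
            class = "irrev_result")
}

#' @export
print.irrev_result <- function(x, ...) {
  cat("<irrev_result> r = ", signif(x$r, 4), " at tau = ", x$tau_samples,
      " samples (", x$percentile, "th pct, ", length(x$r_region),
      " regions)\n", sep = "")
  invisible(x)
}

#' Partial lagged correlation matrices
#'
#' Lagged correlations with all other regions regressed out: for each
#' ordered pair (i, j), region i at times `1..n-tau` and region j at times
#' `tau+1..n` are each residualized (with intercept) on the contemporaneous
#' values of the remaining regions, and the residuals are correlated. This
#' controls for a common driver C inducing a spurious lagged correlation
#' between A and B. With exactly two regions there is nothing to regress
#' out and the plain [corr_matrices()] is returned.
#'
#' @inheritParams corr_matrices
#' @param max_condition condition-number bound on the regressor matrix.
#' @return `lagged_corr_matrices` (reversed matrix via the transpose
#'   identity, which holds because residualizing commutes with reversal).
#' @export
partial_corr_matrices <- function(epoch, tau, demean = TRUE,
                                  max_condition = 1e8) {
  stopifnot(is.matrix(epoch))
  N <- nrow(epoch); n <- ncol(epoch)
  if (N == 2L) return(corr_matrices(epoch, tau, demean = demean))
  if (n - tau <= N)
    stop("n_samples - tau must exceed n_regions for the residual regression")
  if (demean) epoch <- demean_rows(epoch)
  idx_a <- seq_len(n - tau); idx_b <- (tau + 1):n
  Cf <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) { Cf[i, j] <- 1; next }
    others <- setdiff(seq_len(N), c(i, j))
    Za <- t(epoch[others, idx_a, drop = FALSE])
    Zb <- t(epoch[others, idx_b, drop = FALSE])
    ka <- kappa(crossprod(cbind(1, Za)), exact = FALSE)
    if (!is.finite(ka) || ka > max_condition^2)
      stop("ill-conditioned regressor matrix (condition number too large)")
    ra <- stats::lm.fit(cbind(1, Za), epoch[i, idx_a])$residuals
    rb <- stats::lm.fit(cbind(1, Zb), epoch[j, idx_b])$residuals
    den <- sqrt(sum(ra^2) * sum(rb^2))
    Cf[i, j] <- if (den == 0) 0 else sum(ra * rb) / den
  }
  dimnames(Cf) <- list(rownames(epoch), rownames(epoch))
  structure(list(Cf = Cf, Cr = t(Cf), tau_samples = as.integer(tau)),
            class = "lagged_corr_matrices")
}

# All-lag numerators for every ordered region pair of one demeaned epoch,
# via one FFT-based cross-correlation per unordered pair. Returns a list
# with num[i, j, tau_index] implicit as a (N*N) x n_lags matrix restricted
# to the requested tau grid, already normalized to correlations.
epoch_xcorr_all <- function(epoch, tau_grid) {
  N <- nrow(epoch); n <- ncol(epoch)
  ss <- rowSums(epoch^2)
  if (any(ss == 0)) stop("zero-variance region")
  nfft <- stats::nextn(2L * n, 2)
  Fx <- stats::mvfft(rbind(t(epoch), matrix(0, nfft - n, N)))
  out_f <- matrix(0, N * N, length(tau_grid))  # Cf[i,j] rows in column-major order
  for (j in seq_len(N)) {
    # cross-corr of every i with j: sum_t x_i(t) x_j(t+tau) for tau>=0 is
    # the IFFT of conj(F_i) * F_j at indices tau+1
    cc <- Re(stats::mvfft(Conj(Fx) * Fx[, j], inverse = TRUE)) / nfft
    vals <- cc[tau_grid + 1L, , drop = FALSE]            # lags x i
    den <- sqrt(ss * ss[j])
    out_f[(j - 1L) * N + seq_len(N), ] <- t(vals) / den  # rows i for column j
  }
  out_f
}

#' Irreversibility across all lags
#'
#' Evaluates [dataset_irrev()] over a grid of lags (default: every positive
#' lag `1..n_samples-1`) and integrates the resulting curve by the
#' trapezoidal rule over the lag expressed in seconds, giving the "total"
#' irreversibility. Uses an FFT cross-correlation path so the full curve
#' costs one FFT per region per epoch rather than one matrix product per
#' lag.
#'
#' @param env an [envelope_epochs()] dataset.
#' @param percentile thresholding percentile.
#' @param tau_grid integer lags to evaluate; default all positive lags.
#' @param threshold as in [dataset_irrev()].
#' @return object of class `irrev_curve`: `tau_samples` (grid), `tau_s`,
#'   `r` (curve values), `total` (area under the curve, units of r x s).
#' @export
irrev_curve <- function(env, percentile = 95, tau_grid = NULL,
                        threshold = TRUE) {
  stopifnot(inherits(env, "envelope_epochs"))
  ns <- n_samples(env); N <- n_regions(env); ne <- n_epochs(env)
  if (is.null(tau_grid)) tau_grid <- seq_len(ns - 1L)
  tau_grid <- as.integer(sort(unique(tau_grid)))
  if (length(tau_grid) < 2L) stop("at least two lags are required for a curve")
  stopifnot(min(tau_grid) >= 1L, max(tau_grid) <= ns - 1L)
  nl <- length(tau_grid)
  ut_idx <- which(upper.tri(matrix(0, N, N)))   # linear indices of (i, j), i < j
  ri <- ((ut_idx - 1L) %% N) + 1L               # matched (j, i) indices, pairwise
  ci <- ((ut_idx - 1L) %/% N) + 1L
  lt_idx <- (ri - 1L) * N + ci
  acc <- matrix(0, 1, nl)
  r_sum <- numeric(nl)
  for (e in seq_len(ne)) {
    X <- demean_rows(epoch_matrix(env, e))
    cf <- epoch_xcorr_all(X, tau_grid)          # (N*N) x nl, column-major [i,j]
    Rvals <- (cf[ut_idx, , drop = FALSE] - cf[lt_idx, , drop = FALSE])^2
    r_sum <- r_sum + if (threshold) col_thresholded_means(Rvals, percentile)
                     else colMeans(Rvals)
  }
  r <- r_sum / ne
  tau_s <- tau_grid / env$fs
  total <- sum(diff(tau_s) * (utils::head(r, -1) + utils::tail(r, -1)) / 2)
  structure(list(tau_samples = tau_grid, tau_s = tau_s, r = r, total = total,
                 percentile = percentile, fs = env$fs),
            class = "irrev_curve")
}

#' @export
print.irrev_curve <- function(x, ...) {
  cat("<irrev_curve> ", length(x$tau_samples), " lags; peak r = ",
      signif(max(x$r), 4), " at tau = ", x$tau_samples[which.max(x$r)],
      " samples; total = ", signif(x$total, 4), "\n", sep = "")
  invisible(x)
}
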