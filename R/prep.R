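#' Frequency band specification
#'
#' Standard bands for the envelope analysis: theta (4-8 Hz), alpha
#' (8-13 Hz), beta (13-30 Hz), gamma (30-48 Hz). `"broadband"` is a
#' passthrough (no filtering). The delta band is excluded by construction:
#' with 2-second epochs a single slow cycle can span a whole epoch.
#'
#' @param name one of `"broadband"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`, or `"custom"` with explicit edges.
#' @param low_hz,high_hz band edges for `"custom"`.
#' @return list with `name`, `low_hz`, `high_hz` (`NULL` for broadband).
#' @export
band_spec <- function(name = c("broadband", "theta", "alpha", "beta", "gamma",
                               "custom"),
                      low_hz = NULL, high_hz = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
                  broadband = c(NA, NA),
                  theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 48),
                  custom = c(low_hz, high_hz))
  if (name == "custom") {
    if (is.null(low_hz) || is.null(high_hz) || low_hz <= 0 || high_hz <= low_hz)
      stop("custom band needs 0 < low_hz < high_hz")
  }
  list(name = name,
       low_hz = if (name == "broadband") NULL else edges[1],
       high_hz = if (name == "broadband") NULL else edges[2])
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, order 4 per
#' direction. Broadband specs pass the input through untouched.
#'
#' @param ts numeric matrix, regions x samples.
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @return filtered matrix, same shape.
#' @export
bandpass <- function(ts, band, fs, order = 4) {
  stopifnot(is.matrix(ts))
  if (band$name == "broadband") return(ts)
  if (band$high_hz >= fs / 2)
    stop("band upper edge (", band$high_hz, " Hz) at or above Nyquist (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / (fs / 2),
                       type = "pass")
  out <- t(apply(ts, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(ts)
  out
}

#' Symmetric orthogonalization
#'
#' Finds the set of signals closest (in least squares) to the input whose
#' zero-lag correlations are exactly zero, treating all channels
#' symmetrically rather than sequentially: with row-demeaned data `X`
#' (regions x samples), the symmetric orthogonalizer is
#' \eqn{Y = (X X^T)^{-1/2} X} up to per-channel rescaling, i.e. the unitary
#' polar factor of `X`. Used to remove spurious zero-lag correlations
#' (signal leakage) before envelope extraction.
#'
#' @param ts numeric matrix, regions x samples, `n_samples > n_regions`.
#' @param rank_tol relative singular-value tolerance for rank checking.
#' @return matrix of the same shape with (numerically) zero pairwise
#'   zero-lag correlations; each output row is rescaled to its input norm.
#' @export
symmetric_orthogonalize <- function(ts, rank_tol = 1e-10) {
  stopifnot(is.matrix(ts))
  N <- nrow(ts); n <- ncol(ts)
  if (n <= N) stop("n_samples must exceed n_regions")
  X <- ts - rowMeans(ts)
  sv <- svd(X)
  rel <- sv$d / sv$d[1]
  if (any(rel < rank_tol)) {
    bad <- which(abs(sv$u[, which(rel < rank_tol)[1]]) ==
                   max(abs(sv$u[, which(rel < rank_tol)[1]])))
    stop("rank-deficient input: channel(s) collinear (e.g. channel ",
         paste(bad, collapse = ", "), ")")
  }
  Y <- sv$u %*% t(sv$v)                  # orthonormal rows, closest to X
  scale <- sqrt(rowSums(X^2) / rowSums(Y^2))
  out <- Y * scale                       # restore per-channel amplitude
  dimnames(out) <- dimnames(ts)
  out
}

#' Analytic-signal amplitude envelope
#'
#' Magnitude of the analytic signal of each channel, computed via the
#' frequency-domain Hilbert transform: negative frequencies zeroed,
#' positive frequencies doubled. The envelope of `A*sin(2*pi*f*t)` is `A`
#' away from the edges, and the envelope is invariant to sign flips.
#'
#' @param ts numeric matrix, regions x samples (or a vector).
#' @return non-negative matrix of the same shape.
#' @export
hilbert_envelope <- function(ts) {
  vec <- is.null(dim(ts))
  if (vec) ts <- matrix(ts, nrow = 1)
  if (!all(is.finite(ts))) stop("input must be finite")
  n <- ncol(ts)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else             { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Fx <- stats::mvfft(t(ts)) * h
  env <- Mod(t(stats::mvfft(Fx, inverse = TRUE) / n))
  dimnames(env) <- dimnames(ts)
  if (vec) drop(env) else env
}

#' Epoch a continuous recording and demean per epoch
#'
#' Cuts a regions x samples matrix into consecutive non-overlapping epochs
#' of `epoch_length_s` seconds, dropping any trailing partial epoch, and
#' subtracts each region's within-epoch mean. Demeaned epochs are the input
#' expected by the lagged-correlation estimator.
#'
#' @param ts numeric matrix, regions x samples.
#' @param fs sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds (default 2).
#' @return an [envelope_epochs()] object (demeaned, so values may be
#'   negative even for envelope input).
#' @export
epoch_and_demean <- function(ts, fs, epoch_length_s = 2) {
  stopifnot(is.matrix(ts))
  len <- round(fs * epoch_length_s)
  ne <- floor(ncol(ts) / len)
  if (ne < 1L) stop("input shorter than one epoch (", len, " samples)")
  N <- nrow(ts)
  vals <- array(0, dim = c(ne, N, len))
  for (e in seq_len(ne)) {
    seg <- ts[, ((e - 1) * len + 1):(e * len), drop = FALSE]
    vals[e, , ] <- seg - rowMeans(seg)
  }
  envelope_epochs(vals, fs = fs,
                  region_labels = rownames(ts) %||% paste0("R", seq_len(N)),
                  epoch_length_s = epoch_length_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Envelope construction front-end
#'
#' Chains the preparation steps on an already source-localized regions x
#' samples recording: optional band-pass, optional symmetric
#' orthogonalization (applied to filtered data), Hilbert envelope, epoching
#' with per-epoch demeaning. The broadband path skips both the filter and,
#' by default, the orthogonalization.
#'
#' @param ts regions x samples matrix.
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()]; default broadband.
#' @param orthogonalize logical; default TRUE for narrowband bands, FALSE
#'   for broadband.
#' @param epoch_length_s epoch duration (default 2 s).
#' @return an [envelope_epochs()] object.
#' @export
prepare_envelopes <- function(ts, fs, band = band_spec("broadband"),
                              orthogonalize = band$name != "broadband",
                              epoch_length_s = 2) {
  x <- bandpass(ts, band, fs)
  if (orthogonalize) x <- symmetric_orthogonalize(x)
  env <- hilbert_envelope(x)
  epoch_and_demean(env, fs, epoch_length_s)
}
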