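#' Sliding-window hierarchy-metric timeseries
#'
#' Evaluates a hierarchy metric (irreversibility, hierarchical coherence,
#' or inhomogeneity) in overlapping windows inside each epoch. Windows
#' never straddle epoch boundaries — epochs are temporally discontinuous
#' after artifact rejection, and a window across a cut would manufacture
#' spurious dynamics — so the result concatenates per-epoch window blocks
#' in recording order. Each window is demeaned before the metric is
#' computed. With 2-s epochs, 1-s windows and 80% overlap there are six
#' windows per epoch (starts 0, 0.2, ..., 1.0 s).
#'
#' @param env an [envelope_epochs()] dataset.
#' @param metric `"irreversibility"`, `"coherence"` or `"inhomogeneity"`.
#' @param tau lag in samples (must be below the window length).
#' @param percentile threshold percentile.
#' @param window_s window length in seconds (default 1).
#' @param overlap fractional overlap in `[0, 1)` (default 0.8).
#' @param mode asymmetry summary mode for coherence/inhomogeneity.
#' @return object of class `metric_timeseries`: `values`, `start_s`
#'   (window start within the recording), `epoch` (source epoch index),
#'   `metric`, `window_s`, `step_s`.
#' @export
sliding_metric <- function(env, metric = c("irreversibility", "coherence",
                                           "inhomogeneity"),
                           tau, percentile = 95, window_s = 1.0, overlap = 0.8,
                           mode = c("absolute", "signed")) {
  metric <- match.arg(metric); mode <- match.arg(mode)
  stopifnot(inherits(env, "envelope_epochs"))
  fs <- env$fs
  w <- round(window_s * fs)
  ns <- n_samples(env)
  if (w > ns) stop("window longer than epoch")
  if (tau >= w) stop("tau must be smaller than the window length")
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, ns - w + 1L, by = step)
  ne <- n_epochs(env)
  vals <- numeric(0); st <- numeric(0); ep <- integer(0)
  for (e in seq_len(ne)) {
    X <- epoch_matrix(env, e)
    for (s0 in starts) {
      Xi <- X[, s0:(s0 + w - 1L), drop = FALSE]
      m <- corr_matrices(Xi, tau)             # demeans per window
      v <- if (metric == "irreversibility") {
        R <- irrev_matrix(m)
        thresholded_mean(R[upper.tri(R)], percentile)
      } else {
        A <- all_region_asymmetry(m, percentile)
        f <- if (mode == "absolute") abs(A) else A
        if (metric == "coherence") mean(f) else stats::sd(f)
      }
      vals <- c(vals, v); ep <- c(ep, e)
      st <- c(st, (e - 1L) * env$epoch_length_s + (s0 - 1L) / fs)
    }
  }
  structure(list(values = vals, start_s = st, epoch = ep, metric = metric,
                 window_s = window_s, step_s = step / fs),
            class = "metric_timeseries")
}

#' Embedding delay from the first minimum of mutual information
#'
#' Scans the histogram mutual information between `x(t)` and
#' `x(t + tau_RN)` for `tau_RN = 1..max_delay` and returns the first local
#' minimum — the lag at which the shifted series stops being redundant
#' with the original. If the curve has no local minimum the argmin is
#' returned with a warning.
#'
#' @param ts a `metric_timeseries` or numeric vector.
#' @param max_delay largest delay scanned; default half the series length.
#' @param n_bins histogram bins per axis (default 10).
#' @return integer delay (in samples of the metric timeseries), with the
#'   scanned MI curve as attribute `"mi"`.
#' @export
mi_delay <- function(ts, max_delay = NULL, n_bins = 10L) {
  x <- if (inherits(ts, "metric_timeseries")) ts$values else as.numeric(ts)
  if (stats::sd(x) == 0) stop("constant series: delay undefined")
  Tn <- length(x)
  if (is.null(max_delay)) max_delay <- floor(Tn / 2)
  max_delay <- min(max_delay, Tn - 2L)
  stopifnot(max_delay >= 1L)
  mi <- vapply(seq_len(max_delay), function(d)
    hist_mi(x[seq_len(Tn - d)], x[(d + 1):Tn], n_bins), numeric(1))
  locmin <- which(diff(sign(diff(c(hist_mi(x, x, n_bins), mi)))) > 0)
  out <- if (length(locmin)) locmin[1] else {
    warning("no local minimum of mutual information; returning the argmin")
    which.min(mi)
  }
  structure(as.integer(out), mi = mi)
}

# Equal-width 2D histogram mutual information (natural log).
hist_mi <- function(x, y, n_bins) {
  bx <- cut(x, breaks = n_bins, labels = FALSE)
  by <- cut(y, breaks = n_bins, labels = FALSE)
  j <- table(bx, by) / length(x)
  px <- rowSums(j); py <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log(j[nz] / outer(px, py)[nz]))
}

# Delay-embed a series: rows are [x(t), x(t + tau), ..., x(t + (m-1) tau)].
delay_embed <- function(x, m, tau) {
  Tn <- length(x)
  npts <- Tn - (m - 1L) * tau
  if (npts < 2L) stop("series too short for this embedding")
  out <- vapply(seq_len(m), function(d) x[((d - 1L) * tau + 1L):((d - 1L) * tau + npts)],
                numeric(npts))
  if (is.null(dim(out))) out <- matrix(out, ncol = m)
  out
}

#' Embedding dimension by false nearest neighbours
#'
#' For each dimension `m`, finds every point's nearest neighbour in the
#' `m`-dimensional delay embedding and flags the pair as false neighbours
#' if their distance in dimension `m + 1` is more than twice their
#' distance in dimension `m`. The optimal dimension minimizes the number
#' of false neighbours (ties resolve to the smallest `m`).
#'
#' @param ts a `metric_timeseries` or numeric vector.
#' @param tau_RN embedding delay (e.g. from [mi_delay()]).
#' @param m_max largest dimension scanned (default 10).
#' @return integer `m_optimal`, with the per-dimension false-neighbour
#'   counts as attribute `"fnn"`.
#' @export
fnn_dimension <- function(ts, tau_RN, m_max = 10L) {
  x <- if (inherits(ts, "metric_timeseries")) ts$values else as.numeric(ts)
  if (length(x) - m_max * tau_RN < 2L)
    stop("series too short for m_max embedding at this delay")
  fnn <- integer(m_max - 1L)
  for (m in seq_len(m_max - 1L)) {
    # common point set so each point exists in both m and m+1 dims
    Ebig <- delay_embed(x, m + 1L, tau_RN)
    Em <- Ebig[, seq_len(m), drop = FALSE]
    D <- as.matrix(stats::dist(Em))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    dm <- D[cbind(seq_len(nrow(D)), nn)]
    dm1 <- sqrt(dm^2 + (Ebig[, m + 1L] - Ebig[nn, m + 1L])^2)
    fnn[m] <- sum(dm1 > 2 * dm)
  }
  structure(which.min(fnn), fnn = fnn)
}

#' Recurrence network at the connectivity threshold
#'
#' Builds the recurrence network of a set of phase-space points: two
#' timepoints are linked if their Euclidean distance is at most
#' `epsilon`, and `epsilon` is chosen as the smallest pairwise distance at
#' which the network forms a single connected component (incrementally
#' increasing thresholds until connectivity). The recurrence rate is the
#' network's edge density.
#'
#' @param points numeric matrix of embedded points (rows), or a numeric
#'   vector of 1-D points.
#' @return object of class `recurrence_net`: `epsilon`, `adjacency`
#'   (binary, symmetric, zero diagonal), `recurrence_rate`.
#' @export
recurrence_network <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  Tn <- nrow(points)
  if (Tn < 2L) stop("at least two points are required")
  D <- as.matrix(stats::dist(points))
  cand <- sort(unique(D[upper.tri(D)]))
  # binary search over candidate thresholds for the connectivity transition
  lo <- 1L; hi <- length(cand)
  if (cand[1] == 0 && all(D[upper.tri(D)] == 0)) {
    eps <- 0
  } else {
    connected_at <- function(eps) {
      Adj <- D <= eps; diag(Adj) <- FALSE
      # BFS from point 1
      seen <- logical(Tn); seen[1] <- TRUE; frontier <- 1L
      while (length(frontier)) {
        nb <- which(Reduce(`|`, lapply(frontier, function(i) Adj[i, ])) & !seen)
        seen[nb] <- TRUE; frontier <- nb
      }
      all(seen)
    }
    if (!connected_at(cand[hi])) stop("graph cannot be connected")  # unreachable
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (connected_at(cand[mid])) hi <- mid else lo <- mid + 1L
    }
    eps <- cand[lo]
  }
  Adj <- (D <= eps); diag(Adj) <- FALSE
  rr <- sum(Adj) / (Tn * (Tn - 1))
  structure(list(epsilon = eps, adjacency = Adj * 1L, recurrence_rate = rr),
            class = "recurrence_net")
}

#' @export
print.recurrence_net <- function(x, ...) {
  cat("<recurrence_net> ", nrow(x$adjacency), " points, epsilon = ",
      signif(x$epsilon, 4), ", recurrence rate = ",
      signif(x$recurrence_rate, 4), "\n", sep = "")
  invisible(x)
}

#' Recurrence rate of a metric timeseries
#'
#' Convenience wrapper chaining [mi_delay()], [fnn_dimension()],
#' [delay_embed()] and [recurrence_network()].
#'
#' @param ts a `metric_timeseries` or numeric vector.
#' @param m_max largest embedding dimension scanned.
#' @return scalar recurrence rate, with `tau_RN`, `m` and the network as
#'   attributes.
#' @export
metric_recurrence_rate <- function(ts, m_max = 10L) {
  x <- if (inherits(ts, "metric_timeseries")) ts$values else as.numeric(ts)
  tau_RN <- as.integer(mi_delay(x))
  m_cap <- max(2L, min(m_max, floor((length(x) - 2L) / max(1L, tau_RN))))
  m <- as.integer(fnn_dimension(x, tau_RN, m_max = m_cap))
  net <- recurrence_network(delay_embed(x, m, tau_RN))
  structure(net$recurrence_rate, tau_RN = tau_RN, m = m, net = net)
}

#' Coherent phase-randomization surrogates
#'
#' Generates surrogate envelope epochs that destroy the temporal dynamics
#' while preserving the second-order (cross-spectral) structure, epoch by
#' epoch:
#' \describe{
#'   \item{`common_phase`}{one random phase per frequency is multiplied
#'     into *every* channel's spectrum. Cross-spectra — and hence the full
#'     circular cross-correlation function — are preserved exactly.}
#'   \item{`cholesky_csd`}{new realizations are drawn from the Cholesky
#'     factor of the per-frequency cross-spectral density matrix with
#'     independent random phases per channel; cross-spectra are preserved
#'     in expectation. Singular CSDs are ridge-regularized.}
#' }
#' Hermitian symmetry is preserved so the output is real-valued.
#'
#' @param env an [envelope_epochs()] dataset (epoch length >= 8).
#' @param method `"common_phase"` (default) or `"cholesky_csd"`.
#' @param seed integer seed.
#' @return surrogate [envelope_epochs()] (values may be negative: the
#'   surrogate preserves spectra, not marginals).
#' @export
coherent_phase_surrogate <- function(env, method = c("common_phase",
                                                     "cholesky_csd"),
                                     seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(env, "envelope_epochs"))
  ns <- n_samples(env)
  if (ns < 8L) stop("epochs must have at least 8 samples")
  ne <- n_epochs(env); N <- n_regions(env)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- if (ns %% 2 == 0) ns / 2 - 1 else (ns - 1) / 2  # free frequencies
  out <- env$values
  for (e in seq_len(ne)) {
    X <- t(epoch_matrix(env, e))              # samples x regions
    Fx <- stats::mvfft(X)
    if (method == "common_phase") {
      phi <- stats::runif(half, 0, 2 * pi)
      rot <- rep(1 + 0i, ns)
      rot[2:(half + 1)] <- exp(1i * phi)
      rot[ns:(ns - half + 1)] <- Conj(rot[2:(half + 1)])
      Fy <- Fx * rot
    } else {
      Fy <- Fx
      for (k in 2:(half + 1)) {
        S <- tcrossprod(Fx[k, ], Conj(Fx[k, ]))        # rank-1 CSD estimate
        delta <- 1e-10 * max(Re(sum(diag(S))), .Machine$double.eps) / N
        eg <- eigen(S + diag(delta + 0i, N), symmetric = TRUE)
        lam <- pmax(Re(eg$values), 0)
        L <- eg$vectors %*% diag(sqrt(lam), N)         # L %*% Conj(t(L)) = S
        z <- exp(1i * stats::runif(N, 0, 2 * pi))
        Fy[k, ] <- as.vector(L %*% z)
        Fy[ns - k + 2, ] <- Conj(Fy[k, ])
      }
    }
    Y <- Re(stats::mvfft(Fy, inverse = TRUE) / ns)
    out[e, , ] <- t(Y)
  }
  envelope_epochs(out, fs = env$fs, region_labels = env$region_labels,
                  epoch_length_s = env$epoch_length_s)
}

#' Compare recurrence rates between drug levels, true vs surrogate
#'
#' For every dataset in a paired cohort, computes the sliding-window
#' metric timeseries and its recurrence rate, and the same for coherent
#' phase-randomized surrogates (dynamics destroyed, cross-correlations
#' preserved: the static null). Paired permutation tests per condition
#' contrast the drug levels on true and surrogate recurrence rates, so a
#' genuinely dynamical effect shows a stronger contrast on the true series
#' than under the static null.
#'
#' @param datasets named list of [envelope_epochs()] keyed
#'   `"participant|drug|condition"` (e.g. from [make_cohort()]).
#' @param design the [study_design()].
#' @param metric,tau,percentile,window_s,overlap passed to
#'   [sliding_metric()].
#' @param surrogate_method passed to [coherent_phase_surrogate()].
#' @param n_surrogates surrogates per dataset (their RRs are averaged).
#' @param n_perm permutations for the paired tests.
#' @param seed integer seed.
#' @return list of class `dynamics_comparison`: `rr` (long data.frame
#'   with participant, drug, condition, rr_true, rr_surrogate), `tests`
#'   (per condition: p_true, p_surrogate).
#' @export
dynamics_compare <- function(datasets, design, metric = "irreversibility",
                             tau, percentile = 95, window_s = 1.0,
                             overlap = 0.8,
                             surrogate_method = "common_phase",
                             n_surrogates = 1L, n_perm = 1000L, seed = 1L) {
  grid <- design_grid(design)
  key <- paste(grid$participant, grid$drug, grid$condition, sep = "|")
  missing_keys <- setdiff(key, names(datasets))
  if (length(missing_keys))
    stop("missing datasets: ", paste(utils::head(missing_keys, 5), collapse = ", "))
  rr_true <- rr_sur <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    env <- datasets[[key[k]]]
    ts <- sliding_metric(env, metric, tau, percentile, window_s, overlap)
    rr_true[k] <- as.numeric(metric_recurrence_rate(ts))
    srr <- vapply(seq_len(n_surrogates), function(si) {
      se <- coherent_phase_surrogate(env, surrogate_method,
                                     seed = seed + 7919L * k + si)
      sts <- sliding_metric(se, metric, tau, percentile, window_s, overlap)
      as.numeric(metric_recurrence_rate(sts))
    }, numeric(1))
    rr_sur[k] <- mean(srr)
  }
  rr <- cbind(grid, rr_true = rr_true, rr_surrogate = rr_sur)
  control <- design$drug_levels[1]
  tests <- do.call(rbind, lapply(design$condition_levels, function(cond) {
    sub <- rr[rr$condition == cond, ]
    a_t <- sub$rr_true[sub$drug != control][order(sub$participant[sub$drug != control])]
    b_t <- sub$rr_true[sub$drug == control][order(sub$participant[sub$drug == control])]
    a_s <- sub$rr_surrogate[sub$drug != control][order(sub$participant[sub$drug != control])]
    b_s <- sub$rr_surrogate[sub$drug == control][order(sub$participant[sub$drug == control])]
    data.frame(condition = cond,
               p_true = paired_permutation(a_t, b_t, n_perm, seed)$p,
               p_surrogate = paired_permutation(a_s, b_s, n_perm, seed)$p)
  }))
  structure(list(rr = rr, tests = tests), class = "dynamics_comparison")
}
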