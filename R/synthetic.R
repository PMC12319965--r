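#' Directed coupling graph with controllable asymmetry
#'
#' Constructs the weight matrix of a stable linear stochastic recurrence
#' whose time-reversal asymmetry is controlled by a single dial
#' `kappa` in `[0, 1]`. The coupling backbone is a directed ring through a
#' seeded random ordering of the regions with random edge weights, plus a
#' weak symmetric random background. The ring enters as the convex mixture
#' `(1 - kappa) * reciprocated + kappa * one-directional`, so at
#' `kappa = 0` the full coupling matrix is exactly symmetric — a
#' detailed-balance (time-reversible) process — and the forward/backward
#' weight difference of every ring edge grows linearly in `kappa`. The
#' coupling acts at `coupling_lag` samples, giving the directional signal
#' a known propagation delay. The system is rescaled (coupling only, so
#' the autoregressive timescale is identical across `kappa`) until the
#' companion-form spectral radius is at most `target_radius < 1`.
#'
#' @param n_regions number of channels.
#' @param kappa asymmetry dial in `[0, 1]`.
#' @param coupling_lag delay (samples) at which coupling acts (default 1).
#' @param ar self-coupling (autoregressive) coefficient (default 0.5).
#' @param coupling_gain total incoming coupling weight per region before
#'   stabilization (default 0.8).
#' @param background relative weight of the symmetric random background
#'   coupling (default 0.3).
#' @param target_radius spectral-radius cap (default 0.95).
#' @param seed integer seed for the random structure.
#' @return object of class `coupling_graph` with elements `A` (lag-1
#'   self-coupling, diagonal), `C` (coupling at `coupling_lag`, entry
#'   `C[i, j]` = influence of region j on region i), `kappa`,
#'   `coupling_lag`, `spectral_radius`.
#' @export
coupling_graph <- function(n_regions, kappa, coupling_lag = 1L, ar = 0.5,
                           coupling_gain = 0.8, background = 0.3,
                           target_radius = 0.95, seed = 1L) {
  stopifnot(n_regions >= 2, kappa >= 0, kappa <= 1, coupling_lag >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample(n_regions)                              # ring through random order
  nxt <- ord[c(2:n_regions, 1)]
  Wf <- matrix(0, n_regions, n_regions)
  Wf[cbind(nxt, ord)] <- stats::runif(n_regions, 0.5, 1) # edge ord[k] -> nxt[k]
  Wsym <- (Wf + t(Wf)) / 2
  B <- matrix(stats::runif(n_regions^2), n_regions); diag(B) <- 0
  Wbg <- (B + t(B)) / 2
  Wbg <- Wbg / max(rowSums(Wbg))
  W <- (1 - kappa) * Wsym + kappa * Wf + background * Wbg
  W <- coupling_gain * W / max(rowSums(W))              # normalize coupling mass
  A <- diag(ar, n_regions)
  g <- structure(list(A = A, C = W, kappa = kappa,
                      coupling_lag = as.integer(coupling_lag),
                      n_regions = n_regions),
                 class = "coupling_graph")
  if (ar >= target_radius) stop("ar must be below target_radius")
  rho <- companion_radius(g)
  it <- 0L
  while (rho > target_radius && it < 100L) {
    # shrink only the coupling, keeping the AR timescale identical across
    # kappa; the radius is monotone in |C| and tends to ar as C -> 0
    g$C <- g$C * min(0.95, target_radius / rho)
    rho <- companion_radius(g)
    it <- it + 1L
  }
  if (rho >= 1) stop("unstable coupling graph (spectral radius ", round(rho, 3), ")")
  g$spectral_radius <- rho
  g
}

# Spectral radius of the companion form of x(t) = A x(t-1) + C x(t-lag).
companion_radius <- function(g) {
  N <- g$n_regions; L <- max(1L, g$coupling_lag)
  M <- matrix(0, N * L, N * L)
  M[1:N, 1:N] <- g$A
  M[1:N, ((L - 1) * N + 1):(L * N)] <- M[1:N, ((L - 1) * N + 1):(L * N)] + g$C
  if (L > 1) M[(N + 1):(N * L), 1:(N * (L - 1))] <- diag(N * (L - 1))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# Save/restore .Random.seed so seeded generators do not disturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Coupling graph from an explicit weight matrix
#'
#' Wraps a user-supplied coupling matrix (entry `[i, j]` = influence of
#' region j on region i at `coupling_lag`) with an autoregressive
#' self-coupling. Unlike [coupling_graph()], no rescaling is applied: an
#' unstable system is an error.
#'
#' @param C square coupling matrix, zero diagonal.
#' @param ar autoregressive self-coupling (default 0.5).
#' @param coupling_lag coupling delay in samples (default 1).
#' @return a `coupling_graph` object.
#' @export
coupling_graph_matrix <- function(C, ar = 0.5, coupling_lag = 1L) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  g <- structure(list(A = diag(ar, nrow(C)), C = C,
                      kappa = NA_real_, coupling_lag = as.integer(coupling_lag),
                      n_regions = nrow(C)),
                 class = "coupling_graph")
  rho <- companion_radius(g)
  if (rho >= 1)
    stop("unstable coupling graph (spectral radius ", round(rho, 3), " >= 1)")
  g$spectral_radius <- rho
  g
}

#' Simulate envelope-like epochs from a coupling graph
#'
#' Runs the linear stochastic recurrence
#' `x(t) = A x(t-1) + C x(t-lag) + eta(t)` with Gaussian innovations and
#' uses it as the slow amplitude modulation of a per-channel oscillatory
#' carrier: `y_i(t) = (offset + x_i(t)) * cos(2*pi*f_c*t + phi_i)`. The
#' magnitude of the analytic signal of `y` then recovers an envelope that
#' fluctuates (up to the rare excursions below zero that the offset makes
#' negligible) exactly like the latent recurrence, so the directional
#' asymmetry imposed through `C` is carried into the lagged
#' cross-correlations of the envelopes — the quantity the analysis
#' measures. `carrier_hz = 0` skips the carrier and returns the analytic
#' magnitude of the recurrence itself. A burn-in is discarded and the
#' envelope is split into fixed-length epochs; demeaning is left to
#' downstream stages.
#'
#' @param graph a [coupling_graph()] or [coupling_graph_matrix()].
#' @param n_epochs number of epochs to produce.
#' @param fs sampling rate in Hz (default 200).
#' @param epoch_length_s epoch duration (default 2 s).
#' @param noise_sd innovation standard deviation (default 1).
#' @param seed integer seed.
#' @param burn_in samples discarded before recording (default 400).
#' @param carrier_hz carrier frequency (default 40 Hz; 0 = no carrier).
#' @param offset_k carrier amplitude offset in units of the modulation's
#'   standard deviation (default 4).
#' @return an [envelope_epochs()] object (non-negative values).
#' @export
simulate_network_timeseries <- function(graph, n_epochs, fs = 200,
                                        epoch_length_s = 2, noise_sd = 1,
                                        seed = 1L, burn_in = 400L,
                                        carrier_hz = 40, offset_k = 4) {
  stopifnot(inherits(graph, "coupling_graph"), n_epochs >= 1)
  if (companion_radius(graph) >= 1) stop("unstable coupling graph")
  N <- graph$n_regions
  len <- round(fs * epoch_length_s)
  Tn <- n_epochs * len + burn_in
  if (Tn < 2 * len) stop("total simulated length must cover at least two epochs")
  L <- graph$coupling_lag
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eta <- matrix(stats::rnorm(N * (Tn + L), sd = noise_sd), N)
  X <- matrix(0, N, Tn + L)
  a <- diag(graph$A)
  for (t in (L + 1):(Tn + L))
    X[, t] <- a * X[, t - 1] + graph$C %*% X[, t - L] + eta[, t]
  X <- X[, (L + burn_in + 1):(Tn + L), drop = FALSE]
  X <- X / stats::sd(X)
  if (carrier_hz > 0) {
    phi <- stats::runif(N, 0, 2 * pi)
    tt <- seq_len(ncol(X)) / fs
    Y <- (offset_k + X) * t(cos(outer(2 * pi * carrier_hz * tt, phi, "+")))
  } else {
    Y <- X
  }
  env <- hilbert_envelope(Y)
  vals <- array(0, dim = c(n_epochs, N, len))
  for (e in seq_len(n_epochs)) vals[e, , ] <- env[, ((e - 1) * len + 1):(e * len)]
  envelope_epochs(vals, fs = fs, epoch_length_s = epoch_length_s)
}

#' Cohort specification for the synthetic study grid
#'
#' @param n_subjects number of participants.
#' @param drug_effect multiplicative reduction `delta` in `[0, 1]` of the
#'   coupling asymmetry under the drug level (`kappa_drug =
#'   kappa_s * (1 - delta)`).
#' @param kappa_mean,kappa_sd between-subject distribution of the control
#'   asymmetry (truncated to `[0, 1]`).
#' @param n_regions,n_epochs,fs,epoch_length_s dataset geometry (defaults:
#'   8 regions, 30 epochs, 200 Hz, 2 s — small fixture scale with the
#'   study's epoch geometry).
#' @param coupling_lag propagation delay of the directed coupling (samples).
#' @param noise_sd innovation sd.
#' @param seed master seed; per-dataset seeds are derived deterministically.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16L, drug_effect = 0.8,
                        kappa_mean = 0.6, kappa_sd = 0.1,
                        n_regions = 8L, n_epochs = 30L, fs = 200,
                        epoch_length_s = 2, coupling_lag = 4L,
                        noise_sd = 1, seed = 1L) {
  if (drug_effect < 0 || drug_effect > 1) stop("drug_effect must be in [0, 1]")
  stopifnot(n_subjects >= 1, n_regions >= 2, n_epochs >= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' One envelope dataset per (participant, drug, condition) cell of the
#' design. Each subject draws a control asymmetry `kappa_s`; the drug
#' sessions use `kappa_s * (1 - drug_effect)`; the subject's coupling
#' structure is shared between sessions and all else (noise, geometry) is
#' matched. Conditions are independent realizations of the same
#' subject-level process.
#'
#' @param spec a [cohort_spec()].
#' @param design a [study_design()]; defaults to `n_subjects` participants
#'   x control/drug x the four standard conditions.
#' @return named list of [envelope_epochs()], keyed
#'   `"participant|drug|condition"`, with attributes `design`, `kappa`
#'   (per-subject control values) and `grid` (data.frame).
#' @export
make_cohort <- function(spec, design = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(design))
    design <- study_design(sprintf("S%02d", seq_len(spec$n_subjects)))
  if (length(design$participant_ids) != spec$n_subjects)
    stop("design has ", length(design$participant_ids),
         " participants but spec says ", spec$n_subjects)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  kappa_s <- pmin(1, pmax(0, stats::rnorm(spec$n_subjects, spec$kappa_mean,
                                          spec$kappa_sd)))
  names(kappa_s) <- design$participant_ids
  grid <- design_grid(design)
  out <- vector("list", nrow(grid))
  names(out) <- paste(grid$participant, grid$drug, grid$condition, sep = "|")
  control <- design$drug_levels[1]
  for (k in seq_len(nrow(grid))) {
    p_i <- match(grid$participant[k], design$participant_ids)
    c_i <- match(grid$condition[k], design$condition_levels)
    is_drug <- grid$drug[k] != control
    kap <- if (is_drug) kappa_s[p_i] * (1 - spec$drug_effect) else kappa_s[p_i]
    g <- coupling_graph(spec$n_regions, kappa = kap,
                        coupling_lag = spec$coupling_lag,
                        seed = spec$seed + 1000L * p_i)   # structure shared per subject
    ds_seed <- spec$seed + 1000L * p_i + 10L * c_i + is_drug
    out[[k]] <- simulate_network_timeseries(
      g, n_epochs = spec$n_epochs, fs = spec$fs,
      epoch_length_s = spec$epoch_length_s, noise_sd = spec$noise_sd,
      seed = ds_seed)
  }
  attr(out, "design") <- design
  attr(out, "grid") <- grid
  attr(out, "kappa") <- kappa_s
  out
}

#' Four-node toy networks illustrating hierarchy
#'
#' Four weighted directed networks on four nodes arranged in a ring.
#' Network 1 has every ring edge reciprocated with equal weight 1, so each
#' node's in-strength equals its out-strength: the network is irreversible
#' yet completely non-hierarchical. Network 2 removes one direction of one
#' reciprocal pair, leaving a single directed edge of weight 1, so exactly
#' two nodes become in/out imbalanced. Networks 3 and 4 scale that directed
#' edge by 2 and 0.5 respectively.
#'
#' @return list of four `toy_network` objects, each with `nodes` (labels)
#'   and `weights` (4 x 4 matrix, `weights[u, v]` = edge u -> v).
#' @export
toy_networks <- function() {
  nodes <- c("TL", "TR", "BR", "BL")          # ring: TL-TR-BR-BL-TL
  ring <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  W1 <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(ring))) {
    W1[ring[k, 1], ring[k, 2]] <- 1
    W1[ring[k, 2], ring[k, 1]] <- 1
  }
  flip <- function(W, w) { W[2, 1] <- 0; W[1, 2] <- w; W }  # TR->TL removed
  W2 <- flip(W1, 1); W3 <- flip(W1, 2); W4 <- flip(W1, 0.5)
  lapply(list(W1, W2, W3, W4), function(W)
    structure(list(nodes = nodes, weights = W), class = "toy_network"))
}

#' Lagged-correlation surrogate of a toy network
#'
#' Maps a toy network's weights directly onto a forward lagged-correlation
#' matrix (`Cf[u, v]` proportional to the u -> v weight, scaled into
#' `[0, 1]`), with the reversed matrix as its transpose — the idealized
#' correlation structure the network would induce, for exercising the
#' hierarchy metrics without simulation noise.
#'
#' @param net a `toy_network` from [toy_networks()].
#' @param tau_samples nominal lag recorded in the result (default 1).
#' @return a `lagged_corr_matrices` object.
#' @export
toy_corr_matrices <- function(net, tau_samples = 1L) {
  stopifnot(inherits(net, "toy_network"))
  Cf <- net$weights / max(net$weights, 1)
  diag(Cf) <- 1
  structure(list(Cf = Cf, Cr = t(Cf), tau_samples = as.integer(tau_samples)),
            class = "lagged_corr_matrices")
}

#' Synthetic brain map with controlled spatial autocorrelation
#'
#' Draws a Gaussian random field over region centroids with exponential
#' spatial covariance `exp(-d / correlation_length)`, the canonical smooth
#' map fixture for spatial-null testing. As `correlation_length -> 0` the
#' values become i.i.d. (flat variogram).
#'
#' @param centroids N x 3 matrix of coordinates in mm (N >= 10).
#' @param correlation_length e-folding length of the covariance, in mm.
#' @param seed integer seed.
#' @param labels optional region labels.
#' @return a [brain_map()] object.
#' @export
make_synthetic_map <- function(centroids, correlation_length, seed = 1L,
                               labels = NULL) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 3)
  N <- nrow(centroids)
  if (N < 10) stop("at least 10 regions are required")
  if (correlation_length <= 0) stop("correlation_length must be positive")
  D <- as.matrix(stats::dist(centroids))
  Sig <- exp(-D / correlation_length)
  L <- chol(Sig + diag(1e-9, N))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- drop(t(L) %*% stats::rnorm(N))
  if (is.null(labels)) labels <- paste0("R", seq_len(N))
  brain_map(labels, vals, centroids)
}
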