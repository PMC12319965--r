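#' Incoming-outgoing asymmetry of one region
#'
#' Lagged correlations define, at every region, an outgoing component (the
#' region leading each partner: the forward row `Cf[region, ]`) and an
#' incoming component (each partner leading the region: the reversed row,
#' i.e. `Cf[, region]`). The squared off-diagonal entries of both rows are
#' concatenated into one vector of connection magnitudes, thresholded at
#' the vector's own percentile (ties dropped), surviving *outgoing*
#' magnitudes are negated, and the signed survivors are averaged. A region
#' whose strongest surviving connections are predominantly incoming gets a
#' positive asymmetry; predominantly outgoing gives a negative one; exactly
#' symmetric correlation matrices give zero for every region. Returns 0
#' when nothing survives thresholding.
#'
#' @param m a `lagged_corr_matrices` object.
#' @param region region index.
#' @param percentile threshold percentile in `[0, 100)` (95 in the
#'   standard analysis).
#' @return scalar signed asymmetry.
#' @export
region_asymmetry <- function(m, region, percentile = 95) {
  stopifnot(inherits(m, "lagged_corr_matrices"))
  N <- nrow(m$Cf)
  if (region < 1 || region > N) stop("region index out of range")
  outgoing <- m$Cf[region, -region]^2
  incoming <- m$Cr[region, -region]^2   # = Cf[-region, region]^2
  conc <- c(incoming, outgoing)
  thr <- stats::quantile(conc, percentile / 100, names = FALSE, type = 7)
  keep <- conc > thr
  if (!any(keep)) return(0)
  signed <- c(incoming, -outgoing)
  mean(signed[keep])
}

# Vectorized per-epoch asymmetry across all regions: Cf2 = Cf^2, region r's
# outgoing = row r, incoming = column r (off-diagonal), concatenation per
# region as a 2(N-1) x N matrix, thresholded columnwise.
all_region_asymmetry <- function(m, percentile) {
  Cf2 <- m$Cf^2
  N <- nrow(Cf2)
  off <- row(Cf2) != col(Cf2)
  outg <- matrix(t(Cf2)[off], nrow = N - 1L)  # column r = Cf2[r, -r]
  inc  <- matrix(Cf2[off],    nrow = N - 1L)  # column r = Cf2[-r, r]
  conc <- rbind(inc, outg)
  nr <- nrow(conc); nc <- ncol(conc)
  o <- order(rep(seq_len(nc), each = nr), conc)
  S <- matrix(conc[o], nr, nc)
  h <- (nr - 1) * percentile / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  thr <- S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
  keep <- conc > rep(thr, each = nr)
  signed <- rbind(inc, -outg)
  cnt <- colSums(keep)
  ifelse(cnt > 0, colSums(signed * keep) / pmax(cnt, 1L), 0)
}

#' Asymmetry profile with hierarchical coherence and inhomogeneity
#'
#' Computes the per-region incoming-outgoing asymmetry in every epoch,
#' averages across epochs, and summarizes across regions: the hierarchical
#' coherence is the mean and the hierarchical inhomogeneity the standard
#' deviation of `f(A_region)`, with `f` the identity (`mode = "signed"`)
#' or the absolute value (`mode = "absolute"`, the default — signed
#' asymmetries of a balanced network cancel in the mean even when
#' individual regions are strongly imbalanced).
#'
#' @param env an [envelope_epochs()] dataset.
#' @param tau lag in samples.
#' @param percentile threshold percentile.
#' @param mode `"absolute"` (default) or `"signed"` summary.
#' @param use summation variant, see [lagged_corr()].
#' @return object of class `asymmetry_profile`: `A_region` (named
#'   N-vector, epoch-averaged signed asymmetry), `coherence`,
#'   `inhomogeneity`, `tau_samples`, `percentile`, `mode`.
#' @export
asymmetry_profile <- function(env, tau, percentile = 95,
                              mode = c("absolute", "signed"),
                              use = c("truncated", "circular")) {
  mode <- match.arg(mode); use <- match.arg(use)
  stopifnot(inherits(env, "envelope_epochs"))
  ne <- n_epochs(env); N <- n_regions(env)
  if (ne < 1L) stop("at least one epoch is required")
  A_ep <- matrix(0, ne, N)
  for (e in seq_len(ne)) {
    m <- corr_matrices(epoch_matrix(env, e), tau, use = use)
    A_ep[e, ] <- all_region_asymmetry(m, percentile)
  }
  A_region <- colMeans(A_ep)
  names(A_region) <- env$region_labels
  profile_from_A(A_region, mode, tau, percentile)
}

#' Summaries from a precomputed asymmetry vector
#'
#' @param A_region signed per-region asymmetries.
#' @param mode `"absolute"` or `"signed"`.
#' @param tau_samples,percentile recorded metadata.
#' @return an `asymmetry_profile` object.
#' @export
profile_from_A <- function(A_region, mode = c("absolute", "signed"),
                           tau_samples = NA_integer_, percentile = NA_real_) {
  mode <- match.arg(mode)
  f <- if (mode == "absolute") abs(A_region) else A_region
  structure(list(A_region = A_region,
                 coherence = mean(f),
                 inhomogeneity = stats::sd(f),
                 tau_samples = tau_samples, percentile = percentile,
                 mode = mode),
            class = "asymmetry_profile")
}

#' Asymmetry profile of precomputed correlation matrices
#'
#' Single-matrix analogue of [asymmetry_profile()], used e.g. on the
#' idealized correlation structure of a toy network
#' ([toy_corr_matrices()]).
#'
#' @param m a `lagged_corr_matrices` object.
#' @param percentile threshold percentile.
#' @param mode summary mode.
#' @return an `asymmetry_profile` object.
#' @export
matrix_asymmetry_profile <- function(m, percentile = 95,
                                     mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  A <- all_region_asymmetry(m, percentile)
  names(A) <- rownames(m$Cf)
  profile_from_A(A, mode, m$tau_samples, percentile)
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat("<asymmetry_profile> coherence = ", signif(x$coherence, 4),
      ", inhomogeneity = ", signif(x$inhomogeneity, 4),
      " (", x$mode, " mode, ", length(x$A_region), " regions)\n", sep = "")
  invisible(x)
}
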