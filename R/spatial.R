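#' Regional brain map
#'
#' A scalar value per region plus 3-D centroid coordinates, the unit of
#' exchange for spatial-autocorrelation-aware map comparisons. Maps enter
#' as regional vectors (e.g. receptor density, myelination index,
#' connectivity gradient already averaged within a parcellation).
#'
#' @param region character labels.
#' @param value numeric, one per region, finite.
#' @param centroids N x 3 numeric matrix of coordinates in mm.
#' @return object of class `brain_map`.
#' @export
brain_map <- function(region, value, centroids) {
  region <- as.character(region)
  stopifnot(length(region) == length(value),
            is.matrix(centroids), nrow(centroids) == length(region),
            ncol(centroids) == 3)
  if (!all(is.finite(value))) stop("map values must be finite")
  if (anyDuplicated(region)) stop("region labels must be unique")
  structure(list(region = region, value = as.numeric(value),
                 centroids = centroids),
            class = "brain_map")
}

#' Read a brain map from TSV
#'
#' Expects columns `region`, `value`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path file path.
#' @return a [brain_map()].
#' @export
read_brain_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "value", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d)))
    stop("map TSV must have columns: ", paste(need, collapse = ", "))
  brain_map(d$region, d$value, as.matrix(d[, c("x_mm", "y_mm", "z_mm")]))
}

#' Write a brain map to TSV
#' @param map a [brain_map()].
#' @param path output path.
#' @export
write_brain_map <- function(map, path) {
  stopifnot(inherits(map, "brain_map"))
  d <- data.frame(region = map$region, value = map$value,
                  x_mm = map$centroids[, 1], y_mm = map$centroids[, 2],
                  z_mm = map$centroids[, 3])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical variogram of a brain map
#'
#' Semivariance `0.5 * (v_i - v_j)^2` of all region pairs, binned by
#' centroid distance into equal-count bins. The variogram quantifies the
#' spatial autocorrelation that surrogate maps must reproduce.
#'
#' @param map a [brain_map()].
#' @param n_bins number of equal-count distance bins (default 10).
#' @return data.frame with `distance` (bin mean) and `semivariance`.
#' @export
variogram <- function(map, n_bins = 10L) {
  stopifnot(inherits(map, "brain_map"))
  N <- length(map$value)
  if (N < 10) stop("at least 10 regions are required")
  D <- as.matrix(stats::dist(map$centroids))
  ut <- upper.tri(D)
  d <- D[ut]
  sv <- 0.5 * outer(map$value, map$value, "-")[ut]^2
  bin_variogram(d, sv, n_bins)
}

bin_variogram <- function(d, sv, n_bins) {
  qs <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs <- unique(qs)
  if (length(qs) < n_bins + 1)
    warning("identical distances collapsed ", n_bins + 1 - length(qs), " bin(s)")
  bin <- cut(d, breaks = qs, include.lowest = TRUE, labels = FALSE)
  data.frame(distance = tapply(d, bin, mean),
             semivariance = tapply(sv, bin, mean),
             row.names = NULL)
}

#' Variogram-matched surrogate maps
#'
#' Spatial-autocorrelation-preserving null maps: each surrogate permutes
#' the empirical values, smooths every region's value by an
#' exponential-distance-kernel weighted sum over its k nearest neighbours
#' (kernel scale = the k-th neighbour distance, self-normalizing), picks
#' the k whose surrogate variogram is closest (summed squared difference)
#' to the empirical variogram, and rescales the smoothed map back to the
#' empirical mean and variance.
#'
#' @param map a [brain_map()].
#' @param n number of surrogates (default 1000).
#' @param k_grid candidate neighbourhood sizes (default
#'   `c(3, 5, 8, 13, 21, 34)`, clipped to N - 1).
#' @param n_bins variogram bins.
#' @param seed integer seed.
#' @param rescale rescale surrogates to the empirical mean/variance
#'   (default TRUE).
#' @return object of class `surrogate_ensemble`: `maps` (n x N matrix),
#'   `k` (chosen neighbourhood per surrogate), `objective` (variogram
#'   distance per surrogate), `seed`.
#' @export
variogram_surrogates <- function(map, n = 1000L,
                                 k_grid = c(3, 5, 8, 13, 21, 34),
                                 n_bins = 10L, seed = 1L, rescale = TRUE) {
  stopifnot(inherits(map, "brain_map"))
  N <- length(map$value)
  k_grid <- unique(pmin(as.integer(k_grid), N - 1L))
  if (any(k_grid < 1L)) stop("k_grid entries must be >= 1")
  D <- as.matrix(stats::dist(map$centroids))
  if (any(D[upper.tri(D)] == 0))
    stop("degenerate distances: identical centroids")
  ut <- upper.tri(D); dvec <- D[ut]
  qs <- unique(stats::quantile(dvec, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  bin <- cut(dvec, breaks = qs, include.lowest = TRUE, labels = FALSE)
  emp_vg <- tapply(0.5 * outer(map$value, map$value, "-")[ut]^2, bin, mean)
  # precompute, per k, the row-normalized smoothing weights W_k (N x N)
  ord <- apply(D, 1, order)                      # cols: neighbor order per region
  Wk <- lapply(k_grid, function(k) {
    W <- matrix(0, N, N)
    for (i in seq_len(N)) {
      nb <- ord[, i]; nb <- nb[nb != i][seq_len(k)]
      sc <- D[i, nb[k]]
      w <- exp(-D[i, nb] / sc)
      W[i, nb] <- w / sum(w)
    }
    W
  })
  mu <- mean(map$value); sdv <- stats::sd(map$value)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  maps <- matrix(0, n, N)
  kk <- integer(n); obj <- numeric(n)
  for (s in seq_len(n)) {
    perm <- sample(map$value)
    best <- NULL; best_obj <- Inf; best_k <- NA_integer_
    for (ki in seq_along(k_grid)) {
      sm <- as.vector(Wk[[ki]] %*% perm)
      if (rescale) sm <- (sm - mean(sm)) / stats::sd(sm) * sdv + mu
      vg <- tapply(0.5 * outer(sm, sm, "-")[ut]^2, bin, mean)
      o <- sum((vg - emp_vg)^2)
      if (o < best_obj) { best <- sm; best_obj <- o; best_k <- k_grid[ki] }
    }
    maps[s, ] <- best; kk[s] <- best_k; obj[s] <- best_obj
  }
  structure(list(maps = maps, k = kk, objective = obj, seed = seed,
                 region = map$region),
            class = "surrogate_ensemble")
}

#' Map correlation with a spatial-autocorrelation-preserving null
#'
#' Pearson correlation between two regional maps, with significance
#' assessed against the correlations of `map_a` with each member of a
#' surrogate ensemble built from `map_b`:
#' `p = (1 + #{|r_null| >= |r|}) / (n + 1)` (two-tailed default).
#'
#' @param map_a,map_b [brain_map()]s with identical region labels.
#' @param ensemble a [variogram_surrogates()] ensemble built from `map_b`.
#' @param two_tailed compare absolute correlations (default TRUE).
#' @return list with `r`, `p`, `null_r` (surrogate correlations).
#' @export
spatial_corr_test <- function(map_a, map_b, ensemble, two_tailed = TRUE) {
  stopifnot(inherits(map_a, "brain_map"), inherits(map_b, "brain_map"),
            inherits(ensemble, "surrogate_ensemble"))
  if (!identical(map_a$region, map_b$region))
    stop("region label sets differ between maps")
  if (!identical(ensemble$region, map_b$region))
    stop("ensemble was not built from map_b (labels differ)")
  r <- stats::cor(map_a$value, map_b$value)
  null_r <- as.vector(stats::cor(map_a$value, t(ensemble$maps)))
  n <- length(null_r)
  p <- if (two_tailed) (1 + sum(abs(null_r) >= abs(r))) / (n + 1)
       else (1 + sum(null_r >= r)) / (n + 1)
  list(r = r, p = p, null_r = null_r)
}
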