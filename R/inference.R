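#' Lag selection by grand-mean maximization ("orthogonal contrast")
#'
#' Selects the lag maximizing the mean irreversibility across all datasets
#' (both drug levels, all conditions, all participants), so the selection
#' is orthogonal to any drug contrast tested afterwards. Ties resolve to
#' the smallest lag.
#'
#' @param curves list of `irrev_curve` objects on a common lag grid.
#' @return list of class `tau_selection` with `approach`, `tau_optimal`
#'   (samples), `grand_mean` (curve).
#' @export
select_tau_orthogonal <- function(curves) {
  grid <- common_grid(curves)
  M <- vapply(curves, function(cu) cu$r, numeric(length(grid)))
  gm <- rowMeans(M)
  structure(list(approach = "orthogonal",
                 tau_optimal = grid[which.max(gm)],
                 grand_mean = gm, tau_grid = grid),
            class = "tau_selection")
}

common_grid <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grid <- curves[[1]]$tau_samples
  for (cu in curves)
    if (!identical(cu$tau_samples, grid)) stop("curves are on different lag grids")
  grid
}

#' Counter-balanced participant folds
#'
#' Partitions the dataset grid into folds that group whole participants,
#' so every fold automatically contains both drug levels and every
#' condition in equal proportion and no within-participant pairing leaks
#' across folds. Requires the participant count to be divisible by
#' `n_folds`.
#'
#' @param design a [study_design()].
#' @param n_folds number of folds (default 8).
#' @param seed integer seed for the participant shuffle.
#' @return data.frame: the design grid plus a `fold` column.
#' @export
make_folds <- function(design, n_folds = 8L, seed = 1L) {
  grid <- design_grid(design)
  ids <- design$participant_ids
  if (length(ids) %% n_folds != 0L)
    stop("participant count (", length(ids), ") not divisible by n_folds (",
         n_folds, "): counter-balanced folds unsatisfiable")
  per <- length(ids) / n_folds
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(ids)
  fold_of <- setNames(rep(seq_len(n_folds), each = per), shuffled)
  grid$fold <- unname(fold_of[grid$participant])
  grid
}

#' Cross-validated lag selection for the drug contrast
#'
#' Implements the stratified cross-validation selection of the lag that
#' maximizes the drug-placebo irreversibility difference: datasets are
#' partitioned into counter-balanced participant folds; in each loop the
#' training folds pick the lag with the highest absolute difference
#' between the drug-level means of r(tau), and the held-out fold's
#' difference at that lag is recorded; the winning lag is the one whose
#' test fold showed the largest absolute difference. Significance of the
#' drug contrast at the selected lag is assessed by a paired sign-flip
#' permutation test of the per-participant (control - drug) differences,
#' averaged over conditions.
#'
#' @param curves named list of `irrev_curve` objects keyed
#'   `"participant|drug|condition"` (as produced over a cohort).
#' @param design the [study_design()].
#' @param n_folds number of folds (default 8).
#' @param n_perm permutations for the significance test (default 1000).
#' @param seed integer seed (folds and permutations).
#' @return `tau_selection` list: `tau_optimal`, `fold_tau` (training
#'   winner per fold), `fold_stat` (test-fold |difference| per fold),
#'   `p_value`, `observed_diff` (mean control - drug at `tau_optimal`),
#'   `folds`.
#' @export
select_tau_crossval <- function(curves, design, n_folds = 8L,
                                n_perm = 1000L, seed = 1L) {
  grid_df <- make_folds(design, n_folds, seed)
  key <- paste(grid_df$participant, grid_df$drug, grid_df$condition, sep = "|")
  if (!all(key %in% names(curves)))
    stop("missing curves for datasets: ",
         paste(utils::head(setdiff(key, names(curves)), 5), collapse = ", "))
  taug <- common_grid(curves)
  M <- vapply(curves[key], function(cu) cu$r, numeric(length(taug)))
  is_control <- grid_df$drug == design$drug_levels[1]
  fold_tau <- integer(n_folds); fold_stat <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- grid_df$fold != f
    d_train <- rowMeans(M[, tr & !is_control, drop = FALSE]) -
               rowMeans(M[, tr & is_control, drop = FALSE])
    best <- which.max(abs(d_train))                     # ties: smallest lag
    fold_tau[f] <- taug[best]
    te <- !tr
    fold_stat[f] <- abs(mean(M[best, te & !is_control]) -
                        mean(M[best, te & is_control]))
  }
  winner <- which.max(fold_stat)
  tau_opt <- fold_tau[winner]
  ti <- match(tau_opt, taug)
  # per-participant paired difference at tau_optimal, conditions averaged
  pp <- vapply(design$participant_ids, function(p) {
    sel_c <- grid_df$participant == p & is_control
    sel_d <- grid_df$participant == p & !is_control
    mean(M[ti, sel_c]) - mean(M[ti, sel_d])
  }, numeric(1))
  perm <- paired_permutation_diff(pp, n_perm = n_perm, seed = seed + 1L)
  structure(list(approach = "crossval", tau_optimal = tau_opt,
                 fold_tau = fold_tau, fold_stat = fold_stat,
                 p_value = perm$p, observed_diff = mean(pp),
                 folds = grid_df, tau_grid = taug),
            class = "tau_selection")
}

#' @export
print.tau_selection <- function(x, ...) {
  cat("<tau_selection> approach = ", x$approach, ", tau_optimal = ",
      x$tau_optimal, " samples", sep = "")
  if (!is.null(x$p_value)) cat(", p = ", signif(x$p_value, 3), sep = "")
  cat("\n"); invisible(x)
}

# Sign-flip permutation on a vector of paired differences.
paired_permutation_diff <- function(d, n_perm = 1000L, seed = 1L) {
  n <- length(d)
  obs <- abs(mean(d))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n)
  null <- abs(colMeans(signs * d))
  list(p = (1 + sum(null >= obs)) / (n_perm + 1), observed = mean(d), null = null)
}

#' Paired permutation test by sign flipping
#'
#' Tests whether paired per-subject values `a` and `b` differ: the
#' statistic is `|mean(a - b)|` and the null distribution is generated by
#' random sign flips of the paired differences. The p-value uses the
#' add-one convention `(1 + exceedances) / (n_perm + 1)` and is therefore
#' never zero.
#'
#' @param a,b numeric vectors of equal length (>= 3), one value per subject.
#' @param n_perm number of permutations (warning below 100).
#' @param seed integer seed.
#' @return list with `p`, `observed` (mean difference), `null` (vector of
#'   permuted statistics).
#' @export
paired_permutation <- function(a, b, n_perm = 1000L, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value")
  paired_permutation_diff(a - b, n_perm = n_perm, seed = seed)
}

#' Cluster-based permutation test over the lag axis
#'
#' Compares paired r(tau) curves between the two drug levels while
#' controlling the family-wise error over lags: a paired t statistic is
#' computed at every lag, contiguous supra-threshold runs of equal sign
#' form clusters with mass = sum of t values, and each observed cluster's
#' mass is compared against the permutation distribution of the *maximum*
#' absolute cluster mass under within-subject sign flips.
#'
#' @param curves_a,curves_b lists of `irrev_curve` objects paired by
#'   subject (same order), on a common lag grid.
#' @param alpha_cluster pointwise alpha forming the cluster threshold
#'   (default 0.05, two-sided paired t).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `cluster_result`: data.frame `clusters`
#'   (`start`, `end` lag indices into the grid, `tau_start`, `tau_end`,
#'   `mass`, `p`), plus `t_values`, `tau_grid`, `threshold`.
#' @export
cluster_perm_over_tau <- function(curves_a, curves_b, alpha_cluster = 0.05,
                                  n_perm = 1000L, seed = 1L) {
  stopifnot(length(curves_a) == length(curves_b), length(curves_a) >= 3)
  grid <- common_grid(c(curves_a, curves_b))
  if (length(grid) < 2L) stop("lag grid too short to cluster")
  A <- vapply(curves_a, function(cu) cu$r, numeric(length(grid)))
  B <- vapply(curves_b, function(cu) cu$r, numeric(length(grid)))
  D <- A - B                                    # lags x subjects
  n <- ncol(D)
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  tstat <- function(D) {
    m <- rowMeans(D); s <- apply(D, 1, stats::sd)
    ifelse(s == 0, 0, m / (s / sqrt(n)))
  }
  clusters_of <- function(tv) {
    lab <- integer(length(tv)); lab[tv > tcrit] <- 1L; lab[tv < -tcrit] <- -1L
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    data.frame(start = starts[keep], end = ends[keep],
               mass = mapply(function(s, e) sum(tv[s:e]), starts[keep], ends[keep]))
  }
  t_obs <- tstat(D)
  cl <- clusters_of(t_obs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  max_null <- replicate(n_perm, {
    flip <- sample(c(-1, 1), n, replace = TRUE)
    cp <- clusters_of(tstat(D * rep(flip, each = nrow(D))))
    if (nrow(cp) == 0) 0 else max(abs(cp$mass))
  })
  cl$p <- vapply(cl$mass,
                 function(m) (1 + sum(max_null >= abs(m))) / (n_perm + 1),
                 numeric(1))
  cl$tau_start <- grid[cl$start]; cl$tau_end <- grid[cl$end]
  structure(list(clusters = cl, t_values = t_obs, tau_grid = grid,
                 threshold = tcrit, max_null = max_null),
            class = "cluster_result")
}

#' Repeated-measures ANOVA on a result table
#'
#' Within-subject ANOVA with factors drug and condition (optionally
#' region): fits `stats::aov` with `Error(participant/...)` strata on a
#' validated, complete, balanced long table, and returns a tidy F/p table.
#' Tukey-adjusted post-hoc pairwise contrasts on a requested factor are
#' available through emmeans.
#'
#' @param table long-format data.frame with columns `participant`, `drug`,
#'   `condition`, `value` (plus `region` if requested), one metric only.
#' @param factors character vector, `c("drug", "condition")` or
#'   `c("drug", "condition", "region")`.
#' @param posthoc optional factor name for Tukey post-hoc contrasts.
#' @return list of class `rm_anova`: `anova` (data.frame with effect, df,
#'   F, p), `posthoc` (data.frame or NULL), `fit`.
#' @export
rm_anova <- function(table, factors = c("drug", "condition"), posthoc = NULL) {
  stopifnot(all(c("participant", "value", factors) %in% names(table)))
  if (!all(is.finite(table$value))) stop("non-finite values in table")
  # balance check: every participant must have exactly one row per cell
  cells <- interaction(table[factors], drop = FALSE)
  tab <- table(table$participant, cells)
  if (any(tab != 1L))
    stop("unbalanced design: each participant needs exactly one value per ",
         paste(factors, collapse = " x "), " cell")
  dat <- table
  dat$participant <- factor(dat$participant)
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  rhs <- paste(factors, collapse = " * ")
  err <- paste0("Error(participant/(", rhs, "))")
  fml <- stats::as.formula(paste("value ~", rhs, "+", err))
  # inline the formula and data into the call so downstream re-fits
  # (emmeans) can recover them outside this function's environment
  fit <- eval(bquote(stats::aov(.(fml), data = .(dat))))
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    s <- stratum[[1]]
    eff <- trimws(rownames(s))
    ok <- eff != "Residuals" & !is.na(s[["F value"]])
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[ok], df = s$Df[ok], F = s[["F value"]][ok],
        p = s[["Pr(>F)"]][ok], row.names = NULL)
  }
  atab <- do.call(rbind, rows)
  ph <- NULL
  if (!is.null(posthoc)) {
    stopifnot(posthoc %in% factors)
    em <- emmeans::emmeans(fit, stats::as.formula(paste("~", posthoc)),
                           data = dat)
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
  }
  structure(list(anova = atab, posthoc = ph, fit = fit), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) { print(x$anova); invisible(x) }

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone in the input ranks.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# D'Agostino-Pearson K^2 omnibus test (skewness + kurtosis), standard
# closed form; returns the p-value.
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 20) stop("K^2 test needs n >= 20")
  m <- mean(x); s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1)); W <- sqrt(W2)
  delta <- 1 / sqrt(log(W))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * asinh(Y / alpha)
  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
           sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  Ak <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zg2 <- ((1 - 2 / (9 * Ak)) -
          ((1 - 2 / Ak) / (1 + xk * sqrt(2 / (Ak - 4))))^(1 / 3)) /
         sqrt(2 / (9 * Ak))
  K2 <- Zg1^2 + Zg2^2
  stats::pchisq(K2, df = 2, lower.tail = FALSE)
}

# Jarque-Bera test, asymptotic chi^2(2) form; returns the p-value.
jarque_bera <- function(x) {
  n <- length(x)
  m <- mean(x); s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  JB <- n / 6 * (g1^2 + g2^2 / 4)
  stats::pchisq(JB, df = 2, lower.tail = FALSE)
}

#' Normality test battery
#'
#' Runs a fixed panel of normality tests — Shapiro-Wilk, D'Agostino K²,
#' Anderson-Darling, Jarque-Bera — at a common alpha and reports each
#' verdict plus the majority summary. Used to check whether a metric's
#' distribution across participants is close enough to normal for
#' parametric contrasts.
#'
#' @param values numeric vector, `n >= 8` (K² additionally needs
#'   `n >= 20` and is reported as NA below that).
#' @param alpha significance level per test (default 0.05).
#' @return data.frame with columns `test`, `p`, `pass`, plus attribute
#'   `majority_pass`.
#' @export
normality_battery <- function(values, alpha = 0.05) {
  if (length(values) < 8) stop("too few samples (need n >= 8)")
  if (stats::sd(values) == 0) stop("degenerate input: zero variance")
  ps <- c(
    shapiro_wilk = stats::shapiro.test(values)$p.value,
    dagostino_k2 = if (length(values) >= 20) dagostino_k2(values) else NA_real_,
    anderson_darling = nortest::ad.test(values)$p.value,
    jarque_bera = jarque_bera(values))
  out <- data.frame(test = names(ps), p = unname(ps), pass = unname(ps) >= alpha,
                    row.names = NULL)
  attr(out, "majority_pass") <- mean(out$pass, na.rm = TRUE) > 0.5
  out
}
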