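#' Build a feature table for drug-vs-control classification
#'
#' Pivots a long result table into one observation per (participant, drug)
#' session with one feature per condition (scalar mode) or one per
#' condition x region (regional mode). Labels are balanced by
#' construction: each participant contributes one control and one drug
#' session.
#'
#' @param results long data.frame with columns `participant`, `drug`,
#'   `condition`, `metric`, `value` and, for regional mode, `region`.
#' @param feature_set metric name to pivot (must match `metric` values).
#' @param mode `"scalar"` (default) or `"regional"`.
#' @param design a [study_design()] giving the full grid; missing cells
#'   are an error.
#' @return object of class `feature_table`: `x` (observations x features
#'   matrix), `label` (factor, control level first), `participant`,
#'   `feature_set`.
#' @export
build_features <- function(results, feature_set, mode = c("scalar", "regional"),
                           design) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"))
  sub <- results[results$metric == feature_set, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for metric '", feature_set, "'")
  grid <- design_grid(design)
  obs <- unique(grid[, c("participant", "drug")])
  if (mode == "scalar") {
    feats <- design$condition_levels
    x <- matrix(NA_real_, nrow(obs), length(feats),
                dimnames = list(NULL, feats))
    for (i in seq_len(nrow(obs)))
      for (j in seq_along(feats)) {
        v <- sub$value[sub$participant == obs$participant[i] &
                       sub$drug == obs$drug[i] & sub$condition == feats[j]]
        if (length(v) != 1) stop("missing or duplicated cell: ",
                                 obs$participant[i], "/", obs$drug[i], "/", feats[j])
        x[i, j] <- v
      }
  } else {
    if (is.null(sub$region)) stop("regional mode needs a 'region' column")
    regions <- sort(unique(sub$region))
    feats <- as.vector(outer(regions, design$condition_levels,
                             function(r, cd) paste(cd, r, sep = ".")))
    x <- matrix(NA_real_, nrow(obs), length(feats),
                dimnames = list(NULL, feats))
    for (i in seq_len(nrow(obs))) {
      si <- sub[sub$participant == obs$participant[i] & sub$drug == obs$drug[i], ]
      key <- paste(si$condition, si$region, sep = ".")
      v <- si$value[match(feats, key)]
      if (anyNA(v)) stop("missing regional cells for ", obs$participant[i])
      x[i, ] <- v
    }
  }
  if (any(apply(x, 2, stats::sd) == 0))
    warning("zero-variance feature(s): ",
            paste(colnames(x)[apply(x, 2, stats::sd) == 0], collapse = ", "))
  control <- design$drug_levels[1]
  structure(list(x = x,
                 label = factor(obs$drug, levels = design$drug_levels),
                 participant = obs$participant,
                 feature_set = feature_set, mode = mode,
                 control_level = control),
            class = "feature_table")
}

# Participant-stratified 80/20 split: both sessions of a participant land
# on the same side, so no within-participant information leaks from train
# to test. Returns a logical test mask over observations.
participant_split <- function(participants, train_frac = 0.8) {
  ids <- unique(participants)
  n_test <- max(1L, round(length(ids) * (1 - train_frac)))
  test_ids <- sample(ids, n_test)
  participants %in% test_ids
}

#' Random-forest evaluation of a feature set
#'
#' Repeatedly splits the observations 80/20 (participant-stratified: a
#' participant's two sessions always stay on the same side), trains a
#' bagged-tree ensemble (100 trees, default settings) on the training
#' portion and records the AUROC of the held-out portion. Runs are seeded
#' so that different feature sets evaluated with the same seed share the
#' same splits, which makes their AUROC vectors pairable.
#'
#' @param features a [build_features()] table.
#' @param n_runs number of train/test splits (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @param shuffle_labels permute labels before every run (chance
#'   calibration).
#' @param leakage_safe FALSE reverts to plain observation-level splits.
#' @return numeric vector of AUROCs (class `classifier_report`), with
#'   attributes `feature_set`, `seed`.
#' @export
rf_evaluate <- function(features, n_runs = 100L, train_frac = 0.8, seed = 1L,
                        shuffle_labels = FALSE, leakage_safe = TRUE) {
  stopifnot(inherits(features, "feature_table"))
  x <- features$x; y <- features$label
  if (nrow(x) < 8) stop("too few observations to split")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  auc <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    yy <- if (shuffle_labels) sample(y) else y
    repeat {
      test <- if (leakage_safe) participant_split(features$participant, train_frac)
              else seq_len(nrow(x)) %in% sample(nrow(x), max(2L, round(nrow(x) * (1 - train_frac))))
      if (length(unique(yy[!test])) == 2L && length(unique(yy[test])) == 2L) break
    }
    fit <- randomForest::randomForest(x[!test, , drop = FALSE], yy[!test],
                                      ntree = 100)
    prob <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, 2]
    auc[run] <- as.numeric(pROC::auc(response = yy[test], predictor = prob,
                                     levels = levels(y), direction = "<",
                                     quiet = TRUE))
  }
  structure(auc, class = c("classifier_report", "numeric"),
            feature_set = features$feature_set, seed = seed)
}

#' Nested cross-validation over the lag
#'
#' Outer loop: participant-stratified 80/20 holdout as in
#' [rf_evaluate()]. Inner loop: 5-fold cross-validation on the training
#' portion picks the lag whose feature table maximizes the inner AUROC;
#' the outer model is trained at that lag and scored on the holdout.
#' Feature tables are supplied precomputed per lag so the metric is
#' evaluated once per (dataset, lag), not once per run.
#'
#' @param features_by_tau named list of [build_features()] tables, one per
#'   lag; names are the lags (samples).
#' @param n_runs outer runs (default 100).
#' @param train_frac outer training fraction.
#' @param inner_folds inner folds (default 5).
#' @param seed integer seed.
#' @return list of class `nested_tau_report`: `auc` (outer AUROC per
#'   run), `tau_chosen` (lag per run).
#' @export
rf_nested_tau <- function(features_by_tau, n_runs = 100L, train_frac = 0.8,
                          inner_folds = 5L, seed = 1L) {
  stopifnot(length(features_by_tau) >= 1L)
  taus <- as.integer(names(features_by_tau))
  if (anyNA(taus)) stop("features_by_tau must be named by integer lags")
  f1 <- features_by_tau[[1]]
  y <- f1$label; parts <- f1$participant
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  auc <- numeric(n_runs); tau_chosen <- integer(n_runs)
  for (run in seq_len(n_runs)) {
    repeat {
      test <- participant_split(parts, train_frac)
      if (length(unique(y[!test])) == 2L && length(unique(y[test])) == 2L) break
    }
    tr_idx <- which(!test)
    tr_parts <- unique(parts[tr_idx])
    fold_of <- setNames(rep(seq_len(inner_folds), length.out = length(tr_parts)),
                        sample(tr_parts))
    inner_auc <- vapply(seq_along(taus), function(ti) {
      xt <- features_by_tau[[ti]]$x
      scores <- labs <- NULL
      for (f in seq_len(inner_folds)) {
        va <- tr_idx[fold_of[parts[tr_idx]] == f]
        tr <- setdiff(tr_idx, va)
        if (length(va) == 0 || length(unique(y[tr])) < 2) next
        fit <- randomForest::randomForest(xt[tr, , drop = FALSE], y[tr], ntree = 100)
        scores <- c(scores, stats::predict(fit, xt[va, , drop = FALSE],
                                           type = "prob")[, 2])
        labs <- c(labs, as.character(y[va]))
      }
      if (length(unique(labs)) < 2) return(0.5)
      as.numeric(pROC::auc(response = factor(labs, levels = levels(y)),
                           predictor = scores, levels = levels(y),
                           direction = "<", quiet = TRUE))
    }, numeric(1))
    best <- which.max(inner_auc)
    tau_chosen[run] <- taus[best]
    xb <- features_by_tau[[best]]$x
    fit <- randomForest::randomForest(xb[!test, , drop = FALSE], y[!test],
                                      ntree = 100)
    prob <- stats::predict(fit, xb[test, , drop = FALSE], type = "prob")[, 2]
    auc[run] <- as.numeric(pROC::auc(response = y[test], predictor = prob,
                                     levels = levels(y), direction = "<",
                                     quiet = TRUE))
  }
  structure(list(auc = auc, tau_chosen = tau_chosen),
            class = "nested_tau_report")
}

#' Pairwise comparison of classifier reports
#'
#' Wilcoxon signed-rank tests on paired AUROC vectors (runs share split
#' seeds across feature sets), with Benjamini-Hochberg adjustment across
#' all pairs.
#'
#' @param reports named list of AUROC vectors from [rf_evaluate()] with a
#'   common seed.
#' @return data.frame with columns `a`, `b`, `median_diff`, `p`, `q`.
#' @export
compare_feature_sets <- function(reports) {
  stopifnot(length(reports) >= 2L, !is.null(names(reports)))
  n <- lengths(reports)
  if (length(unique(n)) != 1L) stop("reports must have equal run counts (paired)")
  seeds <- vapply(reports, function(r) attr(r, "seed") %||% NA_integer_, numeric(1))
  if (length(unique(seeds[!is.na(seeds)])) > 1L)
    stop("reports were not generated with a shared seed: runs are unpaired")
  combs <- utils::combn(names(reports), 2)
  out <- do.call(rbind, apply(combs, 2, function(pr) {
    a <- as.numeric(reports[[pr[1]]]); b <- as.numeric(reports[[pr[2]]])
    p <- if (all(a == b)) 1
         else suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    data.frame(a = pr[1], b = pr[2], median_diff = stats::median(a - b), p = p)
  }))
  out$q <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Mean undirected functional connectivity of a dataset
#'
#' Mean zero-lag Pearson correlation over all region pairs, averaged
#' across epochs — the undirected baseline the directed metrics are
#' compared against.
#'
#' @param env an [envelope_epochs()] dataset.
#' @return scalar.
#' @export
mean_undirected_fc <- function(env) {
  stopifnot(inherits(env, "envelope_epochs"))
  ut <- upper.tri(matrix(0, n_regions(env), n_regions(env)))
  mean(vapply(seq_len(n_epochs(env)), function(e) {
    C <- stats::cor(t(epoch_matrix(env, e)))
    mean(C[ut])
  }, numeric(1)))
}

#' Mean forward lagged cross-correlation of a dataset
#'
#' Mean of the forward lagged correlation matrix over all ordered region
#' pairs, averaged across epochs.
#'
#' @param env an [envelope_epochs()] dataset.
#' @param tau lag in samples.
#' @return scalar.
#' @export
mean_forward_xcorr <- function(env, tau) {
  stopifnot(inherits(env, "envelope_epochs"))
  N <- n_regions(env)
  off <- row(matrix(0, N, N)) != col(matrix(0, N, N))
  mean(vapply(seq_len(n_epochs(env)), function(e) {
    m <- corr_matrices(epoch_matrix(env, e), tau)
    mean(m$Cf[off])
  }, numeric(1)))
}
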