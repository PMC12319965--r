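make_results <- function(design, effect = 0.5, seed = 1, regional = FALSE,
                         n_regions = 3) {
  grid <- design_grid(design)
  set.seed(seed)
  if (!regional) {
    grid$metric <- "irreversibility"
    grid$value <- ifelse(grid$drug == "drug", -effect, 0) + rnorm(nrow(grid))
    grid
  } else {
    out <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
      g <- grid
      g$metric <- "irreversibility"
      g$region <- paste0("R", r)
      g$value <- ifelse(g$drug == "drug", -effect, 0) + rnorm(nrow(g))
      g
    }))
    out
  }
}

test_that("build_features pivots scalar and regional modes with exact shapes", {
  design <- study_design(sprintf("P%02d", 1:16))
  ft <- build_features(make_results(design), "irreversibility",
                       design = design)
  expect_equal(dim(ft$x), c(32, 4))           # 16 x 2 sessions, 4 conditions
  expect_equal(colnames(ft$x), design$condition_levels)
  expect_equal(levels(ft$label), c("control", "drug"))
  expect_equal(as.vector(table(ft$label)), c(16, 16))
  ftr <- build_features(make_results(design, regional = TRUE, n_regions = 3),
                        "irreversibility", mode = "regional", design = design)
  expect_equal(dim(ftr$x), c(32, 12))          # 4 conditions x 3 regions
  expect_error(build_features(make_results(design), "nope", design = design),
               "no rows")
  incomplete <- make_results(design)[-1, ]
  expect_error(build_features(incomplete, "irreversibility", design = design),
               "missing")
})

test_that("build_features warns on zero-variance features", {
  design <- study_design(sprintf("P%02d", 1:8))
  res <- make_results(design)
  res$value <- 1
  expect_warning(build_features(res, "irreversibility", design = design),
                 "zero-variance")
})

test_that("participant splits keep session pairs together", {
  design <- study_design(sprintf("P%02d", 1:10))
  ft <- build_features(make_results(design), "irreversibility",
                       design = design)
  set.seed(100)
  for (rep in 1:10) {
    test <- insideout:::participant_split(ft$participant, 0.8)
    split_of <- tapply(test, ft$participant, function(x) length(unique(x)))
    expect_true(all(split_of == 1))           # no participant straddles
    expect_equal(sum(test), 4)                # 2 of 10 participants -> 4 obs
  }
})

test_that("rf_evaluate separates a strong effect and is seed-deterministic", {
  design <- study_design(sprintf("P%02d", 1:12))
  ft <- build_features(make_results(design, effect = 3), "irreversibility",
                       design = design)
  auc <- rf_evaluate(ft, n_runs = 20, seed = 5)
  expect_length(auc, 20)
  expect_gt(median(auc), 0.9)
  auc2 <- rf_evaluate(ft, n_runs = 20, seed = 5)
  expect_identical(as.numeric(auc), as.numeric(auc2))
  # shuffled labels: chance-level
  auc_sh <- rf_evaluate(ft, n_runs = 40, seed = 5, shuffle_labels = TRUE)
  expect_gt(median(auc_sh), 0.25)
  expect_lt(median(auc_sh), 0.75)
})

test_that("rf_evaluate on uninformative features stays near chance", {
  design <- study_design(sprintf("P%02d", 1:12))
  ft <- build_features(make_results(design, effect = 0), "irreversibility",
                       design = design)
  auc <- rf_evaluate(ft, n_runs = 40, seed = 6)
  expect_gt(median(auc), 0.2)
  expect_lt(median(auc), 0.8)
})

test_that("compare_feature_sets pairs runs and applies FDR", {
  design <- study_design(sprintf("P%02d", 1:12))
  strong <- build_features(make_results(design, effect = 3, seed = 2),
                           "irreversibility", design = design)
  weak <- build_features(make_results(design, effect = 0, seed = 3),
                         "irreversibility", design = design)
  rs <- rf_evaluate(strong, n_runs = 30, seed = 7)
  rw <- rf_evaluate(weak, n_runs = 30, seed = 7)
  cmp <- compare_feature_sets(list(strong = rs, weak = rw))
  expect_equal(nrow(cmp), 1)
  expect_gt(cmp$median_diff, 0)
  expect_lt(cmp$p, 0.01)
  expect_true(all(cmp$q >= cmp$p - 1e-12))
  # identical reports: p = 1 by convention
  cmp0 <- compare_feature_sets(list(a = rs, b = rs))
  expect_equal(cmp0$p, 1)
  # unpaired (different seeds) is an error
  rw2 <- rf_evaluate(weak, n_runs = 30, seed = 8)
  expect_error(compare_feature_sets(list(a = rs, b = rw2)), "shared seed")
})

test_that("rf_nested_tau picks the informative lag most of the time", {
  design <- study_design(sprintf("P%02d", 1:12),
                         condition_levels = c("Open", "Closed"))
  feats <- list(
    "2" = build_features(make_results(design, effect = 0, seed = 4),
                         "irreversibility", design = design),
    "5" = build_features(make_results(design, effect = 3, seed = 5),
                         "irreversibility", design = design),
    "9" = build_features(make_results(design, effect = 0, seed = 6),
                         "irreversibility", design = design))
  rep <- rf_nested_tau(feats, n_runs = 10, seed = 9)
  expect_length(rep$auc, 10)
  expect_gte(mean(rep$tau_chosen == 5), 0.7)
  expect_gt(median(rep$auc), 0.8)
})

test_that("mean_undirected_fc and mean_forward_xcorr scalar summaries", {
  set.seed(101)
  # two perfectly correlated regions: uFC = 1
  x <- rnorm(100)
  vals <- array(0, dim = c(1, 2, 100))
  vals[1, 1, ] <- x; vals[1, 2, ] <- x
  env <- envelope_epochs(vals, fs = 50)
  expect_equal(mean_undirected_fc(env), 1, tolerance = 1e-12)
  expect_true(is.finite(mean_forward_xcorr(env, 3)))
  vals2 <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
  env2 <- envelope_epochs(vals2, fs = 50)
  expect_lt(abs(mean_undirected_fc(env2)), 0.5)
})
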