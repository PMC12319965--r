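make_curve <- function(r, tau_grid, fs = 200) {
  structure(list(tau_samples = as.integer(tau_grid), tau_s = tau_grid / fs,
                 r = r, total = NA_real_, percentile = 95, fs = fs),
            class = "irrev_curve")
}

test_that("select_tau_orthogonal picks the grand-mean argmax", {
  grid <- 1:10
  curves <- list(make_curve(c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0), grid),
                 make_curve(c(0, 0, 3, 0, 0, 0, 0, 0, 0, 0), grid),
                 make_curve(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0), grid))
  sel <- select_tau_orthogonal(curves)
  expect_equal(sel$tau_optimal, 3)
  curves[[3]] <- make_curve(rep(0, 9), 1:9)
  expect_error(select_tau_orthogonal(curves), "different lag grids")
})

test_that("make_folds gives counter-balanced participant-blocked folds", {
  design <- study_design(sprintf("P%02d", 1:16))
  folds <- make_folds(design, n_folds = 8, seed = 3)
  expect_equal(sort(unique(folds$fold)), 1:8)
  for (f in 1:8) {
    sub <- folds[folds$fold == f, ]
    expect_equal(nrow(sub), 16)                       # 2 participants x 2 x 4
    expect_equal(length(unique(sub$participant)), 2)
    expect_equal(as.vector(table(sub$drug)), c(8, 8)) # counter-balanced
  }
  # whole participants: no participant spans folds
  expect_true(all(tapply(folds$fold, folds$participant,
                         function(x) length(unique(x))) == 1))
  expect_identical(folds, make_folds(design, 8, seed = 3))  # deterministic
  expect_error(make_folds(study_design(sprintf("P%d", 1:15)), 8),
               "not divisible")
})

test_that("paired_permutation: trivial and enumeration oracles", {
  a <- c(1, 2, 3, 4, 5)
  expect_warning(res0 <- paired_permutation(a, a, n_perm = 99), "coarse")
  expect_equal(res0$p, 1)
  # exhaustive 2^5 sign flips vs Monte-Carlo
  set.seed(80)
  d <- rnorm(5) + 1
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  exact <- mean(abs(signs %*% d) / 5 >= obs)
  mc <- paired_permutation(d, rep(0, 5), n_perm = 4000, seed = 1)$p
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc - exact), 4 * se + 1 / 4000)
  # large constant shift, n = 16: p at the permutation floor
  res <- paired_permutation(rnorm(16) + 100, rnorm(16), n_perm = 10000, seed = 2)
  expect_lte(res$p, 0.001)
  # add-one convention: p can never be zero
  expect_gt(res$p, 0)
})

test_that("select_tau_crossval recovers a strong drug contrast at the right lag", {
  design <- study_design(sprintf("P%02d", 1:16),
                         condition_levels = c("Open", "Closed"))
  grid_df <- design_grid(design)
  taug <- 1:20
  set.seed(81)
  curves <- list()
  for (k in seq_len(nrow(grid_df))) {
    base <- abs(rnorm(20, 0, 0.02))
    if (grid_df$drug[k] == "control") base[7] <- base[7] + 0.5   # contrast at lag 7
    key <- paste(grid_df$participant[k], grid_df$drug[k], grid_df$condition[k],
                 sep = "|")
    curves[[key]] <- make_curve(base, taug)
  }
  sel <- select_tau_crossval(curves, design, n_folds = 8, n_perm = 500, seed = 9)
  expect_equal(sel$tau_optimal, 7)
  expect_lt(sel$p_value, 0.05)
  expect_gt(sel$observed_diff, 0)     # control > drug
  sel2 <- select_tau_crossval(curves, design, n_folds = 8, n_perm = 500, seed = 9)
  expect_identical(sel$tau_optimal, sel2$tau_optimal)
  expect_identical(sel$p_value, sel2$p_value)
})

test_that("cluster_perm_over_tau finds a known cluster and calibrates under null", {
  set.seed(82)
  n_sub <- 12; grid <- 1:30
  mk <- function(shift) lapply(seq_len(n_sub), function(i)
    make_curve(abs(rnorm(30, 0, 0.05)) + shift * (grid >= 10 & grid <= 15) *
                 (0.3 + rnorm(1, 0, 0.02)), grid))
  res <- cluster_perm_over_tau(mk(1), mk(0), n_perm = 500, seed = 4)
  sig <- res$clusters[res$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  big <- sig[which.max(abs(sig$mass)), ]
  expect_lte(big$tau_start, 12)
  expect_gte(big$tau_end, 13)
  # pure-null curves: no tiny p-values expected
  res0 <- cluster_perm_over_tau(mk(0), mk(0), n_perm = 500, seed = 5)
  if (nrow(res0$clusters)) expect_gt(min(res0$clusters$p), 0.01)
})

test_that("rm_anova detects a drug main effect and enforces balance", {
  design <- study_design(sprintf("P%02d", 1:10),
                         condition_levels = c("Open", "Closed"))
  grid <- design_grid(design)
  set.seed(83)
  subj_int <- setNames(rnorm(10, 0, 0.2), design$participant_ids)
  grid$metric <- "irreversibility"
  grid$value <- subj_int[grid$participant] +
    ifelse(grid$drug == "drug", -0.3, 0) + rnorm(nrow(grid), 0, 0.05)
  fit <- rm_anova(grid, posthoc = "drug")
  a <- fit$anova
  expect_lt(a$p[a$effect == "drug"], 0.01)
  expect_gt(a$p[a$effect == "condition"], 0.05)
  expect_s3_class(fit$posthoc, "data.frame")
  expect_equal(nrow(fit$posthoc), 1)      # one pairwise drug contrast
  expect_error(rm_anova(grid[-1, ]), "unbalanced")
  bad <- grid; bad$value[1] <- NA
  expect_error(rm_anova(bad), "non-finite")
})

test_that("fdr_adjust matches p.adjust and rejects bad input", {
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("normality battery calibrates on normal vs exponential samples", {
  set.seed(84)
  pass_rate <- function(gen) mean(replicate(60, {
    attr(normality_battery(gen(500)), "majority_pass")
  }))
  expect_gte(pass_rate(function(n) rnorm(n)), 0.9)
  expect_lte(pass_rate(function(n) rexp(n)), 0.1)
  expect_error(normality_battery(rep(1, 50)), "zero variance")
  expect_error(normality_battery(rnorm(5)), "too few")
})

test_that("hand-rolled K2 and JB p-values are uniform-ish under the null", {
  set.seed(85)
  pk <- replicate(200, insideout:::dagostino_k2(rnorm(100)))
  pj <- replicate(200, insideout:::jarque_bera(rnorm(100)))
  # type-I error near alpha
  expect_lt(abs(mean(pk < 0.05) - 0.05), 0.05)
  expect_lt(abs(mean(pj < 0.05) - 0.05), 0.05)
  # strong skew is detected
  expect_lt(insideout:::dagostino_k2(rexp(200)), 1e-4)
  expect_lt(insideout:::jarque_bera(rexp(200)), 1e-4)
})
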