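test_that("the cumulative metric sums the leading components", {
  expect_equal(cumulative_metric(c(0.5, 0.3, 0.2, 0.1), K_hat = 3), 1.0)
  expect_equal(cumulative_metric(c(0.5, 0.3, 0.2, 0.1), K_hat = 1), 0.5)
  expect_equal(cumulative_metric(rep(0, 10)), 0)
  expect_error(cumulative_metric(c(0.5, 0.3), K_hat = 3), "K_hat")
})

test_that("AUC equals brute-force pair enumeration, with and without ties", {
  expect_equal(auc_score(c(2, 3, 0, 1), c("CAC", "CAC", "DYS", "DYS")), 1.0)
  expect_equal(auc_score(rep(1, 6), rep(c("CAC", "DYS"), 3)), 0.5)
  # interleaved case, from the enumeration oracle
  sc <- c(0, 2, 1, 3); lab <- c("CAC", "CAC", "DYS", "DYS")
  expect_equal(auc_score(sc, lab), auc_bruteforce(sc, lab))
  expect_equal(auc_bruteforce(sc, lab), 0.25)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    sc <- sample(0:5, n, replace = TRUE)  # force ties
    lab <- c("CAC", "DYS", sample(c("CAC", "DYS"), n - 2, replace = TRUE))
    expect_equal(auc_score(sc, lab), auc_bruteforce(sc, lab))
  }
  expect_error(auc_score(1:3, c("CAC", "CAC", "CAC")), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  sc <- rnorm(30)
  lab <- sample(c("CAC", "DYS"), 30, replace = TRUE, prob = c(.5, .5))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("DYS", "CAC")), predictor = sc,
    direction = "<", quiet = TRUE)))
  expect_equal(auc_score(sc, lab), ref, tolerance = 1e-12)
})

test_that("the compiled lasso path matches glmnet coefficients", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  worst <- 0
  for (rep in 1:10) {
    n <- sample(12:25, 1)
    X <- scale(matrix(rnorm(n * 10), n))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    lam <- exp(seq(log(0.4), log(0.02), length.out = 10))
    mine <- lasso_logistic_path(X, y, lam)
    g <- suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
      alpha = 1, lambda = lam, standardize = FALSE, thresh = 1e-12))
    gco <- rbind(g$a0, as.matrix(g$beta))
    worst <- max(worst, max(abs(mine[, seq_len(ncol(gco))] - gco)))
  }
  expect_lt(worst, 1e-3)
})

test_that("linearly separable features yield a perfect cross-validated AUC", {
  set.seed(34)
  S <- 20
  lab <- rep(c("CAC", "DYS"), each = S / 2)
  f1 <- c(rnorm(S / 2, 3, 0.3), rnorm(S / 2, -3, 0.3))
  feats <- cbind(f1, matrix(rnorm(S * 9, 0, 0.5), S, 9))
  res <- lasso_weighted_scores(feats, lab)
  expect_equal(res$auc, 1.0)
  expect_length(res$cv_scores, S)
})

test_that("label-independent features give chance-level AUC", {
  set.seed(35)
  S <- 60
  lab <- rep(c("CAC", "DYS"), each = S / 2)
  feats <- matrix(rnorm(S * 10), S, 10)
  res <- lasso_weighted_scores(feats, lab)
  expect_gt(res$auc, 0.35)
  expect_lt(res$auc, 0.65)
  expect_error(lasso_weighted_scores(feats, rep("CAC", S)), "both classes")
})

test_that("duplicated features do not both enter the sparse model", {
  set.seed(36)
  S <- 24
  lab <- rep(c("CAC", "DYS"), each = S / 2)
  signal <- c(rnorm(S / 2, 2), rnorm(S / 2, -2))
  feats <- cbind(signal, signal, matrix(rnorm(S * 8, 0, 1), S, 8))
  res <- lasso_weighted_scores(feats, lab)
  b1 <- res$weights[2, ]  # coefficient rows follow the intercept
  b2 <- res$weights[3, ]
  expect_true(all(pmin(abs(b1), abs(b2)) <= pmax(abs(b1), abs(b2)) * 0.5 + 1e-8))
})

test_that("the permutation p-value follows the add-one formula", {
  fix <- small_gap_cohort()
  pairs <- pair_covariances(fix$X)
  lab <- fix$cohort$manifest$group
  # an unbeatable observed AUC: every permutation falls below it
  pt <- permutation_test_auc(pairs, lab, observed_auc = 2, n_perm = 99,
                             seed = 4, K = 5)
  expect_equal(pt$p, 0.01)
  # an unbeatably bad one: every permutation ties or beats it
  pt2 <- permutation_test_auc(pairs, lab, observed_auc = -1, n_perm = 19,
                              seed = 4, K = 5)
  expect_equal(pt2$p, 1)
  expect_error(permutation_test_auc(pairs, lab, 0.5, n_perm = 0), "n_perm")
})

test_that("two-way ANOVA recovers a planted grade effect", {
  set.seed(37)
  d <- expand.grid(group = c("CAC", "DYS"), grade = c("3", "6"),
                   rep = 1:15)
  d$c_rrnc <- rnorm(nrow(d)) + ifelse(d$grade == "6", 2, 0)
  tab <- anova_group_grade(d)
  expect_lt(tab$p[tab$effect == "grade"], 0.05)
  expect_gt(tab$p[tab$effect == "group"], 0.05)
  expect_false(attr(tab, "degenerate"))
})

test_that("zero-variance metrics are flagged as degenerate", {
  d <- expand.grid(group = c("CAC", "DYS"), grade = c("3", "6"), rep = 1:5)
  d$c_rrnc <- 1
  expect_warning(tab <- anova_group_grade(d), "variance")
  expect_true(attr(tab, "degenerate"))
  d2 <- d[d$grade == "3" | d$group == "CAC", ]
  expect_error(anova_group_grade(d2), "empty")
})

test_that("two-way ANOVA p-values are calibrated under the null", {
  set.seed(38)
  ps <- replicate(200, {
    d <- expand.grid(group = c("CAC", "DYS"), grade = c("3", "6"),
                     rep = 1:5)
    d$c_rrnc <- rnorm(nrow(d))
    anova_group_grade(d)$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("repeated-measures ANOVA detects a modality shift and validates input", {
  set.seed(39)
  base <- data.frame(participant = rep(sprintf("P%02d", 1:12), each = 4),
                     condition = rep(1:4, 12))
  subj <- rnorm(12)[match(base$participant, sprintf("P%02d", 1:12))]
  d <- base
  d$c_rrnc <- subj + rnorm(nrow(d), sd = 0.3) +
    ifelse(d$condition %in% c(1, 2), 1.5, 0)  # rime conditions shifted
  tab <- rm_anova_modality_confusability(d)
  expect_lt(tab$p[tab$effect == "modality"], 0.01)
  expect_gt(tab$p[tab$effect == "confusability"], 0.05)

  # no planted condition effect: nothing reaches significance
  d2 <- base
  d2$c_rrnc <- subj + rnorm(nrow(base), sd = 0.3)
  tab2 <- rm_anova_modality_confusability(d2)
  expect_true(all(tab2$p > 0.05))

  d3 <- d[d$condition != 4, ]
  expect_error(rm_anova_modality_confusability(d3), "all 4 conditions")
})
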