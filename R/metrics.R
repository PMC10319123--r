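# Aggregation of congruency features into group-discrimination metrics:
# the cumulative metric (sum of the top-K-hat RRNC scores), the
# LASSO-weighted metric (sparse logistic regression under
# leave-one-participant-out cross-validation), ROC AUC with permutation
# significance, and factorial ANOVAs on the metrics.

#' Cumulative congruency metric
#'
#' Sum of the first `K_hat` entries of a congruency feature vector
#' (entries are ordered by descending eigenvalue). `K_hat = 3`
#' corresponds to the knee of the eigenvalue spectrum.
#'
#' @param c_s Numeric congruency vector.
#' @param K_hat Number of leading components summed.
#' @return Scalar metric.
#' @export
cumulative_metric <- function(c_s, K_hat = 3) {
  if (K_hat < 1 || K_hat > length(c_s))
    stop(sprintf("K_hat = %d outside [1, %d]", K_hat, length(c_s)))
  sum(c_s[seq_len(K_hat)])
}

#' ROC area under the curve
#'
#' Probability that a randomly chosen reference-group (CAC) score
#' exceeds a randomly chosen case (DYS) score, ties counted one half
#' (the Mann-Whitney identity), computed via midranks.
#'
#' @param scores Numeric decision values (higher = more CAC-like).
#' @param labels Vector with exactly two classes.
#' @param positive Label of the positive (reference) class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "CAC") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Deterministic stratified round-robin fold assignment: within each
# class, samples are dealt to folds in order. Keeps the whole pipeline
# reproducible without consuming RNG state.
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- ((seq_along(idx) - 1L) %% nfolds) + 1L
  }
  fold
}

binomial_deviance <- function(y, eta) {
  p <- 1 / (1 + exp(-eta))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' LASSO logistic regression path
#'
#' L1-penalized logistic regression over a decreasing penalty path
#' (IRLS plus cyclic coordinate descent, unpenalized intercept, warm
#' starts), minimizing `-(1/n) loglik + lambda * ||beta||_1`. The
#' solver is compiled because the permutation test refits it tens of
#' thousands of times on small feature matrices.
#'
#' @param X `n x p` predictor matrix (pre-standardized by the caller).
#' @param y 0/1 response vector.
#' @param lambda Decreasing penalty sequence.
#' @return `(p + 1) x length(lambda)` coefficient matrix, intercept row
#'   first.
#' @export
lasso_logistic_path <- function(X, y, lambda) {
  .lasso_logistic_path_cpp(as.matrix(X), as.numeric(y), as.numeric(lambda))
}

#' LASSO-weighted congruency metric under leave-one-participant-out CV
#'
#' For each participant, a sparse logistic regression (LASSO) is trained
#' on all other participants' congruency features to predict group
#' (CAC = 1, DYS = 0), and the held-out participant receives the fitted
#' linear predictor `x' beta` (training-fold intercept omitted: under
#' leave-one-out the intercept tracks the held-out label through fold
#' composition, injecting a label-dependent offset into otherwise
#' uninformative scores). Features are z-scored per training fold; the
#' penalty is selected inside each training fold by stratified 5-fold
#' cross-validation minimizing binomial deviance.
#'
#' @param features `S x K` matrix of congruency features.
#' @param labels Group labels (`CAC` / `DYS`), length `S`.
#' @param nfolds_inner Inner CV folds for penalty selection.
#' @param nlambda Length of the candidate penalty grid.
#' @param lambda_min_ratio Smallest penalty as a fraction of the
#'   data-derived maximum.
#' @return Object of class `classifier_result`: `cv_scores`
#'   (out-of-fold decision values), `auc`, `weights` (`(K + 1) x S`
#'   matrix: per-fold intercept and coefficients), `lambda`
#'   (per-fold selected penalty), `labels`.
#' @export
lasso_weighted_scores <- function(features, labels, nfolds_inner = 5,
                                  nlambda = 15, lambda_min_ratio = 0.01) {
  features <- as.matrix(features)
  S <- nrow(features)
  labels <- as.character(labels)
  if (length(labels) != S) stop("labels must match feature rows")
  if (length(unique(labels)) != 2)
    stop("both classes must be present")
  y <- as.numeric(labels == "CAC")
  scores <- numeric(S)
  weights <- matrix(NA_real_, ncol(features) + 1, S)
  lam_sel <- numeric(S)
  for (s in seq_len(S)) {
    fit <- fit_lasso_fold(features[-s, , drop = FALSE], y[-s],
                          nfolds_inner, nlambda, lambda_min_ratio)
    scores[s] <- sum((features[s, ] - fit$mu) / fit$sd * fit$beta)
    weights[, s] <- fit$coef
    lam_sel[s] <- fit$lambda
  }
  structure(list(cv_scores = scores,
                 auc = auc_score(scores, labels),
                 weights = weights, lambda = lam_sel, labels = labels),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %d participants, LOO AUC = %.3f\n",
              length(x$cv_scores), x$auc))
  invisible(x)
}

#' Permutation test of the cross-validated AUC
#'
#' Permutes the group labels and re-runs the full pipeline per
#' permutation: nested component extraction from the permuted reference
#' set, congruency features, LOO LASSO, AUC (via
#' [congruency_classifier()]). The p-value is
#' `(1 + #(AUC_perm >= AUC_obs)) / (n_perm + 1)`.
#'
#' @param pairs Precomputed [pair_covariances()] array for the cohort.
#' @param labels Group labels (`CAC` / `DYS`).
#' @param observed_auc The AUC obtained with the true labels.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @param K Components per congruency vector.
#' @param gamma Within-covariance shrinkage.
#' @return List with `p`, `n_perm`, `perm_aucs`.
#' @export
permutation_test_auc <- function(pairs, labels, observed_auc, n_perm = 1000,
                                 seed = 1, K = 10, gamma = 0.05) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.character(labels)
  with_local_seed(seed, {
    perm_aucs <- vapply(seq_len(n_perm), function(b) {
      lp <- sample(labels)
      congruency_classifier(pairs, lp, K = K, gamma = gamma)$auc
    }, numeric(1))
    list(p = (1 + sum(perm_aucs >= observed_auc)) / (n_perm + 1),
         n_perm = n_perm, perm_aucs = perm_aucs)
  })
}

#' Two-way ANOVA of a congruency metric on group and grade
#'
#' Type II sums of squares (robust to mild imbalance) via [car::Anova()].
#' A degenerate fit (zero residual variance) is flagged instead of
#' reporting unstable F statistics.
#'
#' @param metrics Metric table: one row per participant with columns
#'   `group`, `grade` and the response.
#' @param response Name of the response column.
#' @return Data frame with `effect`, `df`, `F`, `p` and attribute
#'   `degenerate`.
#' @export
anova_group_grade <- function(metrics, response = "c_rrnc") {
  if (!all(c("group", "grade", response) %in% names(metrics)))
    stop("metrics must contain group, grade and the response column")
  metrics$group <- factor(metrics$group)
  metrics$grade <- factor(metrics$grade)
  if (any(table(metrics$group, metrics$grade) == 0))
    stop("empty group x grade cell")
  fml <- stats::as.formula(paste(response, "~ group * grade"))
  fit <- stats::lm(fml, data = metrics)
  degenerate <- stats::sigma(fit) < 1e-10
  if (degenerate) {
    warning("zero residual variance; F statistics undefined")
    out <- data.frame(effect = c("group", "grade", "group:grade"),
                      df = NA_real_, F = NA_real_, p = NA_real_)
  } else {
    tab <- car::Anova(fit, type = 2)
    keep <- rownames(tab) != "Residuals"
    out <- data.frame(effect = rownames(tab)[keep],
                      df = tab$Df[keep],
                      F = tab$`F value`[keep],
                      p = tab$`Pr(>F)`[keep])
  }
  attr(out, "degenerate") <- degenerate
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA on modality and confusability
#'
#' The four task conditions form a 2 x 2 within-subject design:
#' modality (rime: conditions 1-2; visual: conditions 3-4) by
#' confusability (confusable: conditions 1 and 3; non-confusable:
#' conditions 2 and 4). Classic univariate repeated-measures F tests via
#' `aov` with participant error strata.
#'
#' @param metrics Metric table with columns `participant`, `condition`
#'   (1..4) and the response; every participant needs all 4 conditions.
#' @param response Name of the response column.
#' @return Data frame with `effect`, `df`, `F`, `p`.
#' @export
rm_anova_modality_confusability <- function(metrics, response = "c_rrnc") {
  need <- c("participant", "condition", response)
  if (!all(need %in% names(metrics)))
    stop("metrics must contain participant, condition and the response")
  counts <- table(metrics$participant)
  bad <- names(counts)[counts != 4]
  if (length(bad) || !all(sort(unique(metrics$condition)) == 1:4))
    stop(sprintf("every participant needs all 4 conditions; offending: %s",
                 paste(bad, collapse = ", ")))
  d <- metrics
  d$modality <- factor(ifelse(d$condition %in% c(1, 2), "rime", "visual"))
  d$confusability <- factor(ifelse(d$condition %in% c(1, 3),
                                   "confusable", "nonconfusable"))
  d$participant <- factor(d$participant)
  d$y <- d[[response]]
  fit <- stats::aov(
    y ~ modality * confusability +
      Error(participant / (modality * confusability)), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    for (r in rownames(tab)) {
      eff <- trimws(r)
      if (eff %in% c("modality", "confusability", "modality:confusability"))
        rows[[eff]] <- data.frame(effect = eff, df = tab[r, "Df"],
                                  F = tab[r, "F value"],
                                  p = tab[r, "Pr(>F)"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
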