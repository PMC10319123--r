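# Fully nested leave-one-participant-out classification: for each held
# out participant, component extraction, congruency features of every
# training participant, feature standardization and penalty selection
# are all computed on the cohort with the held-out participant removed.
# Nothing in a training fold depends on the held-out participant's data.

# RRNC scores of participant `s` against reference members `use`
# (not containing s), projected on the columns of W. `pm` is the
# flattened pair array (one column per ordered pair), built once per
# classifier call.
score_against_pm <- function(pm, D, S_all, s, use, W) {
  Sg <- length(use)
  As <- matrix(rowSums(pm[, s + S_all * (use - 1), drop = FALSE]), D, D)
  Wg <- matrix(rowSums(pm[, use + S_all * (use - 1), drop = FALSE]), D, D)
  Rsb <- (As + t(As)) / Sg
  Rsw <- matrix(pm[, s + S_all * (s - 1)], D, D) + Wg / Sg
  score_projected(Rsb, Rsw, W)
}

pooled_from_pm <- function(pm, D, S_all, idx, gamma) {
  S <- length(idx)
  R_tot <- matrix(rowSums(pm[, rep(idx, S) + S_all * (rep(idx, each = S) - 1),
                             drop = FALSE]), D, D)
  Rw_sum <- matrix(rowSums(pm[, idx + S_all * (idx - 1), drop = FALSE]), D, D)
  Rb <- (R_tot - Rw_sum) / (S * (S - 1))
  Rb <- (Rb + t(Rb)) / 2
  Rw_raw <- Rw_sum / S
  Rw <- (1 - gamma) * Rw_raw + gamma * (sum(diag(Rw_raw)) / D) * diag(D)
  structure(list(Rb = Rb, Rw = Rw, Rw_raw = Rw_raw, gamma = gamma,
                 S = S, n_cols = NA_integer_),
            class = "pooled_cov")
}

#' Nested leave-one-out congruency classification
#'
#' For each held-out participant `s`: components are extracted from the
#' reference (CAC) group excluding `s`; every training participant `t`
#' receives congruency features against that reference additionally
#' excluding `t`; a sparse logistic regression is trained on those
#' features (z-scored per fold, penalty by stratified 5-fold inner CV);
#' and `s` is scored by the fitted weights applied to its own features
#' (computed against the reference excluding `s`). The held-out
#' participant's data therefore influence neither the component bases
#' nor the features used in their training fold.
#'
#' Bases are cached by reference set, which recur across folds.
#'
#' Requires at least 4 reference-group members (a training fold
#' excludes both the held-out and the training participant).
#'
#' @param pairs Precomputed [pair_covariances()] array.
#' @param labels Group labels (`CAC` / `DYS`).
#' @param K Components per feature vector.
#' @param gamma Within-covariance shrinkage.
#' @param nfolds_inner,nlambda,lambda_min_ratio See
#'   [lasso_weighted_scores()].
#' @param return_folds Also return each fold's training feature matrix
#'   (for leakage audits).
#' @return A `classifier_result` (see [lasso_weighted_scores()]); with
#'   `return_folds = TRUE` it additionally carries `fold_features`.
#' @export
congruency_classifier <- function(pairs, labels, K = 10, gamma = 0.05,
                                  nfolds_inner = 5, nlambda = 15,
                                  lambda_min_ratio = 0.01,
                                  return_folds = FALSE) {
  labels <- as.character(labels)
  S <- dim(pairs)[3]
  stopifnot(length(labels) == S)
  if (length(unique(labels)) != 2) stop("both classes must be present")
  is_ref <- labels == "CAC"
  ref <- which(is_ref)
  y <- as.numeric(is_ref)
  D <- dim(pairs)[1]

  pm <- matrix(pairs, D * D, S * S)
  cache <- new.env(parent = emptyenv())
  basis_W <- function(use) {
    key <- paste(use, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    pc <- pooled_from_pm(pm, D, S, use, gamma)
    W <- solve_congruency_components(pc, K)$W
    cache[[key]] <- W
    W
  }
  feature_of <- function(t, excl) {
    use <- setdiff(ref, c(t, excl))
    if (length(use) < 2)
      stop(sprintf("reference group too small after excluding %s",
                   paste(unique(c(t, excl)), collapse = ", ")))
    score_against_pm(pm, D, S, t, use, basis_W(use))
  }

  scores <- numeric(S)
  weights <- matrix(NA_real_, K + 1, S)
  lam_sel <- numeric(S)
  fold_feats <- if (return_folds) vector("list", S) else NULL
  for (s in seq_len(S)) {
    train <- setdiff(seq_len(S), s)
    feats_tr <- t(vapply(train, feature_of, numeric(K), excl = s))
    fit <- fit_lasso_fold(feats_tr, y[train], nfolds_inner, nlambda,
                          lambda_min_ratio)
    f_s <- feature_of(s, integer(0))
    scores[s] <- sum((f_s - fit$mu) / fit$sd * fit$beta)
    weights[, s] <- fit$coef
    lam_sel[s] <- fit$lambda
    if (return_folds) fold_feats[[s]] <- feats_tr
  }
  out <- structure(list(cv_scores = scores,
                        auc = auc_score(scores, labels),
                        weights = weights, lambda = lam_sel,
                        labels = labels),
                   class = "classifier_result")
  if (return_folds) out$fold_features <- fold_feats
  out
}

# One training fold: z-score, select the penalty by stratified inner CV
# minimizing binomial deviance, refit on the whole fold.
fit_lasso_fold <- function(Xtr, ytr, nfolds_inner = 5, nlambda = 15,
                           lambda_min_ratio = 0.01) {
  if (length(unique(ytr)) < 2)
    stop("training fold with a single class; groups too small")
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  Xz <- sweep(sweep(Xtr, 2, mu), 2, sd, `/`)
  n <- nrow(Xz)
  lam_max <- max(abs(crossprod(Xz, ytr - mean(ytr)))) / n
  lam_max <- max(lam_max, 1e-4)
  lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                    length.out = nlambda))
  fold <- stratified_folds(ytr, nfolds_inner)
  fds <- sort(unique(fold))
  dev <- matrix(0, length(fds), nlambda)
  for (fd in fds) {
    tr <- fold != fd
    co <- lasso_logistic_path(Xz[tr, , drop = FALSE], ytr[tr], lambda)
    eta <- cbind(1, Xz[!tr, , drop = FALSE]) %*% co
    dev[match(fd, fds), ] <- apply(eta, 2, function(e)
      binomial_deviance(ytr[!tr], e))
  }
  best <- which.min(colMeans(dev))
  co_full <- lasso_logistic_path(Xz, ytr, lambda)
  list(mu = mu, sd = sd, beta = co_full[-1, best], coef = co_full[, best],
       lambda = lambda[best])
}
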