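# Correlated-component extraction for fixation-related potentials.
#
# For a reference group of S participants with concatenated epoch
# matrices X_i (D x N, equal N), define pairwise cross-covariances
# R_ij = X_i X_j' / N, the pooled between-subject covariance
# Rb = 1/(S(S-1)) * sum_{i != j} R_ij and the pooled within-subject
# covariance Rw = 1/S * sum_i R_ii. Spatial components w maximize the
# congruency ratio rho(w) = (w' Rb w) / (w' Rw w); the maximizers are the
# eigenvectors of the pencil (Rb, Rw), solved here by symmetric whitening
# so eigenvalues are guaranteed real. A participant's congruency with the
# group along component k is the ratio of their subject-to-group
# cross-covariance over the pooled within-covariance after projection
# (RRNC score).

#' Pairwise cross-covariance of two concatenated epoch matrices
#'
#' `R_ij = X_i X_j' / N` with `N` the shared column count. The normalizer
#' cancels in every ratio downstream; it is kept so matrix entries stay
#' on the scale of channel covariances.
#'
#' @param Xi,Xj `D x N` matrices with equal `N`.
#' @return `D x D` matrix with attribute `n_cols`.
#' @export
pairwise_cross_covariance <- function(Xi, Xj) {
  if (ncol(Xi) != ncol(Xj))
    stop(sprintf("column mismatch: %d vs %d", ncol(Xi), ncol(Xj)))
  R <- tcrossprod(Xi, Xj) / ncol(Xi)
  attr(R, "n_cols") <- ncol(Xi)
  R
}

#' All pairwise cross-covariances of a cohort
#'
#' Precomputes `R_ij` for every ordered pair once, so that leave-one-out
#' component extraction and label permutations cost `O(D^2)` per fold
#' instead of rescanning the raw data.
#'
#' @param X_list List of `D x N` matrices (equal `N`).
#' @return `D x D x S x S` array; slice `[, , i, j]` is `R_ij`.
#' @export
pair_covariances <- function(X_list) {
  S <- length(X_list)
  D <- nrow(X_list[[1]])
  N <- ncol(X_list[[1]])
  if (any(vapply(X_list, ncol, integer(1)) != N))
    stop("all participants must share the same column count")
  out <- array(0, c(D, D, S, S))
  for (i in seq_len(S)) {
    for (j in i:S) {
      R <- tcrossprod(X_list[[i]], X_list[[j]]) / N
      out[, , i, j] <- R
      if (j > i) out[, , j, i] <- t(R)
    }
  }
  out
}

#' Pooled between- and within-subject covariances of a reference group
#'
#' `Rb` averages all ordered pairs `i != j` and is symmetrized; `Rw`
#' averages the `S` auto-covariances and is shrunk toward the scaled
#' identity, `Rw <- (1 - gamma) Rw + gamma (tr(Rw) / D) I`. Shrinkage is
#' needed because average-referenced data make `Rw` rank-deficient
#' (rank at most `D - 1`).
#'
#' @param X_list List of `D x N` matrices (the group members); `S >= 2`.
#' @param gamma Shrinkage weight in `[0, 1]`.
#' @return Object of class `pooled_cov`: `Rb`, `Rw` (shrunk), `Rw_raw`,
#'   `gamma`, `S`, `n_cols`.
#' @export
pooled_covariances <- function(X_list, gamma = 0.05) {
  S <- length(X_list)
  if (S < 2) stop("a reference group needs at least 2 members")
  N <- ncol(X_list[[1]])
  if (any(vapply(X_list, ncol, integer(1)) != N))
    stop("all group members must share the same column count")
  D <- nrow(X_list[[1]])
  Xsum <- Reduce(`+`, X_list)
  R_tot <- tcrossprod(Xsum) / N            # sum over all ordered pairs
  Rw_sum <- Reduce(`+`, lapply(X_list, function(X) tcrossprod(X) / N))
  Rb <- (R_tot - Rw_sum) / (S * (S - 1))
  Rb <- (Rb + t(Rb)) / 2
  Rw_raw <- Rw_sum / S
  Rw <- (1 - gamma) * Rw_raw + gamma * (sum(diag(Rw_raw)) / D) * diag(D)
  structure(list(Rb = Rb, Rw = Rw, Rw_raw = Rw_raw, gamma = gamma,
                 S = S, n_cols = N),
            class = "pooled_cov")
}

# Same pooled covariances from a precomputed pair array, for the members
# in `idx`.
pooled_covariances_from_pairs <- function(pairs, idx, gamma = 0.05) {
  S <- length(idx)
  if (S < 2) stop("a reference group needs at least 2 members")
  D <- dim(pairs)[1]
  S_all <- dim(pairs)[3]
  pm <- matrix(pairs, D * D, S_all * S_all)
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

#' Solve for congruency components
#'
#' Solves the generalized eigenvalue problem `Rw^{-1} Rb w = lambda w`
#' via symmetric whitening (`Rw^{-1/2} Rb Rw^{-1/2}`), which guarantees
#' real eigenvalues for the symmetrized, shrunk pencil. Eigenvectors are
#' returned unit-norm, ordered by descending eigenvalue, with sign fixed
#' so the largest-magnitude entry of each forward model is positive.
#'
#' Directions carrying no raw within-subject variance (for
#' average-referenced data, the common-mode direction) have a 0/0
#' congruency ratio and are excluded from the ranking.
#'
#' @param pc A `pooled_cov`.
#' @param K Number of components to return (`K <= D`).
#' @return Object of class `component_basis`: `W` (`D x K` spatial
#'   filters), `lambdas`, `rhos` (Rayleigh quotients, equal to the
#'   eigenvalues), `A` (`D x K` forward models), `gamma`.
#' @export
solve_congruency_components <- function(pc, K) {
  stopifnot(inherits(pc, "pooled_cov"))
  D <- nrow(pc$Rw)
  if (K > D) stop("K cannot exceed the channel count")
  e <- eigen(pc$Rw, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    if (pc$gamma == 0)
      stop("Rw is singular; increase the shrinkage gamma")
    stop("Rw is numerically singular even after shrinkage")
  }
  Wi <- e$vectors %*% (t(e$vectors) / sqrt(e$values))   # Rw^{-1/2}
  M <- Wi %*% pc$Rb %*% Wi
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  W_all <- Wi %*% em$vectors
  W_all <- sweep(W_all, 2, sqrt(colSums(W_all^2)), `/`)
  Rw_raw <- pc$Rw_raw %||% pc$Rw
  vraw <- colSums(W_all * (Rw_raw %*% W_all))
  valid <- vraw > sum(diag(Rw_raw)) / D * 1e-8
  if (sum(valid) < K)
    stop(sprintf("only %d components carry within-subject variance; K = %d too large",
                 sum(valid), K))
  keep <- which(valid)[seq_len(K)]     # eigen order is descending lambda
  lambdas <- em$values[keep]
  W <- W_all[, keep, drop = FALSE]
  A <- matrix(0, D, K)
  rhos <- numeric(K)
  for (kk in seq_len(K)) {
    a <- forward_model(pc$Rw, W[, kk])
    i <- which.max(abs(a))
    if (a[i] < 0) {
      W[, kk] <- -W[, kk]
      a <- -a
    }
    A[, kk] <- a
    w <- W[, kk]
    rhos[kk] <- drop(crossprod(w, pc$Rb %*% w) / crossprod(w, pc$Rw %*% w))
  }
  structure(list(W = W, lambdas = lambdas, rhos = rhos, A = A,
                 gamma = pc$gamma),
            class = "component_basis")
}

#' Forward model (scalp topography) of a spatial filter
#'
#' `a = Rw w / (w' Rw w)`: the pattern describing how the component's
#' activity couples into the electrodes. Filters (`w`) are not
#' interpretable as topographies; forward models are.
#'
#' @param Rw Within-subject covariance (`D x D`).
#' @param w Spatial filter (length `D`, nonzero).
#' @return Length-`D` forward-model vector.
#' @export
forward_model <- function(Rw, w) {
  denom <- drop(crossprod(w, Rw %*% w))
  if (abs(denom) < .Machine$double.eps * nrow(Rw))
    stop("w lies in the null space of Rw; forward model undefined")
  drop(Rw %*% w) / denom
}

#' Per-component congruency (RRNC) scores of one participant
#'
#' Projected ratio of the participant's cross-covariance with the group
#' over the pooled within-covariance:
#' `RRNC_k = (w_k' R_sb w_k) / (w_k' R_sw w_k)` with
#' `R_sb = 1/S * sum_i (R_si + R_is)` and
#' `R_sw = 1/S * sum_i (R_ss + R_ii)` over the group members `i`.
#' Raw (unshrunk) covariances are used, so a participant identical to
#' every group member scores exactly 1 on every component.
#'
#' @param Xs The participant's `D x N` matrix.
#' @param X_group List of group members' matrices (not including `Xs`).
#' @param W `D x K` matrix of spatial filters.
#' @return Length-`K` numeric vector of RRNC scores.
#' @export
subject_congruency_score <- function(Xs, X_group, W) {
  S <- length(X_group)
  N <- ncol(Xs)
  if (any(vapply(X_group, ncol, integer(1)) != N))
    stop("participant and group must share the same column count")
  Xgsum <- Reduce(`+`, X_group)
  Rsg <- tcrossprod(Xs, Xgsum) / N          # sum_i R_si
  Rsb <- (Rsg + t(Rsg)) / S
  Rss <- tcrossprod(Xs) / N
  Rii_mean <- Reduce(`+`, lapply(X_group, function(X) tcrossprod(X) / N)) / S
  Rsw <- Rss + Rii_mean
  score_projected(Rsb, Rsw, W)
}

score_projected <- function(Rsb, Rsw, W) {
  num <- colSums(W * (Rsb %*% W))
  den <- colSums(W * (Rsw %*% W))
  if (any(den < max(abs(den), 1) * 1e-12))
    stop("zero projected within-covariance; RRNC undefined")
  num / den
}

#' Leave-one-out congruency feature vectors for a cohort
#'
#' For each participant `s`, extracts components from the reference
#' group (CAC) with `s` excluded when `s` is a member, then computes the
#' RRNC scores of `s` against that same exclusion group for components
#' `k = 1..K` (ordered by descending eigenvalue). This guarantees that a
#' participant's own data never influence the basis used to score them.
#'
#' @param X_list List of `D x N` matrices, one per participant.
#' @param is_ref Logical vector: membership in the reference group.
#' @param K Number of components retained per participant.
#' @param gamma Shrinkage for the pooled within-covariance.
#' @param pairs Optional precomputed [pair_covariances()] array; when
#'   supplied, `X_list` may be `NULL`.
#' @return List with `features` (`S x K` matrix of RRNC scores) and
#'   `bases` (per-participant `component_basis`).
#' @export
congruency_features <- function(X_list = NULL, is_ref, K = 10,
                                gamma = 0.05, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_covariances(X_list)
  S_all <- dim(pairs)[3]
  stopifnot(length(is_ref) == S_all)
  D <- dim(pairs)[1]
  if (K > D) stop("K cannot exceed the channel count")
  ref <- which(is_ref)
  if (length(ref) < 2) stop("reference group too small")
  feats <- matrix(NA_real_, S_all, K)
  bases <- vector("list", S_all)

  # flat view: column (i, j) of `pm` holds vec(R_ij). Every fold sums
  # only over its own exclusion group, so a participant's data provably
  # (bit-exactly) never enter the basis used to score them.
  pm <- matrix(pairs, D * D, S_all * S_all)
  col_of <- function(i, j) i + S_all * (j - 1)

  for (s in seq_len(S_all)) {
    in_ref <- is_ref[s]
    use <- if (in_ref) setdiff(ref, s) else ref
    Sg <- length(use)
    if (Sg < 2)
      stop(sprintf("reference group too small after excluding participant %d", s))
    Rss <- pairs[, , s, s]
    Tg <- matrix(rowSums(pm[, col_of(rep(use, Sg), rep(use, each = Sg)),
                            drop = FALSE]), D, D)
    Wg_sum <- matrix(rowSums(pm[, col_of(use, use), drop = FALSE]), D, D)
    As <- matrix(rowSums(pm[, col_of(rep(s, Sg), use), drop = FALSE]), D, D)
    Rb <- (Tg - Wg_sum) / (Sg * (Sg - 1))
    Rb <- (Rb + t(Rb)) / 2
    Rw_raw <- Wg_sum / Sg
    Rw <- (1 - gamma) * Rw_raw + gamma * (sum(diag(Rw_raw)) / D) * diag(D)
    pc <- structure(list(Rb = Rb, Rw = Rw, Rw_raw = Rw_raw, gamma = gamma,
                         S = Sg, n_cols = NA_integer_),
                    class = "pooled_cov")
    basis <- solve_congruency_components(pc, K)
    Rsb <- (As + t(As)) / Sg
    Rsw <- Rss + Rw_raw
    feats[s, ] <- score_projected(Rsb, Rsw, basis$W)
    bases[[s]] <- basis
  }
  list(features = feats, bases = bases)
}

#' Per-component temporal profiles
#'
#' Projects every epoch onto each spatial filter and grand-averages the
#' projected time courses, per group of FRP sets.
#'
#' @param W `D x K` matrix of spatial filters.
#' @param frp_groups Named list of lists of `frp_set` objects (e.g. one
#'   entry per participant group).
#' @return Named list of `K x T` matrices of projected mean time courses.
#' @export
temporal_profiles <- function(W, frp_groups) {
  lapply(frp_groups, function(frps) {
    acc <- NULL
    n <- 0
    for (f in frps) {
      Fn <- dim(f$epochs)[3]
      if (Fn == 0) next
      D <- dim(f$epochs)[1]
      Tn <- dim(f$epochs)[2]
      flat <- matrix(f$epochs, D, Tn * Fn)
      proj <- crossprod(W, flat)                 # K x (T*F)
      summed <- array(proj, c(ncol(W), Tn, Fn))
      contrib <- apply(summed, c(1, 2), sum)
      acc <- if (is.null(acc)) contrib else acc + contrib
      n <- n + Fn
    }
    if (n == 0) stop("no epochs available for temporal profiles")
    acc / n
  })
}
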