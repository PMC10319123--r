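test_that("pairwise cross-covariance matches the direct-sum oracle", {
  set.seed(21)
  Xi <- matrix(rnorm(300), 3, 100)
  Xj <- matrix(rnorm(300), 3, 100)
  R <- pairwise_cross_covariance(Xi, Xj)
  oracle <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    oracle[a, b] <- sum(Xi[a, ] * Xj[b, ]) / 100
  expect_equal(unclass(R), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  # gram case: symmetric PSD
  Rii <- pairwise_cross_covariance(Xi, Xi)
  expect_equal(Rii, t(Rii), ignore_attr = TRUE)
  expect_true(all(eigen(Rii, symmetric = TRUE)$values > -1e-12))
  expect_error(pairwise_cross_covariance(Xi, Xj[, 1:50]), "mismatch")
})

test_that("pooled covariances average the ordered pairs", {
  set.seed(22)
  Xs <- lapply(1:3, function(i) matrix(rnorm(2 * 40), 2, 40))
  pc <- pooled_covariances(Xs, gamma = 0)
  # hand enumeration of the 6 ordered pairs and 3 auto terms
  Rb_hand <- matrix(0, 2, 2)
  for (i in 1:3) for (j in 1:3) if (i != j)
    Rb_hand <- Rb_hand + tcrossprod(Xs[[i]], Xs[[j]]) / 40
  Rb_hand <- Rb_hand / 6
  Rb_hand <- (Rb_hand + t(Rb_hand)) / 2
  Rw_hand <- Reduce(`+`, lapply(Xs, function(X) tcrossprod(X) / 40)) / 3
  expect_equal(pc$Rb, Rb_hand, tolerance = 1e-12)
  expect_equal(pc$Rw, Rw_hand, tolerance = 1e-12)

  # identical members: Rb equals Rw
  pc2 <- pooled_covariances(list(Xs[[1]], Xs[[1]], Xs[[1]]), gamma = 0)
  expect_equal(pc2$Rb, pc2$Rw, tolerance = 1e-12)
  expect_error(pooled_covariances(Xs[1]), "at least 2")

  # the fast pair-array path agrees with the direct computation
  pairs <- pair_covariances(Xs)
  pc3 <- rrnc:::pooled_covariances_from_pairs(pairs, 1:3, gamma = 0)
  expect_equal(pc3$Rb, pc$Rb, tolerance = 1e-12)
  expect_equal(pc3$Rw, pc$Rw, tolerance = 1e-12)
})

test_that("independent streams pool to a small between-subject covariance", {
  set.seed(23)
  Xs <- lapply(1:4, function(i) matrix(rnorm(3 * 5000), 3, 5000))
  pc <- pooled_covariances(Xs, gamma = 0)
  expect_lt(norm(pc$Rb, "F"), 0.1 * norm(pc$Rw, "F"))
})

test_that("the diagonal pencil is solved exactly", {
  pc <- make_pooled(diag(c(3, 2, 1)), diag(3))
  b <- solve_congruency_components(pc, 3)
  expect_equal(b$lambdas, c(3, 2, 1))
  expect_equal(abs(b$W), diag(3), tolerance = 1e-10)
  expect_equal(b$rhos, b$lambdas, tolerance = 1e-12)
  # identity pencil: all eigenvalues are 1
  pc2 <- make_pooled(diag(3), diag(3))
  expect_equal(solve_congruency_components(pc2, 3)$lambdas, rep(1, 3),
               tolerance = 1e-12)
})

test_that("the leading eigenvalue matches a random-search maximization of rho", {
  set.seed(24)
  for (rep in 1:5) {
    Rw <- random_spd(4)
    B <- matrix(rnorm(16), 4)
    Rb <- crossprod(B) / 4
    pc <- make_pooled(Rb, Rw)
    b <- solve_congruency_components(pc, 4)
    found <- rho_max_random_search(Rb, Rw)
    expect_lt(found - b$lambdas[1], 1e-9)   # search cannot beat the solver
    expect_lt(b$lambdas[1] - found, 1e-6)   # but converges to it
    expect_equal(b$rhos, b$lambdas, tolerance = 1e-9)
  }
})

test_that("singular Rw without shrinkage asks for regularization", {
  X <- matrix(rnorm(3 * 50), 3, 50)
  X <- sweep(X, 2, colMeans(X))  # average-referenced: rank 2
  pc <- pooled_covariances(list(X, X), gamma = 0)
  expect_error(solve_congruency_components(pc, 2), "shrinkage")
})

test_that("forward models follow the covariance-pattern formula", {
  set.seed(25)
  w <- rnorm(4); w <- w / sqrt(sum(w^2))
  expect_equal(forward_model(diag(4), w), w, tolerance = 1e-12)
  Rw <- random_spd(4)
  a <- forward_model(Rw, w)
  expect_equal(a, drop(Rw %*% w) / drop(crossprod(w, Rw %*% w)),
               tolerance = 1e-12)
  # homogeneity: scaling w by c scales a by 1/c
  expect_equal(forward_model(Rw, 3 * w), a / 3, tolerance = 1e-12)
})

test_that("RRNC endpoints: identical subject scores exactly 1, flipped subject negative", {
  set.seed(26)
  X <- matrix(rnorm(5 * 400), 5, 400)
  group <- list(X, X, X)
  W <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
  expect_equal(subject_congruency_score(X, group, W), rep(1, 3))
  # sign flip of a shared signal drives the score negative
  s <- matrix(rnorm(1 * 400), 1, 400)
  u <- c(1, 0, 0, 0, 0)
  members <- lapply(1:3, function(i) u %*% s + 0.1 * matrix(rnorm(2000), 5))
  flipped <- -u %*% s + 0.1 * matrix(rnorm(2000), 5)
  sc <- subject_congruency_score(flipped, members, matrix(u, 5, 1))
  expect_lt(sc, 0)
  expect_error(subject_congruency_score(X, list(X[, 1:10]), W), "column")
})

test_that("an independent-noise subject scores near zero against a structured group", {
  set.seed(27)
  n <- 2e4
  s <- matrix(rnorm(n), 1, n)
  u <- c(1, 2, 0, -1) / sqrt(6)
  members <- lapply(1:4, function(i) u %*% s + 0.3 * matrix(rnorm(4 * n), 4))
  noise <- matrix(rnorm(4 * n), 4, n)
  pc <- pooled_covariances(members, gamma = 0.01)
  b <- solve_congruency_components(pc, 3)
  sc <- subject_congruency_score(noise, members, b$W)
  expect_true(all(abs(sc) < 0.1))
})

test_that("leave-one-out extraction never sees the scored participant", {
  fix <- small_gap_cohort()
  X <- fix$X
  is_ref <- fix$cohort$manifest$group == "CAC"
  cf <- congruency_features(X, is_ref = is_ref, K = 5)
  # perturb a reference member wildly: their own scoring basis is unchanged
  s <- which(is_ref)[1]
  X2 <- X
  X2[[s]] <- X2[[s]] * 100 + 42
  cf2 <- congruency_features(X2, is_ref = is_ref, K = 5)
  expect_identical(cf$bases[[s]]$W, cf2$bases[[s]]$W)
  expect_identical(cf$bases[[s]]$lambdas, cf2$bases[[s]]$lambdas)
  # perturbing a non-reference member changes nobody else's features
  d <- which(!is_ref)[1]
  X3 <- X
  X3[[d]] <- X3[[d]] * -7 + 1
  cf3 <- congruency_features(X3, is_ref = is_ref, K = 5)
  expect_identical(cf$features[-d, ], cf3$features[-d, ])
})

test_that("the analysis is invariant to a common amplitude rescaling", {
  fix <- small_gap_cohort()
  X <- fix$X
  is_ref <- fix$cohort$manifest$group == "CAC"
  cf1 <- congruency_features(X, is_ref = is_ref, K = 4)
  cf2 <- congruency_features(lapply(X, function(x) x * 3.7),
                             is_ref = is_ref, K = 4)
  expect_equal(cf1$features, cf2$features, tolerance = 1e-9)
  expect_equal(cf1$bases[[1]]$lambdas, cf2$bases[[1]]$lambdas,
               tolerance = 1e-9)
})

test_that("temporal profiles recover projected waveforms and cancel opposites", {
  w <- c(0.6, 0.8)
  g <- sin(seq(0, 2 * pi, length.out = 50))
  ep1 <- array(outer(w, g), c(2, 50, 1))
  f1 <- structure(list(epochs = ep1, fs = 256, k = 1:50,
                       participant = "A", condition = 1), class = "frp_set")
  prof <- temporal_profiles(matrix(w, 2, 1), list(g1 = list(f1)))$g1
  expect_equal(drop(prof), g, tolerance = 1e-12)  # unit w: g * ||w||^2 = g
  ep2 <- array(c(outer(w, g), outer(w, -g)), c(2, 50, 2))
  f2 <- structure(list(epochs = ep2, fs = 256, k = 1:50,
                       participant = "A", condition = 1), class = "frp_set")
  prof2 <- temporal_profiles(matrix(w, 2, 1), list(g1 = list(f2)))$g1
  expect_lt(max(abs(prof2)), 1e-12)
})
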