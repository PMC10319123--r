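test_that("zero-variance inter-fixation intervals give a deterministic train", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 4, mean_ifi = 350,
                       ifi_cv = 0, seed = 1)
  set.seed(1)
  fx <- generate_fixation_sequence(cfg, condition_duration = 3500)
  expect_equal(fx$onset_ms, seq(0, 3150, by = 350))
  expect_true(all(fx$duration_ms > 0))
})

test_that("fixation counts track duration / mean interval", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 4, mean_ifi = 350,
                       ifi_cv = 0.3, seed = 1)
  set.seed(7)
  fx <- generate_fixation_sequence(cfg, condition_duration = 35000)
  expected <- 35000 / 350
  expect_gt(nrow(fx), expected - 3 * sqrt(expected))
  expect_lt(nrow(fx), expected + 3 * sqrt(expected))
  expect_true(all(diff(fx$onset_ms) > 0))
  expect_true(all(fx$onset_ms >= 0 & fx$onset_ms < 35000))
  # onsets on the 1 kHz eye-tracker grid
  expect_equal(fx$onset_ms, round(fx$onset_ms * cfg$fs_eye / 1000) /
                 cfg$fs_eye * 1000)
})

test_that("degenerate fixation-sequence inputs are rejected", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 4, mean_ifi = 350)
  expect_error(generate_fixation_sequence(cfg, condition_duration = 100),
               "exceed")
  expect_error(cohort_config(n_per_group = 2, mean_ifi = -5), "mean_ifi")
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(n_per_group = 2, noise_spatial_corr = 1.2),
               "spatial_corr")
})

test_that("a cohort is a pure function of its configuration", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 6, n_conditions = 2,
                       letters_per_matrix = 10, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$fixations, c2$fixations)
  expect_identical(c1$manifest, c2$manifest)
})

test_that("cohort structure: participants, conditions, labels", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 6, n_conditions = 4,
                       letters_per_matrix = 8, seed = 5)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$manifest), 4)
  expect_equal(sort(unique(ch$manifest$group)), c("CAC", "DYS"))
  expect_equal(sort(unique(ch$manifest$grade)), c("3", "6"))
  for (p in ch$manifest$participant) {
    expect_equal(nrow(ch$recordings[[p]]$events), 8) # start+end per condition
    expect_equal(sort(unique(ch$fixations[[p]]$condition)), 1:4)
  }
  expect_equal(ncol(ch$truth$mixing_vectors),
               length(cfg$source_waveforms))
  expect_equal(colSums(ch$truth$mixing_vectors^2), rep(1, 3),
               tolerance = 1e-10)
})

test_that("with zero noise and jitter the epoch is exactly the planted pattern", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 5, n_conditions = 1,
                       noise_sd = 0, latency_jitter_sd = c(CAC = 0, DYS = 0),
                       seed = 3)
  set.seed(3)
  M <- matrix(rnorm(5 * 3), 5, 3)
  mixing <- qr.Q(qr(M))
  fix <- data.frame(onset_ms = 2000, duration_ms = 200, x = 0, y = 0)
  rec <- generate_subject_eeg(cfg, list(fix), durations_ms = 5000,
                              gain = 1, jitter_sd = 0, mixing = mixing)
  segs <- extract_condition_segments(rec)
  fx <- align_fixations(
    data.frame(onset_ms = attr(rec, "condition_start_ms") + 2000,
               duration_ms = 200, x = 0, y = 0),
    condition_windows(rec))
  frp <- epoch_at_fixations(segs[[1]], fx)
  expect_equal(dim(frp$epochs)[3], 1)
  pattern <- rrnc:::planted_pattern(cfg, mixing)$pattern
  bsel <- frp$k < 0
  pattern_bc <- pattern - rowMeans(pattern[, bsel, drop = FALSE])
  expect_equal(frp$epochs[, , 1], pattern_bc, tolerance = 1e-9)
})

test_that("zero gain leaves pure noise: the average epoch shrinks with F", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 8, n_conditions = 1,
                       letters_per_matrix = 30, seed = 17,
                       congruency_gain = c(CAC = 0, DYS = 0))
  ch <- generate_cohort(cfg)
  frp <- cohort_frp_sets(ch)[["1"]][[1]]
  avg <- apply(frp$epochs, c(1, 2), mean)
  mean_single <- mean(apply(frp$epochs, 3, function(e) sqrt(mean(e^2))))
  expect_lt(sqrt(mean(avg^2)), 0.5 * mean_single)
})

test_that("two subjects sharing a source correlate on the planted direction", {
  # deterministic fixation trains: the two recordings share the planted
  # signal exactly and differ only in their independent noise
  cfg <- cohort_config(n_per_group = 2, n_channels = 8, n_conditions = 1,
                       letters_per_matrix = 30, noise_sd = 0.25,
                       ifi_cv = 0, duration_cv = 0,
                       latency_jitter_sd = c(CAC = 0, DYS = 0), seed = 23)
  ch <- generate_cohort(cfg)
  X <- condition_matrices(cohort_frp_sets(ch)[["1"]])
  u <- ch$truth$mixing_vectors[, 1]
  expect_gt(cor(drop(crossprod(u, X[[1]])), drop(crossprod(u, X[[2]]))), 0.9)
})

test_that("latency jitter does not increase the leading eigenvalue", {
  l1 <- vapply(c(0, 30, 80), function(j) {
    cfg <- cohort_config(n_per_group = 6, n_channels = 16, n_conditions = 1,
                         letters_per_matrix = 20, seed = 5,
                         latency_jitter_sd = c(CAC = j, DYS = j))
    ch <- generate_cohort(cfg)
    X <- condition_matrices(cohort_frp_sets(ch)[["1"]])
    pc <- pooled_covariances(X[ch$manifest$group == "CAC"])
    solve_congruency_components(pc, 3)$lambdas[1]
  }, numeric(1))
  expect_true(all(diff(l1) <= 0))
})
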