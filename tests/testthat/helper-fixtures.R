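# Shared fixtures, built in code. Cohorts are cached across test files
# because generation is the slowest step.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small two-group cohort with a planted group difference
small_gap_cohort <- function() {
  cached("gap_cohort", {
    cfg <- cohort_config(n_per_group = 6, n_channels = 16, n_conditions = 1,
                         letters_per_matrix = 20, seed = 301,
                         congruency_gain = c(CAC = 1, DYS = 0.5))
    ch <- generate_cohort(cfg)
    X <- condition_matrices(cohort_frp_sets(ch)[["1"]])
    list(cohort = ch, X = X)
  })
}

# a deterministic toy recording: D channels of known sinusoids + events
toy_recording <- function(D = 4, n = 2048, fs = 256, freq = 10,
                          with_events = TRUE) {
  tt <- (seq_len(n) - 1) / fs
  data <- t(sapply(seq_len(D), function(d) sin(2 * pi * freq * tt + d)))
  ev <- if (with_events)
    data.frame(sample = c(600L, 1400L), code = c(101L, 201L))
  else data.frame(sample = integer(), code = integer())
  eeg_recording(data, fs, events = ev)
}

# frp_set stub with a given epoch count
frp_stub <- function(F, D = 3, Tn = 5, participant = "P") {
  structure(list(epochs = array(stats::rnorm(D * Tn * F), c(D, Tn, F)),
                 fs = 256, k = seq_len(Tn), participant = participant,
                 condition = 1),
            class = "frp_set")
}

# random symmetric positive-definite matrix
random_spd <- function(D, jitter = 0.5) {
  A <- matrix(stats::rnorm(D * D), D)
  crossprod(A) / D + jitter * diag(D)
}

# hand-made pooled_cov object
make_pooled <- function(Rb, Rw, gamma = 0) {
  structure(list(Rb = Rb, Rw = Rw, Rw_raw = Rw, gamma = gamma,
                 S = 2L, n_cols = NA_integer_),
            class = "pooled_cov")
}

# derivative-free maximization of the congruency ratio
# rho(w) = (w'Rb w)/(w'Rw w) by adaptive random search: rounds of random
# unit vectors concentrated around the incumbent with shrinking radius.
# Independent of any eigendecomposition.
rho_max_random_search <- function(Rb, Rw, n_total = 1e5, rounds = 10) {
  D <- nrow(Rb)
  per_round <- ceiling(n_total / rounds)
  best_w <- NULL
  best <- -Inf
  radius <- 1
  for (r in seq_len(rounds)) {
    W <- matrix(stats::rnorm(D * per_round), D)
    if (!is.null(best_w)) W <- best_w + radius * W
    W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
    rq <- colSums(W * (Rb %*% W)) / colSums(W * (Rw %*% W))
    i <- which.max(rq)
    if (rq[i] > best) {
      best <- rq[i]
      best_w <- W[, i]
    }
    radius <- radius / 3
  }
  best
}

# brute-force AUC by pair enumeration (independent oracle)
auc_bruteforce <- function(scores, labels, positive = "CAC") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
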