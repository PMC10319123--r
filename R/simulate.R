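# Synthetic co-registered EEG + eye-tracking cohorts with planted
# fixation-locked sources. The generator is first-class: it defines the
# study conditions under which the congruency pipeline is validated.

# Layout constants for assembling a continuous recording (ms).
.SIM_PREROLL_MS <- 3000
.SIM_GAP_MS <- 5000
.SIM_TAIL_MS <- 3000

#' Generate one condition's fixation sequence
#'
#' Draws a serial-reading fixation train for a single letter-matrix
#' condition. Inter-fixation intervals are Gamma distributed with mean
#' `mean_ifi` and coefficient of variation `ifi_cv` (strictly positive and
#' right-skewed, as reading fixations are); `ifi_cv = 0` gives a
#' deterministic train. The first fixation lands at the stimulus onset
#' (t = 0). Onsets are quantized to the eye-tracker sampling grid.
#' Fixation durations are a fixed fraction of the following interval,
#' approximating fixation-plus-saccade timing. Gaze positions walk
#' left-to-right, top-to-bottom over a five-row, ten-column letter grid.
#'
#' Consumes the current RNG stream; seed upstream for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param condition_duration Duration of the condition in ms; must exceed
#'   twice the mean inter-fixation interval.
#' @return Data frame with columns `onset_ms` (relative to stimulus
#'   onset, strictly increasing, within `[0, condition_duration)`),
#'   `duration_ms`, `x`, `y`.
#' @export
generate_fixation_sequence <- function(config, condition_duration) {
  if (config$mean_ifi <= 0) stop("mean_ifi must be positive")
  if (condition_duration <= 2 * config$mean_ifi)
    stop("condition_duration must exceed 2 * mean_ifi")
  n_draw <- ceiling(condition_duration / config$mean_ifi * 2) + 20
  ifi <- rgamma_mean_cv(n_draw, config$mean_ifi, config$ifi_cv)
  onset <- cumsum(c(0, ifi))
  # quantize to the eye-tracker grid, then drop grid collisions
  onset <- round(onset * config$fs_eye / 1000) / config$fs_eye * 1000
  onset <- onset[!duplicated(onset)]
  onset <- onset[onset < condition_duration]
  gap <- c(diff(onset), config$mean_ifi)
  dur <- pmax(0.75 * gap, 1)
  n <- length(onset)
  idx <- (seq_len(n) - 1) %% config$letters_per_matrix
  col <- idx %% 10
  row <- (idx %/% 10) %% 5
  data.frame(
    onset_ms = onset,
    duration_ms = dur,
    x = 360 + col * 133 + stats::rnorm(n, sd = 8),
    y = 240 + row * 150 + stats::rnorm(n, sd = 8)
  )
}

# Planted pattern: D x T matrix of all sources mixed through their
# spatial vectors, sampled on the fixation epoch grid.
planted_pattern <- function(config, mixing) {
  k <- epoch_window_indices(config$fs_eeg)
  t_ms <- k$k / config$fs_eeg * 1000
  G <- vapply(config$source_waveforms, function(wf) {
    wf$amplitude_uv * exp(-((t_ms - wf$latency_ms) / wf$width_ms)^2 / 2)
  }, numeric(length(t_ms)))
  list(pattern = mixing %*% t(G), k = k$k)
}

#' Synthesize one participant's continuous EEG recording
#'
#' Assembles a continuous recording containing one segment per condition
#' (with pre-roll, inter-condition gaps, and tail), embeds condition
#' start/end event markers, plants the configured source waveforms at
#' every fixation onset (scaled by `gain`, latency-jittered by
#' `jitter_sd` ms rounded to the EEG sample grid), and adds spatially
#' correlated Gaussian sensor noise.
#'
#' Consumes the current RNG stream; seed upstream for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param fixations List (one per condition) of fixation data frames as
#'   returned by [generate_fixation_sequence()].
#' @param durations_ms Numeric vector of condition durations in ms.
#' @param gain Source amplitude multiplier for this participant.
#' @param jitter_sd Latency jitter SD in ms for this participant.
#' @param mixing `D x n_sources` matrix of unit-norm mixing vectors.
#' @return An [eeg_recording()]; attribute `condition_start_ms` holds the
#'   stimulus-onset time of each condition on the recording clock.
#' @export
generate_subject_eeg <- function(config, fixations, durations_ms, gain,
                                 jitter_sd, mixing) {
  fs <- config$fs_eeg
  D <- config$n_channels
  n_cond <- length(fixations)
  stopifnot(length(durations_ms) == n_cond)
  start_ms <- numeric(n_cond)
  t_cursor <- .SIM_PREROLL_MS
  for (cnd in seq_len(n_cond)) {
    start_ms[cnd] <- t_cursor
    t_cursor <- t_cursor + durations_ms[cnd] + .SIM_GAP_MS
  }
  total_ms <- t_cursor - .SIM_GAP_MS + .SIM_TAIL_MS
  n_samp <- ceiling(total_ms / 1000 * fs)

  # spatially correlated, temporally white noise
  if (config$noise_sd > 0) {
    r <- config$noise_spatial_corr
    Z <- matrix(stats::rnorm(D * n_samp), D, n_samp)
    common <- stats::rnorm(n_samp)
    data <- config$noise_sd *
      (sqrt(1 - r) * Z + sqrt(r) * matrix(common, D, n_samp, byrow = TRUE))
  } else {
    data <- matrix(0, D, n_samp)
  }

  pp <- planted_pattern(config, mixing)
  P <- gain * pp$pattern
  k <- pp$k
  events <- NULL
  for (cnd in seq_len(n_cond)) {
    fix <- fixations[[cnd]]
    onset_abs <- start_ms[cnd] + fix$onset_ms
    onset_samp <- round(onset_abs / 1000 * fs) + 1L
    if (any(onset_samp < 1 | onset_samp > n_samp))
      stop("fixation onsets must fall within the recording span")
    jit <- round(stats::rnorm(length(onset_samp), 0, jitter_sd) / 1000 * fs)
    for (f in seq_along(onset_samp)) {
      cols <- onset_samp[f] + jit[f] + k
      ok <- cols >= 1 & cols <= n_samp
      if (any(ok))
        data[, cols[ok]] <- data[, cols[ok]] + P[, ok, drop = FALSE]
    }
    events <- rbind(events, data.frame(
      sample = c(round(start_ms[cnd] / 1000 * fs) + 1L,
                 round((start_ms[cnd] + durations_ms[cnd]) / 1000 * fs) + 1L),
      code = c(condition_start_code(cnd), condition_end_code(cnd))
    ))
  }
  rec <- eeg_recording(data, fs, events = events)
  attr(rec, "condition_start_ms") <- start_ms
  rec
}

#' Generate a full synthetic cohort
#'
#' Draws `2 * n_per_group` participants (CAC then DYS; grades 3 and 6
#' alternating within group), a fixation sequence and condition segment
#' per participant and condition, and continuous EEG with the planted
#' congruent sources. Fully reproducible from `config$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return Object of class `rrnc_cohort`: a list with `recordings`
#'   (per participant), `fixations` (per participant, absolute
#'   `onset_ms` on the shared recording clock plus `condition` column),
#'   `manifest` (participant, group, grade), `truth` (planted mixing
#'   vectors, waveforms and labels), and `config`.
#' @export
generate_cohort <- function(config) {
  with_local_seed(config$seed, {
    D <- config$n_channels
    n_src <- length(config$source_waveforms)
    mixing <- config$mixing_vectors
    if (is.null(mixing)) {
      M <- matrix(stats::rnorm(D * n_src), D, n_src)
      mixing <- qr.Q(qr(M))[, seq_len(n_src), drop = FALSE]
      # fix signs for reproducible orientation
      for (s in seq_len(n_src)) {
        i <- which.max(abs(mixing[, s]))
        if (mixing[i, s] < 0) mixing[, s] <- -mixing[, s]
      }
    }
    n_total <- 2L * config$n_per_group
    group <- rep(c("CAC", "DYS"), each = config$n_per_group)
    grade <- rep_len(c("3", "6"), config$n_per_group)
    grade <- c(grade, grade)
    participant <- sprintf("P%02d", seq_len(n_total))
    mean_dur <- config$letters_per_matrix * config$mean_ifi

    recordings <- vector("list", n_total)
    fixlogs <- vector("list", n_total)
    for (p in seq_len(n_total)) {
      durs <- pmax(rgamma_mean_cv(config$n_conditions, mean_dur,
                                  config$duration_cv),
                   2 * config$mean_ifi + 1)
      fixs <- lapply(durs, function(d) generate_fixation_sequence(config, d))
      gain <- config$congruency_gain[[group[p]]] *
        config$grade_gain[[grade[p]]]
      jit <- config$latency_jitter_sd[[group[p]]]
      rec <- generate_subject_eeg(config, fixs, durs, gain, jit, mixing)
      start_ms <- attr(rec, "condition_start_ms")
      log <- do.call(rbind, lapply(seq_along(fixs), function(cnd) {
        f <- fixs[[cnd]]
        data.frame(onset_ms = start_ms[cnd] + f$onset_ms,
                   duration_ms = f$duration_ms,
                   x = f$x, y = f$y, condition = cnd)
      }))
      recordings[[p]] <- rec
      fixlogs[[p]] <- log
    }
    kk <- epoch_window_indices(config$fs_eeg)
    pp <- planted_pattern(config, mixing)
    structure(
      list(
        recordings = stats::setNames(recordings, participant),
        fixations = stats::setNames(fixlogs, participant),
        manifest = data.frame(participant = participant, group = group,
                              grade = grade, stringsAsFactors = FALSE),
        truth = list(mixing_vectors = mixing,
                     waveform_pattern = pp$pattern,
                     epoch_k = kk$k,
                     group_labels = group, grade_labels = grade),
        config = config
      ),
      class = "rrnc_cohort"
    )
  })
}

#' @export
print.rrnc_cohort <- function(x, ...) {
  cat(sprintf("<rrnc_cohort> %d participants (%d CAC / %d DYS), %d channels, %d conditions\n",
              nrow(x$manifest), sum(x$manifest$group == "CAC"),
              sum(x$manifest$group == "DYS"), x$config$n_channels,
              x$config$n_conditions))
  invisible(x)
}
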