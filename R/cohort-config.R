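#' Default planted source waveforms
#'
#' Three fixation-locked components loosely patterned on the visual
#' evoked response sequence seen in letter-string reading: an early
#' posterior positivity near 100 ms, a letter-string negativity near
#' 170 ms, and a broader late positivity near 300 ms.
#'
#' @return A list of waveform descriptors, each with `latency_ms`,
#'   `width_ms` (Gaussian SD) and `amplitude_uv`.
#' @export
default_source_waveforms <- function() {
  list(
    list(latency_ms = 100, width_ms = 30, amplitude_uv = 4),
    list(latency_ms = 170, width_ms = 40, amplitude_uv = -3),
    list(latency_ms = 300, width_ms = 60, amplitude_uv = 2)
  )
}

#' Configuration for a synthetic co-registered EEG / eye-tracking cohort
#'
#' Describes a two-group (DYS / CAC), two-grade (3 / 6) cohort performing
#' a serial letter-matrix naming task. Each participant contributes one
#' continuous multichannel EEG recording containing `n_conditions`
#' stimulus segments, plus a fixation log sampled on the eye-tracker
#' clock. A set of fixation-locked source waveforms, shared across
#' participants through fixed spatial mixing vectors, is planted at every
#' fixation onset; group membership controls the source gain
#' (`congruency_gain`) and the fixation-to-response latency jitter
#' (`latency_jitter_sd`), which together determine how congruent a
#' participant's evoked activity is with the rest of the cohort.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param n_channels Number of EEG channels `D`.
#' @param fs_eeg EEG sampling rate in Hz.
#' @param fs_eye Eye-tracker sampling rate in Hz.
#' @param n_conditions Number of stimulus conditions (letter matrices).
#' @param letters_per_matrix Letters per matrix stimulus; with one
#'   fixation per letter this sets the expected fixation count per
#'   condition (the task uses five rows by ten columns, i.e. 50).
#' @param mean_ifi Mean inter-fixation interval in ms.
#' @param ifi_cv Coefficient of variation of the inter-fixation interval
#'   (0 gives a deterministic fixation train).
#' @param source_waveforms List of waveform descriptors as returned by
#'   [default_source_waveforms()].
#' @param mixing_vectors Optional `D x n_sources` matrix of unit-norm
#'   spatial mixing vectors (one column per source). Drawn once from the
#'   cohort seed when `NULL`.
#' @param congruency_gain Named numeric vector `c(CAC = , DYS = )`
#'   multiplying the planted source amplitude per group.
#' @param latency_jitter_sd Named numeric vector `c(CAC = , DYS = )`:
#'   SD in ms of the i.i.d. Gaussian jitter between fixation onset and
#'   evoked-response onset, rounded to the EEG sample grid.
#' @param grade_gain Named numeric vector `c("3" = , "6" = )`
#'   additionally multiplying source amplitude per grade (default: no
#'   grade effect).
#' @param noise_sd Sensor noise SD in microvolt.
#' @param noise_spatial_corr Exchangeable spatial correlation of the
#'   noise across channels, in `[0, 1)`.
#' @param duration_cv Coefficient of variation of per-participant
#'   condition durations around `letters_per_matrix * mean_ifi`.
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group,
                          n_channels = 64,
                          fs_eeg = 256,
                          fs_eye = 1000,
                          n_conditions = 4,
                          letters_per_matrix = 50,
                          mean_ifi = 350,
                          ifi_cv = 0.3,
                          source_waveforms = default_source_waveforms(),
                          mixing_vectors = NULL,
                          congruency_gain = c(CAC = 1, DYS = 1),
                          latency_jitter_sd = c(CAC = 12, DYS = 12),
                          grade_gain = c("3" = 1, "6" = 1),
                          noise_sd = 5,
                          noise_spatial_corr = 0.3,
                          duration_cv = 0.15,
                          seed = 1L) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (fs_eeg <= 0 || fs_eye <= 0) stop("sampling rates must be positive")
  if (mean_ifi <= 0) stop("mean_ifi must be positive")
  if (ifi_cv < 0) stop("ifi_cv must be >= 0")
  for (nm in c("CAC", "DYS")) {
    if (is.na(congruency_gain[nm])) stop("congruency_gain needs names CAC and DYS")
    if (is.na(latency_jitter_sd[nm])) stop("latency_jitter_sd needs names CAC and DYS")
  }
  if (any(congruency_gain < 0)) stop("congruency_gain must be >= 0")
  if (any(latency_jitter_sd < 0)) stop("latency_jitter_sd must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_spatial_corr < 0 || noise_spatial_corr >= 1)
    stop("noise_spatial_corr must lie in [0, 1)")
  if (!is.null(mixing_vectors)) {
    mixing_vectors <- as.matrix(mixing_vectors)
    if (nrow(mixing_vectors) != n_channels)
      stop("mixing_vectors must have n_channels rows")
    if (ncol(mixing_vectors) != length(source_waveforms))
      stop("need one mixing vector per source waveform")
    nrm <- sqrt(colSums(mixing_vectors^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("mixing vectors must have unit norm")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_channels = as.integer(n_channels),
      fs_eeg = fs_eeg,
      fs_eye = fs_eye,
      n_conditions = as.integer(n_conditions),
      letters_per_matrix = as.integer(letters_per_matrix),
      mean_ifi = mean_ifi,
      ifi_cv = ifi_cv,
      source_waveforms = source_waveforms,
      mixing_vectors = mixing_vectors,
      congruency_gain = congruency_gain,
      latency_jitter_sd = latency_jitter_sd,
      grade_gain = grade_gain,
      noise_sd = noise_sd,
      noise_spatial_corr = noise_spatial_corr,
      duration_cv = duration_cv,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
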