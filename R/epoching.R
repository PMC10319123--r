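# Single-trial fixation-related potentials (sFRPs): epoch condition
# segments around fixation onsets and concatenate epochs into the
# per-participant data matrix used by the congruency core.

#' Epoch sample grid for the fixation window
#'
#' The fixation-locked window spans \[-200, 500) ms under a half-open
#' convention: sample offsets `k` with `-0.2 * fs <= k < 0.5 * fs`,
#' giving an unambiguous integer count at any sampling rate (179 samples
#' at 256 Hz). The baseline sub-window is `-0.2 * fs <= k < 0`.
#'
#' @param fs Sampling rate in Hz.
#' @param tmin,tmax Window bounds in seconds.
#' @return List with integer vectors `k` (all offsets) and `baseline`
#'   (offsets in the baseline window).
#' @export
epoch_window_indices <- function(fs, tmin = -0.2, tmax = 0.5) {
  k <- seq.int(ceiling(tmin * fs), ceiling(tmax * fs) - 1L)
  list(k = k, baseline = k[k < 0])
}

#' Epoch a condition segment at fixation onsets
#'
#' Cuts one epoch per fixation whose full \[-200, 500) ms window lies
#' inside the segment; fixation onsets are mapped to the nearest EEG
#' sample. Each epoch is baseline-corrected by its own per-channel mean
#' over \[-200, 0) ms. Boundary-violating fixations are dropped and
#' counted in attribute `n_dropped`.
#'
#' @param seg A `condition_segment` from [extract_condition_segments()].
#' @param fixations Aligned fixation data frame (onsets in ms relative
#'   to the segment's stimulus onset); rows of other conditions are
#'   ignored if a `condition` column is present.
#' @return An object of class `frp_set`: fields `epochs`
#'   (`D x T x F` array), `fs`, `k` (sample offsets), `participant`,
#'   `condition`.
#' @export
epoch_at_fixations <- function(seg, fixations) {
  stopifnot(inherits(seg, "condition_segment"))
  if (!is.null(fixations$condition))
    fixations <- fixations[fixations$condition == seg$condition, , drop = FALSE]
  grid <- epoch_window_indices(seg$fs)
  k <- grid$k
  Tn <- length(k)
  D <- nrow(seg$data)
  if (nrow(fixations) == 0) {
    warning(sprintf("no fixations to epoch (condition %s)", seg$condition))
    return(structure(list(epochs = array(0, c(D, Tn, 0)), fs = seg$fs,
                          k = k, participant = seg$participant,
                          condition = seg$condition),
                     class = "frp_set"))
  }
  onset_samp <- seg$stimulus_onset_sample +
    round(fixations$onset_ms / 1000 * seg$fs)
  ok <- onset_samp + k[1] >= 1 & onset_samp + k[Tn] <= ncol(seg$data)
  n_dropped <- sum(!ok)
  onset_samp <- onset_samp[ok]
  Fn <- length(onset_samp)
  epochs <- array(0, c(D, Tn, Fn))
  bsel <- which(k < 0)
  for (f in seq_len(Fn)) {
    ep <- seg$data[, onset_samp[f] + k, drop = FALSE]
    epochs[, , f] <- ep - rowMeans(ep[, bsel, drop = FALSE])
  }
  structure(list(epochs = epochs, fs = seg$fs, k = k,
                 participant = seg$participant, condition = seg$condition,
                 n_dropped = n_dropped),
            class = "frp_set")
}

#' Concatenate epochs into the participant data matrix
#'
#' Horizontally concatenates the first `f_common` epochs (fixation
#' order, within-epoch time order preserved) into the `D x (T * f_common)`
#' matrix on which all cross-covariances are computed.
#'
#' @param frps An `frp_set`.
#' @param f_common Number of epochs to keep; defaults to all.
#' @return Matrix `D x (T * f_common)` with attributes `T`, `F_used`,
#'   `participant`, `condition`.
#' @export
concatenate_epochs <- function(frps, f_common = dim(frps$epochs)[3]) {
  stopifnot(inherits(frps, "frp_set"))
  Fn <- dim(frps$epochs)[3]
  if (f_common < 1 || f_common > Fn)
    stop(sprintf("f_common = %d outside [1, %d] (participant %s, condition %s)",
                 f_common, Fn, frps$participant, frps$condition))
  D <- dim(frps$epochs)[1]
  Tn <- dim(frps$epochs)[2]
  X <- matrix(frps$epochs[, , seq_len(f_common)], D, Tn * f_common)
  attr(X, "T") <- Tn
  attr(X, "F_used") <- as.integer(f_common)
  attr(X, "participant") <- frps$participant
  attr(X, "condition") <- frps$condition
  X
}

#' Group-wide common fixation count
#'
#' Cross-participant covariances require equal column counts; every
#' participant is truncated to the minimum epoch count over the list
#' (keeping the earliest epochs).
#'
#' @param frp_sets Non-empty list of `frp_set` objects (one condition).
#' @return The minimum epoch count.
#' @export
common_fixation_count <- function(frp_sets) {
  if (length(frp_sets) == 0) stop("empty list of FRP sets")
  counts <- vapply(frp_sets, function(f) dim(f$epochs)[3], integer(1))
  if (any(counts == 0)) {
    who <- vapply(frp_sets[counts == 0], function(f)
      as.character(f$participant %||% "?"), character(1))
    stop(sprintf("participant(s) with zero epochs: %s",
                 paste(who, collapse = ", ")))
  }
  min(counts)
}
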