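# EEG preprocessing chain: average reference, 0.5 Hz high-pass,
# power-line notches, condition segmentation with baseline subtraction,
# and fixation-log alignment to condition onsets.

# Zero-phase filter of every channel (rows) of a D x N matrix.
filtfilt_rows <- function(filt, data) {
  t(apply(data, 1, function(x) signal::filtfilt(filt, x)))
}

#' Preprocess a continuous EEG recording
#'
#' Applies, in order: re-referencing to the average channel, a zero-phase
#' fourth-order Butterworth high-pass at `hp_cutoff` (realized as two
#' cascaded second-order sections for numerical stability at near-DC
#' cutoffs), and zero-phase Butterworth band-stop notches (2 Hz wide) at
#' each of `notch_freqs`. Zero-phase application preserves fixation-
#' related potential latencies. Sample count is unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param hp_cutoff High-pass cutoff in Hz.
#' @param notch_freqs Numeric vector of notch center frequencies in Hz;
#'   all must lie below the Nyquist frequency.
#' @return The filtered [eeg_recording()]; every sample's channel mean
#'   is zero.
#' @export
preprocess_recording <- function(rec, hp_cutoff = 0.5,
                                 notch_freqs = c(50, 100)) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (length(notch_freqs) && max(notch_freqs) >= nyq)
    stop("notch frequency at or above the Nyquist frequency")
  if (hp_cutoff <= 0 || hp_cutoff >= nyq)
    stop("hp_cutoff must lie in (0, Nyquist)")
  data <- rec$data
  # average reference: remove the instantaneous channel mean
  data <- sweep(data, 2, colMeans(data))
  # remove each channel's DC exactly before filtering; this is part of
  # the high-pass's job and avoids long filter edge transients
  data <- data - rowMeans(data)
  # 4th-order high-pass as two cascaded 2nd-order sections
  hp <- signal::butter(2, hp_cutoff / nyq, type = "high")
  data <- filtfilt_rows(hp, data)
  data <- filtfilt_rows(hp, data)
  for (f0 in notch_freqs) {
    bs <- signal::butter(2, c(f0 - 1, f0 + 1) / nyq, type = "stop")
    data <- filtfilt_rows(bs, data)
  }
  out <- rec
  out$data <- data
  out
}

#' Condition segment
#'
#' A contiguous slice of a preprocessed recording covering one condition,
#' spanning from 2 s before the stimulus onset to 2 s after the trial
#' conclusion (clipped to the recording bounds), baseline-corrected by
#' the per-channel mean of the \[-200, 0) ms window relative to stimulus
#' onset.
#'
#' @param rec A (typically preprocessed) [eeg_recording()].
#' @param pad Padding in seconds on either side of the condition window.
#' @param participant Optional participant id carried on the segments.
#' @return A list of `condition_segment` objects, one per condition,
#'   each with fields `data`, `fs`, `stimulus_onset_sample` (1-based
#'   index within the segment), `condition`, `participant`.
#' @export
extract_condition_segments <- function(rec, pad = 2.0, participant = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  conds <- sort(unique(ev$code[ev$code > 100 & ev$code <= 200] - 100L))
  if (length(conds) == 0) stop("no condition start markers in the recording")
  lapply(conds, function(cnd) {
    start <- ev$sample[ev$code == condition_start_code(cnd)]
    end <- ev$sample[ev$code == condition_end_code(cnd)]
    if (length(start) != 1)
      stop(sprintf("condition %d: missing or duplicated start marker", cnd))
    if (length(end) != 1)
      stop(sprintf("condition %d: missing or duplicated end marker", cnd))
    pad_n <- round(pad * rec$fs)
    lo <- max(1L, start - pad_n)
    hi <- min(ncol(rec$data), end + pad_n)
    seg <- rec$data[, lo:hi, drop = FALSE]
    onset <- start - lo + 1L
    k <- epoch_window_indices(rec$fs)
    bl_cols <- onset + k$baseline
    bl_cols <- bl_cols[bl_cols >= 1 & bl_cols <= ncol(seg)]
    if (length(bl_cols))
      seg <- seg - rowMeans(seg[, bl_cols, drop = FALSE])
    structure(
      list(data = seg, fs = rec$fs, stimulus_onset_sample = onset,
           condition = cnd, participant = participant),
      class = "condition_segment"
    )
  })
}

#' Align a fixation log to condition windows
#'
#' Assigns each fixation to the condition whose `[start_ms, end_ms]`
#' window contains its absolute timestamp, then re-expresses its onset
#' relative to that condition's stimulus onset. Fixations falling outside
#' every window are dropped; the count of dropped rows is attached as
#' attribute `n_excluded`.
#'
#' @param fixations Data frame with columns `onset_ms` (absolute clock),
#'   `duration_ms`, `x`, `y`.
#' @param windows Condition-window table as from [condition_windows()].
#' @return Data frame with columns `onset_ms` (relative to stimulus
#'   onset), `duration_ms`, `x`, `y`, `condition`.
#' @export
align_fixations <- function(fixations, windows) {
  if (nrow(fixations) == 0) {
    warning("empty fixation log")
    out <- data.frame(onset_ms = numeric(), duration_ms = numeric(),
                      x = numeric(), y = numeric(), condition = integer())
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  cond <- rep(NA_integer_, nrow(fixations))
  rel <- rep(NA_real_, nrow(fixations))
  for (i in seq_len(nrow(windows))) {
    hit <- fixations$onset_ms >= windows$start_ms[i] &
      fixations$onset_ms <= windows$end_ms[i]
    cond[hit] <- windows$condition[i]
    rel[hit] <- fixations$onset_ms[hit] - windows$start_ms[i]
  }
  keep <- !is.na(cond)
  out <- data.frame(onset_ms = rel[keep],
                    duration_ms = fixations$duration_ms[keep],
                    x = fixations$x[keep], y = fixations$y[keep],
                    condition = cond[keep])
  out <- out[order(out$condition, out$onset_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Load a fixation log CSV and align it to condition windows
#'
#' Reads a fixation CSV (columns `onset_ms`, `duration_ms`, `x`, `y`;
#' absolute timestamps on the clock shared with the EEG event markers)
#' and aligns it with [align_fixations()].
#'
#' @param path Path to the CSV file.
#' @param windows Condition-window table as from [condition_windows()].
#' @return As [align_fixations()].
#' @export
load_fixations <- function(path, windows) {
  if (!file.exists(path)) stop(sprintf("fixation log not found: %s", path))
  fx <- utils::read.csv(path)
  need <- c("onset_ms", "duration_ms", "x", "y")
  missing_cols <- setdiff(need, names(fx))
  if (length(missing_cols))
    stop(sprintf("fixation log %s lacks columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  bad <- which(!is.finite(fx$onset_ms) | !is.finite(fx$duration_ms) |
                 fx$duration_ms <= 0)
  if (length(bad))
    stop(sprintf("fixation log %s: unparseable or invalid row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  align_fixations(fx, windows)
}
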