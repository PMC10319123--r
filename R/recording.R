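#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous EEG recording: a channels-by-
#' samples matrix in microvolt, the sampling rate, channel names, and an
#' event table of `(sample, code)` marker rows. Condition `k` is delimited
#' by a start marker (stimulus onset, code `100 + k`) and an end marker
#' (trial conclusion, code `200 + k`).
#'
#' @param data Numeric matrix, channels x samples (microvolt).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel names (defaults to
#'   `CH01`, `CH02`, ...).
#' @param events Data frame with integer columns `sample` (1-based) and
#'   `code`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          events = data.frame(sample = integer(), code = integer())) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("CH%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the channel dimension")
  events <- as.data.frame(events)
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices must lie within the recording")
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         events = events[order(events$sample), , drop = FALSE]),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

condition_start_code <- function(condition) 100L + as.integer(condition)
condition_end_code <- function(condition) 200L + as.integer(condition)

#' Condition windows of a recording
#'
#' Reads the event table and returns, per condition, the stimulus-onset
#' and trial-end times in ms on the recording clock.
#'
#' @param rec An [eeg_recording()].
#' @return Data frame with columns `condition`, `start_ms`, `end_ms`,
#'   `start_sample`, `end_sample`.
#' @export
condition_windows <- function(rec) {
  ev <- rec$events
  starts <- ev[ev$code > 100 & ev$code <= 200, , drop = FALSE]
  out <- lapply(seq_len(nrow(starts)), function(i) {
    cond <- starts$code[i] - 100L
    end <- ev$sample[ev$code == condition_end_code(cond)]
    if (length(end) != 1)
      stop(sprintf("condition %d: expected one end marker, found %d",
                   cond, length(end)))
    data.frame(condition = cond,
               start_ms = (starts$sample[i] - 1) / rec$fs * 1000,
               end_ms = (end - 1) / rec$fs * 1000,
               start_sample = starts$sample[i],
               end_sample = end)
  })
  do.call(rbind, out)
}
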