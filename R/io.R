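# Portable on-disk container for recordings and fixation logs:
# a little-endian float64 array plus a JSON sidecar with sampling rate,
# channel names, dimensions and the event table; fixation logs as CSV.

#' Write a recording to the portable container
#'
#' Writes `<prefix>.dat` (channels x samples, column-major little-endian
#' float64) and `<prefix>.json` (sampling rate, channel names, dims,
#' event table).
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(
    fs = rec$fs,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    channel_names = rec$channel_names,
    events = rec$events
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording from the portable container
#'
#' @param prefix Path prefix used in [write_recording()].
#' @return An [eeg_recording()].
#' @export
read_recording <- function(prefix) {
  jpath <- paste0(prefix, ".json")
  dpath <- paste0(prefix, ".dat")
  if (!file.exists(jpath) || !file.exists(dpath))
    stop(sprintf("recording container not found at prefix %s", prefix))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  con <- file(dpath, "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  vals <- readBin(con, what = "numeric", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    stop(sprintf("recording %s: expected %d samples, read %d",
                 prefix, n, length(vals)))
  ev <- as.data.frame(meta$events)
  if (nrow(ev) == 0) ev <- data.frame(sample = integer(), code = integer())
  eeg_recording(matrix(vals, meta$n_channels, meta$n_samples),
                fs = meta$fs, channel_names = meta$channel_names,
                events = ev)
}

#' Write a fixation log CSV
#'
#' @param fixations Data frame with columns `onset_ms`, `duration_ms`,
#'   `x`, `y` and optionally `condition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  utils::write.csv(fixations, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One recording container and one fixation CSV per participant, plus
#' `manifest.csv` (participant, group, grade).
#'
#' @param cohort An `rrnc_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rrnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$manifest$participant) {
    write_recording(cohort$recordings[[p]], file.path(dir, p))
    write_fixations(cohort$fixations[[p]],
                    file.path(dir, paste0(p, "_fixations.csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `recordings`, `fixations` and `manifest`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop(sprintf("no manifest.csv in %s", dir))
  manifest <- utils::read.csv(mpath, colClasses = c(grade = "character"))
  recs <- lapply(manifest$participant, function(p)
    read_recording(file.path(dir, p)))
  fixs <- lapply(manifest$participant, function(p) {
    fp <- file.path(dir, paste0(p, "_fixations.csv"))
    if (!file.exists(fp)) stop(sprintf("missing fixation log for %s", p))
    utils::read.csv(fp)
  })
  list(recordings = stats::setNames(recs, manifest$participant),
       fixations = stats::setNames(fixs, manifest$participant),
       manifest = manifest)
}
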