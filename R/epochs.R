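#' Construct an EEG epoch set
#'
#' Bundles raw per-trial multichannel signals with their montage, sampling
#' rate and per-trial metadata. Signals are held as a 3-d numeric array
#' (trials x channels x samples); trial metadata is a tibble with one row per
#' trial carrying at least `subject_id`, `database_id`, `valence` and
#' `arousal` (self-ratings on the 1-9 scale).
#'
#' @param signals Numeric array, trials x channels x samples.
#' @param channels Character vector of channel names (length = dim 2).
#' @param fs Sampling rate in Hz.
#' @param trial_meta Data frame with one row per trial.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(signals, channels, fs, trial_meta) {
  if (!is.array(signals) || length(dim(signals)) != 3) {
    stop("`signals` must be a 3-d array (trials x channels x samples).",
         call. = FALSE)
  }
  channels <- canonical_channels(channels)
  if (dim(signals)[2] != length(channels)) {
    stop("Channel dimension (", dim(signals)[2], ") does not match the ",
         length(channels), " channel names supplied.", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz.", call. = FALSE)
  }
  trial_meta <- tibble::as_tibble(trial_meta)
  if (nrow(trial_meta) != dim(signals)[1]) {
    stop("`trial_meta` has ", nrow(trial_meta), " rows but `signals` has ",
         dim(signals)[1], " trials.", call. = FALSE)
  }
  structure(
    list(signals = signals, channels = channels, fs = fs,
         trial_meta = trial_meta),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  subjects:", length(unique(x$trial_meta$subject_id)),
      " databases:", paste(unique(x$trial_meta$database_id), collapse = ", "),
      "\n")
  invisible(x)
}

#' Restrict an epoch set to a channel set
#'
#' Returns the epochs restricted to the requested channels, reordered to
#' follow the channel-set order. Trial metadata is untouched. Selecting the
#' same set twice is the same as selecting it once.
#'
#' @param epochs An [eeg_epochs] object.
#' @param channels A [channel_set] (or character vector of channel names).
#' @return An `eeg_epochs` object with only the requested channels.
#' @export
select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  wanted <- canonical_channels(as.character(channels))
  idx <- match(wanted, epochs$channels)
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop("Channel(s) not present in the epoch set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- epochs
  out$signals <- epochs$signals[, idx, , drop = FALSE]
  out$channels <- epochs$channels[idx]
  out
}
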