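#' The five analysis frequency bands
#'
#' Theta (4-8 Hz), slow alpha (8-10 Hz), alpha (8-12 Hz), beta (12-30 Hz) and
#' gamma (above 30 Hz). Slow alpha deliberately overlaps alpha: both are kept
#' as distinct features. Gamma is open-ended above 30 Hz; [band_edges()] caps
#' it below the Nyquist frequency.
#'
#' @format Named list of `c(low, high)` pairs in Hz; gamma's high edge is
#'   `NA` (resolved per sampling rate).
#' @export
eeg_bands <- list(
  theta      = c(4, 8),
  slow_alpha = c(8, 10),
  alpha      = c(8, 12),
  beta       = c(12, 30),
  gamma      = c(30, NA)
)

#' Resolve a band name to concrete edges at a sampling rate
#'
#' Gamma has no fixed upper edge; it is capped at `min(45, 0.45 * fs)` Hz to
#' stay clear of mains interference and the Nyquist limit.
#'
#' @param name One of `"theta"`, `"slow_alpha"`, `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @param fs Sampling rate in Hz (must exceed 60 Hz so gamma is meaningful).
#' @return A `band_spec`: list with `name`, `low_hz`, `high_hz`.
#' @examples
#' band_edges("theta", 256)
#' band_edges("gamma", 128) # capped at 45 Hz
#' @export
band_edges <- function(name, fs) {
  if (!name %in% names(eeg_bands)) {
    stop("Unknown band ", deparse(name), "; valid bands are: ",
         paste(names(eeg_bands), collapse = ", "), call. = FALSE)
  }
  if (fs <= 60) {
    stop("Sampling rate must exceed 60 Hz for the gamma band to be defined.",
         call. = FALSE)
  }
  edges <- eeg_bands[[name]]
  high <- if (is.na(edges[2])) min(45, 0.45 * fs) else edges[2]
  band_spec(name, edges[1], high)
}

#' @rdname band_edges
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @export
band_spec <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("Band edges must satisfy 0 < low < high.", call. = FALSE)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

# Zero-phase Butterworth band-pass, realised as a 5th-order high-pass
# followed by a 5th-order low-pass, each run forward-backward. The cascade
# form keeps the recursion stable for narrow low-frequency bands at high
# sampling rates, where a single transfer-function band-pass of the same
# order is not.
band_filter <- function(x, band, fs) {
  nyq <- fs / 2
  if (band$low_hz >= nyq) {
    stop("Band ", band$name, " (", band$low_hz, "-", band$high_hz,
         " Hz) lies entirely above the Nyquist frequency ", nyq, " Hz.",
         call. = FALSE)
  }
  high <- min(band$high_hz, 0.99 * nyq)
  hp <- signal::butter(5, band$low_hz / nyq, type = "high")
  lp <- signal::butter(5, high / nyq, type = "low")
  x <- as.numeric(x)
  x <- x - mean(x) # avoid forward-backward edge transients from DC offsets
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Differential entropy of a band-filtered epoch
#'
#' Under a Gaussian assumption the differential entropy of a signal with
#' variance `s2` is `0.5 * log(2 * pi * e * s2)` nats; this is computed on
#' the band-filtered epoch. With `band = NULL` the signal is used broadband
#' (no filtering). DE is invariant to the signal mean, and scaling the
#' signal by `c` adds `log(abs(c))`.
#'
#' @param x Numeric vector: one channel of one epoch (at least 1 s long).
#' @param band A [band_spec], or `NULL` for broadband.
#' @param fs Sampling rate in Hz.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x, band = NULL, fs = NULL) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("Signal contains non-finite values.",
                               call. = FALSE)
  if (!is.null(band)) {
    if (is.null(fs)) stop("`fs` is required when filtering by band.",
                          call. = FALSE)
    if (length(x) < fs) {
      stop("Epoch shorter than 1 s; too short for band features.",
           call. = FALSE)
    }
    x <- band_filter(x, band, fs)
  }
  s2 <- stats::var(x)
  if (!is.finite(s2) || s2 <= 0) {
    stop("Degenerate (zero-variance) signal: differential entropy undefined.",
         call. = FALSE)
  }
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Welch power spectral density
#'
#' One-sided Welch estimate with Hann windows of `window_sec` seconds and
#' 50\% overlap, density-scaled so that the integral over frequency equals
#' the signal power.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds (default 1).
#' @return A tibble with columns `freq` (Hz) and `power` (units^2 / Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 1) {
  x <- as.numeric(x)
  nwin <- round(fs * window_sec)
  if (length(x) < 1.5 * nwin) {
    stop("Signal too short for Welch estimation: need at least two ",
         "half-overlapping ", window_sec, " s windows.", call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  step <- max(1, floor(nwin / 2))
  starts <- seq(1, length(x) - nwin + 1, by = step)
  nfreq <- floor(nwin / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)] * w
    spec <- abs(stats::fft(seg))^2 / (fs * sum(w^2))
    acc <- acc + spec[seq_len(nfreq)]
  }
  p <- acc / length(starts)
  # one-sided: double all interior bins
  interior <- 2:(nfreq - 1 + nwin %% 2)
  p[interior] <- 2 * p[interior]
  tibble::tibble(freq = seq(0, nfreq - 1) * fs / nwin, power = p)
}

#' Mean band power from a Welch spectrum
#'
#' Mean Welch power density over the frequency bins in `[low, high)`;
#' strictly positive for any non-constant input.
#'
#' @inheritParams differential_entropy
#' @param band A [band_spec].
#' @return Mean power density in the band (units^2 / Hz).
#' @export
band_psd <- function(x, band, fs) {
  nyq <- fs / 2
  if (band$low_hz >= nyq) {
    stop("Band ", band$name, " lies entirely above the Nyquist frequency.",
         call. = FALSE)
  }
  spec <- welch_psd(x, fs)
  sel <- spec$freq >= band$low_hz & spec$freq < band$high_hz
  if (!any(sel)) {
    stop("No spectral bins fall inside band ", band$name, ".", call. = FALSE)
  }
  mean(spec$power[sel])
}

#' Extract DE and PSD band features from an epoch set
#'
#' One feature row per trial, computed over the whole trial. Columns are
#' ordered channel-major following the channel-set order; within each channel
#' the five DE features (band order theta, slow_alpha, alpha, beta, gamma)
#' precede the five PSD features. The dimension contract is
#' `m = 10 * n_channels`: 320 features for the full montage, 120 for the
#' auditory set, 50 for the visual set.
#'
#' @param epochs An [eeg_epochs] object.
#' @param channels A [channel_set]; defaults to the full montage.
#' @return A raw (unnormalized) [feature_table].
#' @export
extract_features <- function(epochs, channels = region_channels("all")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sub <- select_channels(epochs, channels)
  fs <- sub$fs
  bands <- lapply(names(eeg_bands), band_edges, fs = fs)
  names(bands) <- names(eeg_bands)
  ntrial <- dim(sub$signals)[1]
  nchan <- length(sub$channels)
  cols <- tidyr::expand_grid(
    channel = sub$channels,
    type = c("DE", "PSD"),
    band = names(eeg_bands)
  )[, c("channel", "band", "type")]
  # enforce DE block before PSD block within channel, bands in canonical order
  cols <- dplyr::arrange(
    cols,
    match(.data$channel, sub$channels),
    match(.data$type, c("DE", "PSD")),
    match(.data$band, names(eeg_bands))
  )
  values <- matrix(NA_real_, nrow = ntrial, ncol = nrow(cols))
  for (tr in seq_len(ntrial)) {
    for (ch in seq_len(nchan)) {
      sig <- sub$signals[tr, ch, ]
      filtered <- lapply(bands, function(b) {
        tryCatch(band_filter(sig, b, fs), error = function(e) {
          stop("Trial ", tr, ", channel ", sub$channels[ch], ": ",
               conditionMessage(e), call. = FALSE)
        })
      })
      spec <- welch_psd(sig, fs) # one spectrum serves all five bands
      base <- (ch - 1) * 10
      for (bi in seq_along(bands)) {
        s2 <- stats::var(filtered[[bi]])
        if (!is.finite(s2) || s2 <= 0) {
          stop("Trial ", tr, ", channel ", sub$channels[ch], ", band ",
               names(bands)[bi], ": degenerate signal.", call. = FALSE)
        }
        values[tr, base + bi] <- 0.5 * log(2 * pi * exp(1) * s2)
        b <- bands[[bi]]
        sel <- spec$freq >= b$low_hz & spec$freq < b$high_hz
        values[tr, base + 5 + bi] <- mean(spec$power[sel])
      }
    }
  }
  feature_table(values, cols, sub$trial_meta, normalized = FALSE)
}

#' Joint min-max normalization of a feature table
#'
#' Rescales each feature column to `[0, 1]` via
#' `(x - min(x)) / (max(x) - min(x))`, with min and max computed per column
#' over all samples jointly passed in. In the transductive protocols this
#' means source and target samples are pooled before scaling. Constant
#' columns map to zero.
#'
#' @param table A raw [feature_table].
#' @return The normalized `feature_table` (flag set).
#' @export
minmax_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized) {
    stop("Feature table is already normalized.", call. = FALSE)
  }
  v <- table$values
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  rng <- hi - lo
  out <- sweep(v, 2, lo, "-")
  nonconst <- rng > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2,
                           rng[nonconst], "/")
  out[, !nonconst] <- 0
  feature_table(out, table$columns, table$sample_meta, normalized = TRUE)
}
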