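# Shared fixture builders; everything is generated in code at test time.

# Tiny raw epoch set: sinusoids plus noise, deterministic under seed.
make_epochs <- function(n_trials = 2, channels = biosemi32_montage,
                        fs = 128, seconds = 2, seed = 42) {
  set.seed(seed)
  nsamp <- fs * seconds
  sig <- array(rnorm(n_trials * length(channels) * nsamp),
               dim = c(n_trials, length(channels), nsamp))
  tt <- seq(0, by = 1 / fs, length.out = nsamp)
  for (i in seq_len(n_trials)) {
    for (ch in seq_along(channels)) {
      sig[i, ch, ] <- sig[i, ch, ] + sin(2 * pi * 10 * tt + ch)
    }
  }
  meta <- tibble::tibble(
    subject_id = rep("s1", n_trials),
    database_id = "test_db",
    valence = rep(c(2, 8), length.out = n_trials),
    arousal = rep(c(8, 2), length.out = n_trials)
  )
  eeg_epochs(sig, channels, fs, meta)
}

# Small feature table with controllable content.
make_table <- function(n = 12, channels = c("O1", "Oz"), seed = 1,
                       n_subjects = 3, normalized = FALSE) {
  set.seed(seed)
  cols <- expand.grid(band = names(eeg_bands), type = c("DE", "PSD"),
                      channel = channels, stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$channel, channels),
                     match(cols$type, c("DE", "PSD")),
                     match(cols$band, names(eeg_bands))),
               c("channel", "band", "type")]
  m <- nrow(cols)
  vals <- matrix(rnorm(n * m), n, m)
  if (normalized) {
    vals <- apply(vals, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  }
  meta <- tibble::tibble(
    subject_id = rep(paste0("s", seq_len(n_subjects)), length.out = n),
    database_id = "db1",
    valence = sample(1:9, n, replace = TRUE),
    arousal = sample(1:9, n, replace = TRUE)
  )
  feature_table(vals, cols, meta, normalized = normalized)
}

# Two-domain fixture with a pure mean shift between domains, columns as
# samples; returns the pieces the adaptation tests need.
make_mean_shift <- function(n_per = 10, m = 6, delta = 3, seed = 7) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(m * n_per), m, n_per),
             matrix(rnorm(m * n_per, mean = delta), m, n_per))
  meta <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = n_per),
    database_id = "db"
  )
  design <- domain_onehot(meta)
  list(X = X, design = design, X_bar = augment_features(X, design))
}

# Random symmetric PSD matrix.
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n
}

# Random matrix with orthonormal columns (QR of a Gaussian draw).
random_orthonormal <- function(n, h) {
  qr.Q(qr(matrix(rnorm(n * h), n, h)))[, seq_len(h), drop = FALSE]
}

# Small covariate-shift study used by the protocol plumbing tests:
# 9 subjects x 12 trials, effect 0.8, subject offsets 1.0.
shift_fixture <- function(seed = 0) {
  generate_feature_dataset("mahnob_small",
                           shift_spec(effect_size = 0.8,
                                      subject_offset_sd = 1.0),
                           seed = seed)
}

# Full-scale covariate-shift study (27 x 20) for the transfer-gain check.
shift_study <- function(seed = 0) {
  generate_feature_dataset("mahnob_like",
                           shift_spec(effect_size = 0.8,
                                      subject_offset_sd = 1.0),
                           seed = seed)
}

# Split-signal study: a weaker per-column effect keeps either region alone
# below ceiling, so combining the two regions' independent evidence helps.
split_study <- function(seed = 0) {
  generate_feature_dataset("mahnob_like",
                           shift_spec(effect_size = 0.45,
                                      subject_offset_sd = 1.0),
                           seed = seed)
}
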