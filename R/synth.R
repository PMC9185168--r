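#' Dataset profiles
#'
#' Shape descriptors for synthetic affective-EEG studies. Two packaged
#' profiles mirror the public benchmark layouts: `mahnob_like` (27 subjects,
#' 20 movie-clip trials each, 32 channels at 256 Hz) and `deap_like`
#' (32 subjects, 40 music-video trials each, 32 channels at 128 Hz).
#'
#' @param name Profile label (becomes the `database_id`).
#' @param n_subjects,n_trials Counts (trials are per subject).
#' @param n_channels Number of electrodes (32 for the packaged profiles).
#' @param fs Sampling rate in Hz.
#' @param trial_seconds Trial duration used when generating raw epochs.
#' @return A `dataset_profile` list.
#' @export
dataset_profile <- function(name, n_subjects, n_trials, n_channels = 32,
                            fs = 256, trial_seconds = 60) {
  stopifnot(n_subjects >= 1, n_trials >= 1, n_channels >= 1, fs > 0,
            trial_seconds > 0)
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 fs = fs, trial_seconds = trial_seconds,
                 rating_scale = c(1, 9)),
            class = "dataset_profile")
}

#' @rdname dataset_profile
#' @param profile Name of a packaged profile (`"mahnob_like"`,
#'   `"deap_like"`) or a scaled-down variant for quick experiments
#'   (`"mahnob_small"`, `"deap_small"`).
#' @export
packaged_profile <- function(profile = c("mahnob_like", "deap_like",
                                         "mahnob_small", "deap_small")) {
  profile <- match.arg(profile)
  switch(profile,
    mahnob_like = dataset_profile("mahnob_like", 27, 20, 32, 256, 60),
    deap_like = dataset_profile("deap_like", 32, 40, 32, 128, 63),
    mahnob_small = dataset_profile("mahnob_small", 9, 12, 32, 256, 60),
    deap_small = dataset_profile("deap_small", 10, 16, 32, 128, 63)
  )
}

#' Covariate-shift specification for the generator
#'
#' Controls how strongly subjects and databases differ, and how much
#' class-related signal is injected into the auditory- and visual-region
#' feature columns. Units: the residual noise standard deviation
#' (`noise_sd`) is the scale unit; `effect_size` is the per-column class
#' mean gap in those units; subject offsets are drawn with standard
#' deviation `subject_offset_sd * noise_sd` and are partially aligned
#' (`shift_align`) with the class-discriminant direction, which is what
#' makes pooled cross-subject training degrade while domain adaptation can
#' recover.
#'
#' @param effect_size Class-mean separation in noise-sd units (region
#'   columns only).
#' @param subject_offset_sd Per-subject additive offset scale.
#' @param subject_scale_sd Log-sd of per-subject multiplicative jitter.
#' @param database_offset Cross-database systematic shift scale.
#' @param noise_sd Residual noise sd (the scale unit).
#' @param shift_align Fraction (0-1) of subject-offset variance aligned
#'   with the discriminant direction.
#' @param column_scale_sd Log-sd of per-column scale heterogeneity (0 means
#'   homogeneous scales).
#' @param label_noise Probability that a trial's ratings contradict its
#'   latent state.
#' @param latent_dim Optional intrinsic dimension: when set, region-column
#'   structure is generated through this many latent factors.
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(effect_size = 0.8, subject_offset_sd = 1.0,
                       subject_scale_sd = 0.1, database_offset = 0.5,
                       noise_sd = 1.0, shift_align = 0.6,
                       column_scale_sd = 0, label_noise = 0.1,
                       latent_dim = NULL) {
  stopifnot(effect_size >= 0, subject_offset_sd >= 0, subject_scale_sd >= 0,
            database_offset >= 0, noise_sd > 0,
            shift_align >= 0, shift_align <= 1,
            column_scale_sd >= 0, label_noise >= 0, label_noise < 1)
  structure(list(effect_size = effect_size,
                 subject_offset_sd = subject_offset_sd,
                 subject_scale_sd = subject_scale_sd,
                 database_offset = database_offset,
                 noise_sd = noise_sd, shift_align = shift_align,
                 column_scale_sd = column_scale_sd,
                 label_noise = label_noise,
                 latent_dim = latent_dim),
            class = "shift_spec")
}

# Column structure shared between databases of one study: which columns are
# class-informative (auditory + visual region channels) and with what sign.
synth_column_structure <- function(n_channels, seed) {
  channels <- biosemi32_montage[seq_len(n_channels)]
  cols <- tidyr::expand_grid(channel = channels,
                             type = c("DE", "PSD"),
                             band = names(eeg_bands))
  cols <- dplyr::arrange(
    cols,
    match(.data$channel, channels),
    match(.data$type, c("DE", "PSD")),
    match(.data$band, names(eeg_bands))
  )[, c("channel", "band", "type")]
  region_map <- montage_regions()
  col_region <- region_map$region[match(cols$channel, region_map$channel)]
  informative <- col_region != "other"
  set.seed(seed + 1000003L)
  signs <- ifelse(stats::runif(nrow(cols)) < 0.5, -1, 1)
  signs[!informative] <- 0
  list(columns = cols, informative = informative, signs = signs,
       col_region = col_region)
}

generate_feature_block <- function(profile, shift, structure, seed,
                                   database_offset_seed = NULL) {
  set.seed(seed)
  S <- profile$n_subjects
  Tn <- profile$n_trials
  n <- S * Tn
  m <- nrow(structure$columns)
  signs <- structure$signs
  sd0 <- shift$noise_sd
  subject_id <- rep(sprintf("s%02d", seq_len(S)), each = Tn)
  # balanced latent emotion state per subject
  state <- as.vector(vapply(seq_len(S), function(s)
    sample(rep(c(0L, 1L), length.out = Tn)), integer(Tn)))
  # per-subject alignment score and residual offsets
  # the discriminant-aligned part of each subject's drift is drawn
  # independently per brain region, so the two regions carry independent
  # residual shift and combining them can average it down
  t_s <- matrix(stats::rnorm(S * 2), S, 2,
                dimnames = list(NULL, c("auditory", "visual")))
  aligned <- matrix(0, S, m)
  for (rg in c("auditory", "visual")) {
    cols_rg <- structure$col_region == rg
    aligned[, cols_rg] <- outer(t_s[, rg], signs[cols_rg])
  }
  E_s <- matrix(stats::rnorm(S * m), S, m)
  a <- shift$shift_align
  offset_subject <- shift$subject_offset_sd * sd0 *
    (a * aligned + sqrt(1 - a^2) * E_s)
  scale_subject <- exp(matrix(stats::rnorm(S * m, sd = shift$subject_scale_sd),
                              S, m))
  db_off <- if (is.null(database_offset_seed)) {
    numeric(m)
  } else {
    set.seed(database_offset_seed)
    out <- shift$database_offset * sd0 * stats::rnorm(m)
    set.seed(seed + 7L)
    out
  }
  gap <- shift$effect_size * sd0 * signs # per-column class mean difference
  si <- match(subject_id, unique(subject_id))
  if (is.null(shift$latent_dim)) {
    mu <- outer(state - 0.5, gap) # n x m class means
    noise <- matrix(stats::rnorm(n * m, sd = sd0), n, m)
    X <- (mu + offset_subject[si, ] + noise) * scale_subject[si, ]
  } else {
    d <- shift$latent_dim
    # class signal and subject shifts live in a d-dimensional factor space
    # mapped onto the informative columns; uninformative columns are noise.
    # The signal is spread evenly over all d factors, so a projection that
    # retains fewer than d components truncates part of it: downstream
    # accuracy rises with the subspace dimension until it reaches d, then
    # plateaus.
    set.seed(seed + 13L)
    B <- matrix(stats::rnorm(m * d, sd = 1 / sqrt(d)), m, d)
    B[!structure$informative, ] <- 0
    # the top quarter of the factors are high-variance, signal-free
    # background activity; the class signal is spread evenly over the
    # remaining lower-variance factors, so low-dimensional projections pick
    # up background first and recover the signal progressively
    q <- ceiling(d / 4)
    factor_sd <- c(rep(2.5 * sd0, q), rep(sd0, d - q))
    beta <- c(rep(0, q),
              sample(c(-1, 1), d - q, replace = TRUE) *
                (3 * shift$effect_size / sqrt(d - q)))
    Fsubj <- matrix(stats::rnorm(S * d, sd = shift$subject_offset_sd * sd0),
                    S, d)
    Fn <- matrix(stats::rnorm(n * d), n, d) %*% diag(factor_sd) +
      outer(state - 0.5, sd0 * beta) + Fsubj[si, ]
    # subject shift is carried by the factors; only thin ambient noise added
    X <- Fn %*% t(B) + matrix(stats::rnorm(n * m, sd = 0.1 * sd0), n, m)
  }
  X <- sweep(X, 2, db_off, "+")
  if (shift$column_scale_sd > 0) {
    set.seed(seed + 29L)
    col_scale <- exp(stats::rnorm(m, sd = shift$column_scale_sd))
    X <- sweep(X, 2, col_scale, "*")
  }
  # state-consistent 1-9 ratings with label noise, per axis
  set.seed(seed + 31L)
  draw_ratings <- function() {
    flip <- stats::runif(n) < shift$label_noise
    eff <- ifelse(flip, 1L - state, state)
    ifelse(eff == 1L, sample(6:9, n, replace = TRUE),
           sample(1:5, n, replace = TRUE))
  }
  meta <- tibble::tibble(
    subject_id = subject_id,
    database_id = profile$name,
    trial = rep(seq_len(Tn), times = S),
    valence = draw_ratings(),
    arousal = draw_ratings(),
    state = state
  )
  feature_table(X, structure$columns, meta, normalized = FALSE)
}

#' Generate a synthetic feature-level dataset
#'
#' Emulates a multi-subject affective-EEG study at the feature level:
#' `n_subjects * n_trials` rows of 10-per-channel (DE + PSD x 5 bands)
#' features with correct provenance. A binary latent emotion state per trial
#' shifts the means of auditory- and visual-region columns only
#' (`effect_size`); each subject receives its own affine distortion; 1-9
#' valence/arousal ratings are drawn consistently with the state up to
#' `label_noise`. The latent state is kept in `sample_meta$state` as ground
#' truth.
#'
#' @param profile A [dataset_profile] or packaged profile name.
#' @param shift A [shift_spec].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A raw [feature_table].
#' @export
generate_feature_dataset <- function(profile = "mahnob_like",
                                     shift = shift_spec(), seed = 0) {
  if (is.character(profile)) profile <- packaged_profile(profile)
  stopifnot(inherits(profile, "dataset_profile"),
            inherits(shift, "shift_spec"))
  structure <- synth_column_structure(profile$n_channels, seed)
  generate_feature_block(profile, shift, structure, seed + 101L)
}

#' Generate a paired cross-database study
#'
#' Two feature tables sharing the same class-signal column structure but
#' with database-specific systematic offsets and independent subject
#' effects — the cross-database transfer setting.
#'
#' @param profile_a,profile_b Profiles (objects or packaged names).
#' @param shift A [shift_spec]; `database_offset` controls the systematic
#'   between-database shift.
#' @param seed Integer seed.
#' @return A list with elements `a` and `b`, both raw [feature_table]s.
#' @export
generate_cross_study <- function(profile_a = "mahnob_like",
                                 profile_b = "deap_like",
                                 shift = shift_spec(), seed = 0) {
  if (is.character(profile_a)) profile_a <- packaged_profile(profile_a)
  if (is.character(profile_b)) profile_b <- packaged_profile(profile_b)
  stopifnot(profile_a$n_channels == profile_b$n_channels)
  structure <- synth_column_structure(profile_a$n_channels, seed)
  list(
    a = generate_feature_block(profile_a, shift, structure, seed + 101L,
                               database_offset_seed = seed + 211L),
    b = generate_feature_block(profile_b, shift, structure, seed + 307L,
                               database_offset_seed = seed + 401L)
  )
}

#' Generate synthetic raw EEG epochs
#'
#' Per trial and channel, the signal is a sum of one band-limited
#' oscillation per analysis band (log-normal amplitudes) plus 1/f-shaped
#' background noise. The latent emotion state modulates the amplitude of
#' `effect_band` multiplicatively (`exp(effect_size * (state - 1/2))`) in
#' auditory- and visual-region channels, so the injected effect is
#' recoverable as a differential-entropy gap of `effect_size` nats after
#' feature extraction. Subjects differ by log-normal amplitude scaling.
#'
#' @param profile A [dataset_profile] or packaged name.
#' @param shift A [shift_spec]; `subject_offset_sd` acts as the per-subject
#'   log-amplitude sd at the signal level.
#' @param seed Integer seed.
#' @param effect_band Band whose amplitude carries the emotion effect
#'   (default `"alpha"`).
#' @param band_amplitudes Named baseline amplitudes per band.
#' @return An [eeg_epochs] object; trial metadata includes ratings and the
#'   latent `state`.
#' @export
generate_raw_epochs <- function(profile = "mahnob_small",
                                shift = shift_spec(), seed = 0,
                                effect_band = "alpha",
                                band_amplitudes = c(theta = 1, slow_alpha = 0.5,
                                                    alpha = 1.5, beta = 0.8,
                                                    gamma = 0.4)) {
  if (is.character(profile)) profile <- packaged_profile(profile)
  stopifnot(effect_band %in% names(eeg_bands))
  set.seed(seed)
  fs <- profile$fs
  nsamp <- round(fs * profile$trial_seconds)
  if (nsamp < 2 * fs) stop("Trials must be at least 2 s long.",
                           call. = FALSE)
  S <- profile$n_subjects
  Tn <- profile$n_trials
  n <- S * Tn
  channels <- biosemi32_montage[seq_len(profile$n_channels)]
  region_map <- montage_regions()
  in_region <- channels %in%
    region_map$channel[region_map$region != "other"]
  bands <- lapply(names(eeg_bands), band_edges, fs = fs)
  names(bands) <- names(eeg_bands)
  centers <- vapply(bands, function(b) (b$low_hz + b$high_hz) / 2, 0)
  subject_id <- rep(sprintf("s%02d", seq_len(S)), each = Tn)
  state <- as.vector(vapply(seq_len(S), function(s)
    sample(rep(c(0L, 1L), length.out = Tn)), integer(Tn)))
  subj_logamp <- stats::rnorm(S, sd = shift$subject_offset_sd * 0.3)
  tt <- seq(0, by = 1 / fs, length.out = nsamp)
  signals <- array(0, dim = c(n, length(channels), nsamp))
  for (i in seq_len(n)) {
    s_idx <- match(subject_id[i], unique(subject_id))
    for (ch in seq_along(channels)) {
      x <- numeric(nsamp)
      for (b in seq_along(bands)) {
        amp <- band_amplitudes[[names(bands)[b]]] *
          exp(stats::rnorm(1, sd = 0.2)) * exp(subj_logamp[s_idx])
        if (names(bands)[b] == effect_band && in_region[ch]) {
          amp <- amp * exp(shift$effect_size * (state[i] - 0.5))
        }
        phase <- stats::runif(1, 0, 2 * pi)
        # slight per-trial frequency jitter keeps oscillations band-limited
        f0 <- centers[b] * exp(stats::rnorm(1, sd = 0.02))
        x <- x + amp * sin(2 * pi * f0 * tt + phase)
      }
      # 1/f-ish background: cumulative-sum pink-ish noise, high-passed
      bg <- stats::filter(stats::rnorm(nsamp, sd = 0.3), 0.95,
                          method = "recursive")
      x <- x + as.numeric(bg) * 0.3
      signals[i, ch, ] <- x
    }
  }
  flip1 <- stats::runif(n) < shift$label_noise
  flip2 <- stats::runif(n) < shift$label_noise
  eff1 <- ifelse(flip1, 1L - state, state)
  eff2 <- ifelse(flip2, 1L - state, state)
  meta <- tibble::tibble(
    subject_id = subject_id,
    database_id = profile$name,
    trial = rep(seq_len(Tn), times = S),
    valence = ifelse(eff1 == 1L, sample(6:9, n, TRUE), sample(1:5, n, TRUE)),
    arousal = ifelse(eff2 == 1L, sample(6:9, n, TRUE), sample(1:5, n, TRUE)),
    state = state
  )
  eeg_epochs(signals, channels, fs, meta)
}
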