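test_that("band edges follow the five-band scheme with a capped gamma", {
  expect_equal(unlist(band_edges("theta", 256)[c("low_hz", "high_hz")]),
               c(low_hz = 4, high_hz = 8))
  expect_equal(band_edges("slow_alpha", 256)$high_hz, 10)
  expect_equal(band_edges("alpha", 256)$low_hz, 8)
  expect_equal(band_edges("beta", 256)$high_hz, 30)
  g128 <- band_edges("gamma", 128)
  expect_equal(c(g128$low_hz, g128$high_hz), c(30, 45))
  # below the 45 Hz cap the 0.45*fs rule applies
  expect_equal(band_edges("gamma", 90)$high_hz, 0.45 * 90)
  expect_error(band_edges("delta", 256), "theta")
  expect_error(band_edges("theta", 50), "60 Hz")
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(11)
  x <- rnorm(1e5)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.02)
  # scaling by c adds log(c); a DC offset changes nothing
  expect_equal(differential_entropy(3 * x) - differential_entropy(x),
               log(3), tolerance = 1e-10)
  expect_equal(differential_entropy(x + 100), differential_entropy(x))
  expect_error(differential_entropy(rep(1, 1000)), "Degenerate")
})

test_that("band-filtered DE responds to in-band variance only", {
  fs <- 128
  set.seed(12)
  x <- rnorm(fs * 30)
  b <- band_edges("alpha", fs)
  de1 <- differential_entropy(x, b, fs)
  de2 <- differential_entropy(2 * x, b, fs)
  expect_equal(de2 - de1, log(2), tolerance = 1e-8)
  expect_error(differential_entropy(x[1:64], b, fs), "1 s")
})

test_that("Welch band power satisfies Parseval and flat-spectrum oracles", {
  fs <- 128
  tt <- seq(0, 100, by = 1 / fs)
  A <- 2
  x <- A * sin(2 * pi * 6 * tt)
  theta <- band_edges("theta", fs)
  spec <- welch_psd(x, fs)
  df <- spec$freq[2] - spec$freq[1]
  in_band <- spec$freq >= 4 & spec$freq < 8
  # a 6 Hz sinusoid's power integrates to A^2/2 inside theta
  expect_equal(sum(spec$power[in_band]) * df, A^2 / 2, tolerance = 0.05)
  expect_lt(band_psd(x, band_edges("beta", fs), fs) /
              band_psd(x, theta, fs), 1e-4)
  # white noise: band power fraction tracks the bandwidth fraction
  set.seed(13)
  w <- rnorm(1e5)
  specw <- welch_psd(w, fs)
  frac <- sum(specw$power[specw$freq >= 4 & specw$freq < 8]) /
    sum(specw$power)
  expect_lt(abs(frac / (4 / (fs / 2)) - 1), 0.1)
  expect_error(band_psd(w, band_spec("x", 70, 80), fs), "Nyquist")
})

test_that("feature extraction honours the 10-per-channel dimension contract", {
  ep <- make_epochs(n_trials = 2, fs = 128, seconds = 2)
  full <- extract_features(ep)
  expect_equal(ncol(full$values), 320)
  expect_equal(nrow(full$values), 2)
  aud <- extract_features(ep, region_channels("auditory"))
  expect_equal(ncol(aud$values), 120)
  vis <- extract_features(ep, region_channels("visual"))
  expect_equal(ncol(vis$values), 50)
  # column layout: channel-major, DE block then PSD block
  expect_equal(vis$columns$channel[1:10], rep("PO3", 10))
  expect_equal(vis$columns$type[1:10], rep(c("DE", "PSD"), each = 5))
  expect_equal(vis$columns$band[1:5], names(eeg_bands))
  expect_false(anyNA(full$values))
})

test_that("reordering the channel set permutes feature columns identically", {
  ep <- make_epochs(n_trials = 2, fs = 128, seconds = 2)
  fwd <- extract_features(ep, channel_set(c("O1", "Oz")))
  rev <- extract_features(ep, channel_set(c("Oz", "O1")))
  expect_equal(fwd$values[, 1:10], rev$values[, 11:20],
               ignore_attr = TRUE)
  expect_equal(fwd$values[, 11:20], rev$values[, 1:10],
               ignore_attr = TRUE)
})

test_that("a DC offset leaves every extracted feature unchanged", {
  ep <- make_epochs(n_trials = 1, channels = c("O1"), fs = 128, seconds = 2)
  shifted <- ep
  shifted$signals <- ep$signals + 50
  f1 <- extract_features(ep, channel_set("O1"))
  f2 <- extract_features(shifted, channel_set("O1"))
  de_cols <- f1$columns$type == "DE"
  expect_equal(f1$values[, de_cols], f2$values[, de_cols],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("min-max normalization maps each column onto [0, 1]", {
  tab <- make_table(n = 4, channels = "O1")
  tab$values[, 1] <- c(1, 2, 3, 0)
  tab$values[, 2] <- c(2, 10, 4, 8)
  tab$values[, 3] <- 7 # constant
  norm <- minmax_normalize(tab)
  expect_equal(unname(norm$values[, 1]), c(1, 2, 3, 0) / 3)
  expect_equal(unname(norm$values[, 2]), c(0, 1, 0.25, 0.75))
  expect_equal(unname(norm$values[, 3]), rep(0, 4))
  expect_true(all(norm$values >= 0 & norm$values <= 1))
  expect_true(norm$normalized)
  expect_error(minmax_normalize(norm), "already normalized")
  # a column already spanning [0, 1] is untouched
  tab2 <- make_table(n = 5, channels = "O1")
  tab2$values[, 1] <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(unname(minmax_normalize(tab2)$values[, 1]),
               c(0, 0.25, 0.5, 0.75, 1))
})
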