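test_that("packaged profiles reproduce the benchmark shapes", {
  tab <- generate_feature_dataset("mahnob_like", shift_spec(), seed = 1)
  expect_equal(nrow(tab$values), 540) # 27 subjects x 20 trials
  expect_equal(ncol(tab$values), 320)
  deap <- generate_feature_dataset("deap_like", shift_spec(), seed = 1)
  expect_equal(nrow(deap$values), 1280) # 32 subjects x 40 trials
  # balanced subject allocation
  expect_true(all(table(tab$sample_meta$subject_id) == 20))
  expect_true(all(table(deap$sample_meta$subject_id) == 40))
  expect_equal(length(unique(tab$sample_meta$subject_id)), 27)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  a <- generate_feature_dataset("mahnob_small", shift_spec(), seed = 5)
  b <- generate_feature_dataset("mahnob_small", shift_spec(), seed = 5)
  c <- generate_feature_dataset("mahnob_small", shift_spec(), seed = 6)
  expect_identical(a$values, b$values)
  expect_identical(a$sample_meta, b$sample_meta)
  expect_false(identical(a$values, c$values))
})

test_that("class signal is confined to region-designated columns", {
  tab <- generate_feature_dataset("mahnob_like",
                                  shift_spec(effect_size = 1,
                                             subject_offset_sd = 0.3),
                                  seed = 2)
  state <- tab$sample_meta$state
  map <- montage_regions()
  outside <- tab$columns$channel %in% map$channel[map$region == "other"]
  tstats <- apply(tab$values, 2, function(col) {
    unname(t.test(col[state == 1], col[state == 0])$statistic)
  })
  # non-designated columns show no systematic class gap ...
  expect_lt(max(abs(tstats[outside])), 5)
  expect_lt(mean(abs(tstats[outside]) > 2), 0.1)
  # ... while designated columns carry a strong one on average
  expect_gt(mean(abs(tstats[!outside])), 5)
})

test_that("ratings recover the latent state up to the label noise rate", {
  tab <- generate_feature_dataset("deap_like",
                                  shift_spec(label_noise = 0.1), seed = 3)
  lab <- binarize_labels(tab$sample_meta$valence)
  agree <- mean((lab == "high") == (tab$sample_meta$state == 1))
  expect_gt(agree, 0.85)
  expect_lt(agree, 0.95)
})

test_that("zero effect size yields chance-level downstream accuracy", {
  tab <- generate_feature_dataset("mahnob_small", shift_spec(effect_size = 0),
                                  seed = 0)
  rep <- loso_cv(tab, brada_config("brada", h = 20, seed = 0))
  # 108 samples: 3 binomial sigmas around 0.5
  expect_lt(abs(rep$mean_accuracy - 0.5), 3 * sqrt(0.25 / 108) + 0.02)
})

test_that("raw epoch generation meets its shape and reproducibility contract", {
  prof <- dataset_profile("raw", 2, 3, n_channels = 32, fs = 128,
                          trial_seconds = 2)
  ep <- generate_raw_epochs(prof, shift_spec(), seed = 4)
  expect_equal(dim(ep$signals), c(6, 32, 256))
  expect_equal(ep$fs, 128)
  ep2 <- generate_raw_epochs(prof, shift_spec(), seed = 4)
  expect_identical(ep$signals, ep2$signals)
})

test_that("doubling an injected band amplitude shifts DE by log 2", {
  prof <- dataset_profile("raw", 1, 2, fs = 128, trial_seconds = 60)
  amps <- c(theta = 1, slow_alpha = 0.5, alpha = 1.5, beta = 0.8,
            gamma = 0.4)
  amps2 <- amps; amps2["alpha"] <- amps["alpha"] * 2
  ep1 <- generate_raw_epochs(prof, shift_spec(effect_size = 0), seed = 1,
                             band_amplitudes = amps)
  ep2 <- generate_raw_epochs(prof, shift_spec(effect_size = 0), seed = 1,
                             band_amplitudes = amps2)
  b <- band_edges("alpha", 128)
  o1 <- which(ep1$channels == "O1")
  shift_nats <- mean(vapply(1:2, function(tr) {
    differential_entropy(ep2$signals[tr, o1, ], b, 128) -
      differential_entropy(ep1$signals[tr, o1, ], b, 128)
  }, 0))
  expect_lt(abs(shift_nats - log(2)), 0.05)
})

test_that("the injected effect survives the full raw-to-accuracy round trip", {
  prof <- dataset_profile("raw", 6, 10, n_channels = 32, fs = 128,
                          trial_seconds = 3)
  chans <- channel_set(c(as.character(region_channels("auditory")),
                         as.character(region_channels("visual"))))
  acc <- vapply(c(0, 1.0), function(es) {
    ep <- generate_raw_epochs(prof, shift_spec(effect_size = es), seed = 0)
    tab <- extract_features(ep, chans)
    loso_cv(tab, brada_config("brada", h = 16, seed = 0))$mean_accuracy
  }, 0)
  expect_gt(acc[2], acc[1] + 0.1) # strong effect clearly beats none
  expect_gt(acc[2], 0.7)
})
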