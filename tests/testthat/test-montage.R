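test_that("region channel lists match the method's montage grouping", {
  vis <- region_channels("visual")
  aud <- region_channels("auditory")
  expect_equal(as.character(vis), c("PO3", "PO4", "O1", "Oz", "O2"))
  expect_equal(as.character(aud),
               c("F7", "F8", "F3", "F4", "FC5", "FC6", "T7", "T8",
                 "CP5", "CP6", "P7", "P8"))
  expect_length(region_channels("all"), 32)
  expect_length(intersect(as.character(aud), as.character(vis)), 0)
})

test_that("unknown regions and channels produce informative errors", {
  expect_error(region_channels("frontal"), "auditory.*visual.*all")
  expect_error(channel_set(c("O1", "XX9")), "XX9")
  expect_error(channel_set(c("O1", "O1")), "Duplicate")
})

test_that("channel names are matched case-insensitively and canonicalized", {
  cs <- channel_set(c("oz", "po3", "FC5"))
  expect_equal(as.character(cs), c("Oz", "PO3", "FC5"))
})

test_that("select_channels subsets, preserves metadata, and is idempotent", {
  ep <- make_epochs(n_trials = 3)
  vis <- region_channels("visual")
  sub <- select_channels(ep, vis)
  expect_equal(sub$channels, as.character(vis))
  expect_equal(dim(sub$signals), c(3, 5, dim(ep$signals)[3]))
  expect_identical(sub$trial_meta, ep$trial_meta)
  expect_identical(select_channels(sub, vis)$signals, sub$signals)
  # selecting everything in montage order is the identity
  all_sel <- select_channels(ep, region_channels("all"))
  expect_identical(all_sel$signals, ep$signals)
})

test_that("selecting a channel absent from the epochs names it", {
  ep <- make_epochs(channels = setdiff(biosemi32_montage, "Oz"))
  expect_error(select_channels(ep, region_channels("visual")), "Oz")
})

test_that("the montage region map exports one tab-separated line per channel", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_montage_map(path)
  lines <- readLines(path)
  expect_length(lines, 32)
  parts <- strsplit(lines, "\t")
  expect_true(all(vapply(parts, length, 1L) == 2L))
  map <- montage_regions()
  expect_equal(sum(map$region == "auditory"), 12)
  expect_equal(sum(map$region == "visual"), 5)
})
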