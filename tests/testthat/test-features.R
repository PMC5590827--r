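test_that("maximum click-flash offset matches hand-computed cases in all modes", {
  p0 <- make_frame_pair(c(0, 6, 12), c(0, 6, 12))
  for (m in c("directional", "symmetric")) {
    expect_equal(max_click_flash_offset(p0, mode = m), 0)
  }
  # auditory {0, 100} ms, visual {50} ms -> nearest-neighbour offset 50
  a <- event_sequence(c(0, 100), 2000, "auditory")
  v <- event_sequence(50, 2000, "visual")
  p <- sequence_pair(a, v)
  expect_equal(max_click_flash_offset(p, "directional"), 50)
  expect_equal(max_click_flash_offset(p, "symmetric"), 50)
  # the modes disagree when one modality has an unmatched event
  p2 <- sequence_pair(event_sequence(0, 2000, "auditory"),
                      event_sequence(c(0, 500), 2000, "visual"))
  expect_equal(max_click_flash_offset(p2, "directional"), 0)
  expect_equal(max_click_flash_offset(p2, "symmetric"), 500)
  # sequential mode: largest gap between adjacent opposite-modality events
  p3 <- sequence_pair(event_sequence(c(100, 400), 2000, "auditory"),
                      event_sequence(c(150, 250), 2000, "visual"))
  expect_equal(max_click_flash_offset(p3, "sequential"), 150)  # 250 -> 400
  expect_error(
    max_click_flash_offset(sequence_pair(a, event_sequence(numeric(0), 2000, "visual"))),
    "non-empty")
})

test_that("symmetric offset is modality-symmetric and shift-invariant", {
  set.seed(31)
  for (i in 1:20) {
    p <- generate_pair(TRUE, FALSE, 10, 2000)
    swapped <- p
    swapped$auditory <- p$visual
    swapped$visual <- p$auditory
    expect_equal(max_click_flash_offset(p, "symmetric"),
                 max_click_flash_offset(swapped, "symmetric"))
    shifted <- p
    shifted$auditory$onsets_ms <- p$auditory$onsets_ms + 137
    shifted$visual$onsets_ms <- p$visual$onsets_ms + 137
    shifted$auditory$duration_ms <- shifted$visual$duration_ms <- 2200
    for (m in c("directional", "symmetric", "sequential")) {
      expect_equal(max_click_flash_offset(shifted, m),
                   max_click_flash_offset(p, m))
    }
  }
})

test_that("proportion synchronous counts shared onset frames", {
  expect_equal(proportion_synchronous(make_frame_pair(c(0, 3, 6, 9), c(0, 3, 6, 9))), 1)
  expect_equal(proportion_synchronous(make_frame_pair(c(0, 3, 6, 9), c(1, 4, 7, 10))), 0)
  expect_equal(proportion_synchronous(make_frame_pair(c(0, 3, 6, 9), c(0, 3, 12, 15))), 0.5)
  expect_warning(
    ps <- proportion_synchronous(make_frame_pair(c(0, 3), c(0, 3, 6, 9))),
    "unequal")
  expect_equal(ps, 0.5)   # 2 shared / 4 (the larger count)
})

test_that("full synchrony occurs exactly for identical equal-count trains", {
  set.seed(32)
  for (i in 1:50) {
    fa <- sort(sample(seq(0, 117, by = 3), 12)) + sample(0:2, 12, replace = TRUE)
    fv <- sort(sample(seq(0, 117, by = 3), 12)) + sample(0:2, 12, replace = TRUE)
    p <- make_frame_pair(unique(fa), unique(fv))
    if (length(p$auditory$onsets_ms) != length(p$visual$onsets_ms)) next
    ps <- suppressWarnings(proportion_synchronous(p))
    expect_identical(ps == 1, identical(p$auditory$onsets_ms, p$visual$onsets_ms))
  }
})

test_that("normalized cross-correlogram matches a Pearson-of-overlap oracle", {
  # two hand-written 12-frame trains
  p <- make_frame_pair(c(0, 3, 7, 10), c(1, 3, 8, 10), n_frames = 12)
  ccg <- normalized_xcorr(p, lag_range_ms = 1000)
  a <- v <- numeric(12)
  a[c(0, 3, 7, 10) + 1] <- 1
  v[c(1, 3, 8, 10) + 1] <- 1
  for (m in -2:2) {
    if (m >= 0) {
      oracle <- stats::cor(a[(1 + m):12], v[1:(12 - m)])
    } else {
      oracle <- stats::cor(a[1:(12 + m)], v[(1 - m):12])
    }
    got <- ccg$values[which.min(abs(ccg$lags_ms - m * FRAME_MS))]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_true(all(ccg$values >= -1 - 1e-12 & ccg$values <= 1 + 1e-12))
  # lag grid symmetric about zero, frame resolution
  expect_equal(ccg$lags_ms, -rev(ccg$lags_ms))
})

test_that("identical trains peak at 1 at lag zero and transposing flips lags", {
  set.seed(33)
  p <- generate_pair(FALSE, FALSE, 8, 2000)
  ccg <- normalized_xcorr(p)
  expect_equal(ccg$values[ccg$lags_ms == 0], 1, tolerance = 1e-12)
  expect_equal(max(ccg$values), 1, tolerance = 1e-12)

  q <- generate_pair(TRUE, FALSE, 8, 2000)
  fwd <- normalized_xcorr(q)
  swapped <- q
  swapped$auditory <- q$visual
  swapped$visual <- q$auditory
  rev_ccg <- normalized_xcorr(swapped)
  expect_equal(fwd$values, rev(rev_ccg$values), tolerance = 1e-12)
})

test_that("zero-variance overlaps yield a neutral correlation of zero", {
  # constant (empty) train: every overlap has zero variance
  a <- event_sequence(c(0, 50), 500, "auditory")
  v <- event_sequence(numeric(0), 500, "visual")
  ccg <- normalized_xcorr(sequence_pair(a, v), lag_range_ms = 100)
  expect_true(all(ccg$values == 0))
})

test_that("windowed maximum correlation shrinks with the window", {
  set.seed(34)
  p <- generate_pair(TRUE, FALSE, 10, 2000)
  ccg <- normalized_xcorr(p)
  windows <- c(800, 400, 200, 100, 0)
  vals <- vapply(windows, function(w) max_windowed_xcorr(p, w, ccg), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(max_windowed_xcorr(generate_pair(FALSE, FALSE, 8, 2000)), 1,
               tolerance = 1e-12)
})

test_that("fixed-interval conflict pairs correlate more than triplet pairs in a window", {
  set.seed(35)
  n <- 300
  tri <- replicate(n, max_windowed_xcorr(generate_pair(TRUE, FALSE, 10, 2000, "triplet")))
  rap <- replicate(n, max_windowed_xcorr(generate_pair(TRUE, FALSE, 10, 2000, "raposo")))
  expect_gt(mean(rap), mean(tri))
})

test_that("feature tables have one row per pair and propagate the rate", {
  expect_equal(nrow(feature_table(list())), 0)
  set.seed(36)
  pairs <- lapply(c(8, 10, 12), function(r) generate_pair(TRUE, FALSE, r, 2000))
  ft <- feature_table(pairs)
  expect_equal(nrow(ft), 3)
  expect_equal(ft$rate_hz, c(8, 10, 12))
  expect_named(ft, c("pair_id", "rate_hz", "prop_sync", "max_offset_ms",
                     "max_xcorr_win"))
  expect_true(all(ft$prop_sync >= 0 & ft$prop_sync <= 1))
  expect_true(all(ft$max_xcorr_win >= -1 & ft$max_xcorr_win <= 1))
})
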