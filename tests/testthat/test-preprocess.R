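test_that("binarize uses strict > with the default threshold of 50", {
  expect_equal(binarize(matrix(0, 4, 4)), matrix(FALSE, 4, 4))
  expect_equal(binarize(matrix(50, 4, 4)), matrix(FALSE, 4, 4))
  img <- matrix(0, 20, 20)
  img[5:14, 3:12] <- 200
  expect_equal(sum(binarize(img)), 100)
  expect_error(binarize(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("largest_component_bbox returns tight half-open boxes with 8-connectivity", {
  m <- matrix(FALSE, 8, 10)
  m[4, 8] <- TRUE  # single pixel at 0-based (row 3, col 7)
  expect_equal(unclass(largest_component_bbox(m))[c("x0", "y0", "x1", "y1")],
               list(x0 = 7, y0 = 3, x1 = 8, y1 = 4))
  # larger component wins
  m2 <- matrix(FALSE, 20, 20)
  m2[1:10, 1:10] <- TRUE
  m2[13:15, 13:15] <- TRUE
  b <- largest_component_bbox(m2)
  expect_equal(c(b$x0, b$y0, b$x1, b$y1), c(0, 0, 10, 10))
  # L-shape on 0-based rows 2..6 x cols 1..4 is one 8-connected component
  m3 <- matrix(FALSE, 10, 10)
  m3[3:7, 2] <- TRUE   # vertical arm
  m3[7, 2:5] <- TRUE   # horizontal arm
  b3 <- largest_component_bbox(m3)
  expect_equal(c(b3$x0, b3$y0, b3$x1, b3$y1), c(1, 2, 5, 7))
  expect_error(largest_component_bbox(matrix(FALSE, 3, 3)), "no foreground")
})

test_that("largest_component_bbox agrees with a brute-force flood-fill oracle", {
  set.seed(123)
  for (i in 1:50) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    if (!any(m)) m[16, 16] <- TRUE
    got <- largest_component_bbox(m)
    ora <- bfs_largest_bbox(m)
    expect_equal(unclass(got)[c("x0", "y0", "x1", "y1")], ora)
  }
})

test_that("diagonal-only touching pixels form one component (8- not 4-connectivity)", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:4, 1:4)] <- TRUE
  b <- largest_component_bbox(m)
  expect_equal(c(b$x0, b$y0, b$x1, b$y1), c(0, 0, 4, 4))
})

test_that("crop_frames crops half-open regions and resizes to the requested shape", {
  fr <- lapply(1:3, function(i) matrix(seq_len(128 * 128) + i, 128, 128))
  full <- structure(list(x0 = 0, y0 = 0, x1 = 128, y1 = 128), class = "crop_region")
  expect_identical(crop_frames(fr, full, NULL), fr)  # identity crop
  reg <- structure(list(x0 = 16, y0 = 16, x1 = 112, y1 = 112), class = "crop_region")
  out <- crop_frames(fr, reg, c(64, 64))
  expect_equal(dim(out[[1]]), c(64, 64))
  bad <- structure(list(x0 = 100, y0 = 0, x1 = 200, y1 = 10), class = "crop_region")
  expect_error(crop_frames(fr, bad), "outside")
})

test_that("keyframe crop on noiseless synthetic video excludes the band and recovers the lesion box", {
  ds <- generate_dataset(synthetic_config(n_patients = 2, n_frames = 80,
                                          noise_sigma = 0, seed = 11))
  for (s in ds) {
    reg <- sample_crop_region(s)
    expect_gte(reg$y0, 16)  # annotation band rows 0..15 excluded
    les <- s$lesion
    expect_equal(c(reg$x0, reg$y0, reg$x1, reg$y1),
                 c(les$cx - les$rx - 1, les$cy - les$ry - 1,
                   les$cx + les$rx, les$cy + les$ry))
    # crop idempotence: cropping the cropped keyframe returns the full crop
    key <- s$frames[[s$keyframe_index + 1]]
    cropped <- crop_frames(list(key), reg, NULL)[[1]]
    reg2 <- largest_component_bbox(binarize(cropped))
    expect_equal(c(reg2$x0, reg2$y0, reg2$x1, reg2$y1),
                 c(0, 0, ncol(cropped), nrow(cropped)))
  }
})

test_that("sample_frames pins the evenly-spaced-floor rule and boundary shifts", {
  expect_equal(sample_frames(120, 50), c(45, 46, 47, 48, 49, 50, 51, 52, 53, 55))
  # keyframe near the start: window shifted to [0, 10], not shrunk
  idx <- sample_frames(120, 2)
  expect_equal(idx[1], 0)
  expect_length(idx, 10)
  expect_true(all(idx <= 10))
  # keyframe near the end
  idx2 <- sample_frames(120, 118)
  expect_equal(idx2[length(idx2)], 119)
  expect_true(all(idx2 >= 109))
  # n_out equal to window length: all 11 consecutive indices
  expect_equal(sample_frames(120, 50, half_window = 5, n_out = 11), 45:55)
  expect_error(sample_frames(120, 50, half_window = 5, n_out = 12), "shorter")
  expect_error(sample_frames(120, 130), "out of range")
})

test_that("sample_frames always yields n_out unique increasing in-range indices", {
  set.seed(99)
  for (i in 1:200) {
    n_total <- sample(11:200, 1)
    kf <- sample(0:(n_total - 1), 1)
    idx <- sample_frames(n_total, kf)
    expect_length(idx, 10)
    expect_true(all(diff(idx) > 0))
    expect_true(all(idx >= 0 & idx < n_total))
    expect_true(all(idx >= kf - 10 & idx <= kf + 10))
  }
})
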