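test_that("thresholding classifies pixels by strict intensity comparison", {
  p <- tempfile(fileext = ".png")
  # pure black and pure white 2x2 images
  write_test_png(p, matrix(0, 2, 2))
  expect_equal(unclass(threshold_image(p)), matrix(1L, 2, 2), ignore_attr = TRUE)
  write_test_png(p, matrix(1, 2, 2))
  expect_equal(unclass(threshold_image(p)), matrix(0L, 2, 2), ignore_attr = TRUE)

  # left half dark (10/255), right half bright (245/255), opaque alpha
  r <- cbind(matrix(10 / 255, 4, 2), matrix(245 / 255, 4, 2))
  write_test_png(p, r, a = matrix(1, 4, 4))
  m <- threshold_image(p, alpha_rule = "below")
  expect_equal(unclass(m), cbind(matrix(1L, 4, 2), matrix(0L, 4, 2)), ignore_attr = TRUE)
  expect_equal(sum(is.na(m)), 0L)

  # a pixel exactly at the threshold is white (strict less-than)
  write_test_png(p, matrix(c(127, 126) / 255, 1, 2))
  m <- threshold_image(p, threshold_value = 127 / 255)
  expect_equal(as.vector(unclass(m)), c(0L, 1L))
})

test_that("channel selection thresholds the requested channel", {
  p <- tempfile(fileext = ".png")
  write_test_png(p,
    r = matrix(0.2, 2, 2), g = matrix(0.8, 2, 2), b = matrix(0.4, 2, 2)
  )
  expect_equal(unique(as.vector(threshold_image(p, channel = "red"))), 1L)
  expect_equal(unique(as.vector(threshold_image(p, channel = "green"))), 0L)
  expect_equal(unique(as.vector(threshold_image(p, channel = "blue"))), 1L)
  # average (0.2 + 0.8 + 0.4)/3 = 0.4667 < 0.5
  expect_equal(unique(as.vector(threshold_image(p, channel = "rgb_average"))), 1L)
  expect_equal(unique(as.vector(threshold_image(p, invert = TRUE))), 0L)
})

test_that("grayscale images feed every channel selector identically", {
  p <- tempfile(fileext = ".png")
  set.seed(42)
  png::writePNG(matrix(runif(36), 6, 6), p)
  ms <- lapply(c("red", "green", "blue", "rgb_average"), function(ch) {
    unclass(threshold_image(p, channel = ch))
  })
  expect_identical(ms[[1]], ms[[2]])
  expect_identical(ms[[1]], ms[[3]])
  expect_identical(ms[[1]], ms[[4]])
})

test_that("alpha rules assign transparency with opposite polarity", {
  p <- tempfile(fileext = ".png")
  # dark pixels; top row alpha 1, bottom row alpha 0
  write_test_png(p, matrix(0.1, 2, 3), a = rbind(rep(1, 3), rep(0, 3)))
  above <- threshold_image(p, alpha_rule = "above")
  expect_true(all(is.na(above[1, ])))
  expect_equal(as.vector(above[2, ]), rep(1L, 3))
  below <- threshold_image(p, alpha_rule = "below")
  expect_equal(as.vector(below[1, ]), rep(1L, 3))
  expect_true(all(is.na(below[2, ])))
})

test_that("raising the threshold never decreases the black count", {
  p <- tempfile(fileext = ".png")
  set.seed(7)
  png::writePNG(matrix(runif(400), 20, 20), p)
  counts <- vapply(
    c(0.1, 0.3, 0.5, 0.7, 0.9),
    function(th) sum(threshold_image(p, threshold_value = th) == 1L, na.rm = TRUE),
    numeric(1)
  )
  expect_true(all(diff(counts) >= 0))
})

test_that("thresholding is pixel-local: permuting image rows permutes matrix rows", {
  set.seed(11)
  g <- matrix(runif(64), 8, 8)
  perm <- sample(8)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  png::writePNG(g, p1)
  png::writePNG(g[perm, ], p2)
  m1 <- unclass(threshold_image(p1))
  m2 <- unclass(threshold_image(p2))
  expect_identical(m1[perm, ], m2)
})

test_that("unreadable files and unsupported formats raise input errors", {
  expect_error(threshold_image("no-such-file.png"), class = "bw_input_error")
  p <- tempfile(fileext = ".bmp")
  writeLines("x", p)
  expect_error(threshold_image(p), class = "bw_input_error")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(threshold_image(bad), class = "bw_input_error")
})

test_that("batch conversion preserves order, is deterministic, and fails fast", {
  pb <- tempfile(fileext = ".png")
  pw <- tempfile(fileext = ".png")
  write_test_png(pb, matrix(0, 2, 2))
  write_test_png(pw, matrix(1, 2, 2))
  res <- threshold_image_list(c(pb, pw))
  expect_length(res, 2)
  expect_true(all(res[[1]] == 1L))
  expect_true(all(res[[2]] == 0L))

  expect_error(threshold_image_list(character(0)), class = "bw_param_error")

  trip <- threshold_image_list(rep(pb, 3))
  expect_identical(trip[[1]], trip[[2]])
  expect_identical(trip[[2]], trip[[3]])

  err <- tryCatch(threshold_image_list(c(pb, "missing.png")), error = identity)
  expect_s3_class(err, "bw_input_error")
  expect_match(conditionMessage(err), "missing.png", fixed = TRUE)

  expect_message(
    res <- threshold_image_list(c(pb, "missing.png"), skip_errors = TRUE),
    "missing.png"
  )
  expect_length(res, 2)
  expect_null(res[[2]])
})

test_that("resampling hits the documented target dimensions", {
  big <- bwm(matrix(0L, 2500, 2500))
  small <- resample_bwm(big, "proportional", compress_rate = 0.1)
  expect_equal(dim(small), c(250L, 250L))

  m <- make_fixture("random", 37, 53, seed = 3)
  expect_identical(resample_bwm(m, "none"), m)
  expect_identical(resample_bwm(m, "proportional", compress_rate = 1), m)

  wf <- resample_bwm(m, "width_fixed", target_width = 20)
  expect_equal(ncol(wf), 20L)
  expect_equal(nrow(wf), max(1L, floor(37 * 20 / 53 + 0.5)))
  hf <- resample_bwm(m, "height_fixed", target_height = 10)
  expect_equal(nrow(hf), 10L)
  expect_equal(ncol(hf), max(1L, floor(53 * 10 / 37 + 0.5)))

  expect_error(resample_bwm(m, "proportional", compress_rate = 0), class = "bw_param_error")
  expect_error(resample_bwm(m, "proportional", compress_rate = 1.5), class = "bw_param_error")
  expect_error(resample_bwm(m, "width_fixed"), class = "bw_param_error")
})

test_that("nearest-neighbor resampling picks the source cell at each sampled center", {
  ch <- make_fixture("chessboard", 6, 6)
  got <- resample_bwm(ch, "frame_fixed", target_width = 3, target_height = 3)
  # brute-force nearest-neighbor index computation
  expected <- matrix(NA_integer_, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      si <- floor((i - 0.5) * 6 / 3) + 1L
      sj <- floor((j - 0.5) * 6 / 3) + 1L
      expected[i, j] <- unclass(ch)[si, sj]
    }
  }
  expect_equal(unclass(got), expected, ignore_attr = TRUE)

  # same check on an asymmetric random case
  m <- make_fixture("random", 11, 7, seed = 9)
  got <- resample_bwm(m, "frame_fixed", target_width = 4, target_height = 5)
  for (i in 1:5) {
    for (j in 1:4) {
      si <- min(11L, floor((i - 0.5) * 11 / 5) + 1L)
      sj <- min(7L, floor((j - 0.5) * 7 / 4) + 1L)
      expect_equal(unclass(got)[i, j], unclass(m)[si, sj])
    }
  }
})

test_that("image_information counts every cell exactly once", {
  info <- image_information(make_fixture("chessboard", 6, 6))
  expect_equal(info$n_black, 18L)
  expect_equal(info$n_white, 18L)
  expect_equal(info$n_transparent, 0L)
  expect_equal(info$fraction_black, 0.5)

  all_na <- bwm(matrix(NA_integer_, 2, 2))
  expect_equal(image_information(all_na)$fraction_transparent, 1)

  m <- bwm(matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, NA), 3, 3))
  info <- image_information(m)
  expect_equal(info$fraction_black, 2 / 9)
  expect_equal(info$fraction_white, 6 / 9)
  expect_equal(info$fraction_transparent, 1 / 9)
  expect_equal(
    info$fraction_black + info$fraction_white + info$fraction_transparent, 1
  )
})

test_that("matrix CSV serialization round-trips losslessly", {
  for (m in list(
    make_fixture("random", 9, 13, seed = 5),
    make_fixture("disk", 8, 8),
    bwm(matrix(c(1L, NA, 0L, 1L), 2, 2))
  )) {
    p <- tempfile(fileext = ".csv")
    write_bwm(m, p)
    expect_equal(unclass(read_bwm(p)), unclass(m), ignore_attr = TRUE)
  }

  p <- tempfile(fileext = ".csv")
  writeLines(c("1,0", "NA,1"), p)
  m <- read_bwm(p)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(m[2, 1]))
  expect_equal(m[1, 1], 1L)

  writeLines(c("1,0,1", "0,1"), p)
  expect_error(read_bwm(p), class = "bw_format_error")
  writeLines(c("1,0", "2,1"), p)
  err <- tryCatch(read_bwm(p), error = identity)
  expect_s3_class(err, "bw_format_error")
  expect_match(conditionMessage(err), "row 2, column 1")
})

test_that("bwm validates cell states and dimensions", {
  expect_error(bwm(matrix(2L, 2, 2)), class = "bw_format_error")
  expect_error(bwm(matrix(integer(0), 0, 0)), class = "bw_param_error")
  expect_error(bwm(matrix(0L, 2, 2), height_size = -1), class = "bw_param_error")
  m <- bwm(matrix(c(1, 0, NA, 1), 2, 2), height_size = 100, width_size = 50)
  expect_s3_class(m, "bwm")
  expect_equal(attr(m, "height_size"), 100)
  info <- image_information(m)
  expect_equal(info$n_black + info$n_white + info$n_transparent, 4L)
})
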