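test_that("sobel_outline marks exactly the boundary of a filled rectangle", {
  m <- matrix(0L, 20, 20)
  m[5:12, 7:15] <- 1L
  out <- sobel_outline(m)
  inner <- matrix(0L, 20, 20)
  inner[6:11, 8:14] <- 1L
  expect_identical(out, m - inner) # 1-px frame of the rectangle
})

test_that("an all-ones mask has no outline (replicated borders)", {
  expect_equal(sum(sobel_outline(matrix(1L, 16, 16))), 0)
})

test_that("box_count matches the brute-force oracle on small masks", {
  m <- matrix(0L, 17, 23) # deliberately not divisible by the box sizes
  m[c(1, 5, 17), c(2, 23)] <- 1L
  m[9, 11] <- 1L
  for (s in 2:9) expect_equal(box_count(m, s), oracle_box_count(m, s))
  expect_error(box_count(m, 1), ">= 2")
})

test_that("box counts are non-increasing in box size", {
  m <- withr::with_seed(42, matrix(rbinom(48 * 48, 1, 0.1), 48, 48))
  curve <- box_count_curve(m, sizes = 2:21)
  expect_true(all(diff(curve$count) <= 0))
})

test_that("box_sizes respects min_box, max_fraction and spacing modes", {
  cfg_all <- fd_config(box_spacing = "all")
  s_all <- box_sizes(c(64, 64), cfg_all)
  expect_identical(s_all, 2:28) # floor(0.45 * 64) = 28
  s_geo <- box_sizes(c(64, 64), fd_config())
  expect_true(all(s_geo %in% s_all))
  expect_true(all(diff(s_geo) > 0))
  s_log2 <- box_sizes(c(64, 64), fd_config(box_spacing = "log2"))
  expect_identical(s_log2, c(2L, 4L, 8L, 16L))
  expect_identical(box_sizes(c(4, 4), fd_config()), integer(0))
})

test_that("fit_fd recovers a slope from exact power-law counts", {
  s <- 2:40
  curve <- tibble::tibble(box_size = s, count = 500 * s^(-1.4))
  res <- fit_fd(curve)
  expect_s3_class(res, "fd_result")
  expect_equal(res$fd, 1.4, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_identical(res$qc, "ok")
})

test_that("fit_fd drops zero counts with a warning and flags short fits", {
  curve <- tibble::tibble(box_size = 2:7, count = c(40, 20, 10, 5, 0, 0))
  expect_warning(res <- fit_fd(curve), "zero count")
  expect_identical(res$qc, "poor_fit") # only 4 sizes remain
  expect_true(is.na(res$fd))
})

test_that("fit_fd flags flat curves and low r-squared as poor_fit", {
  flat <- tibble::tibble(box_size = 2:10, count = rep(7, 9))
  res <- fit_fd(flat)
  expect_identical(res$qc, "poor_fit")
  expect_equal(res$fd, 0)
  noisy <- tibble::tibble(box_size = 2:10,
                          count = c(50, 400, 30, 300, 20, 200, 10, 100, 5))
  expect_identical(fit_fd(noisy)$qc, "poor_fit")
})

test_that("mask_fd flags an empty outline", {
  res <- mask_fd(matrix(0L, 32, 32))
  expect_identical(res$qc, "degenerate_outline")
  expect_true(is.na(res$fd))
})

test_that("tidy and glance work on fd_result", {
  res <- mask_fd(phantom_circle(24, 64), outline = FALSE)
  td <- tidy(res)
  expect_true(all(c("box_size", "count") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("fd", "r_squared", "qc") %in% names(gl)))
})
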