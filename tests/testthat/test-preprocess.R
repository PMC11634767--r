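test_that("histogram stretching maps the percentile window to [0, 1]", {
  m <- matrix(seq(0, 100, length.out = 400), 20, 20)
  st <- stretch_histogram(m, p_low = 2, p_high = 98)
  q <- quantile(as.vector(m), c(0.02, 0.98), names = FALSE)
  expect_equal(range(st$pixels), c(0, 1))
  # a value inside the window maps affinely
  expect_equal(st$pixels[m == m[10, 10]][1],
               (m[10, 10] - q[1]) / (q[2] - q[1]))
  # values outside clip
  expect_true(all(st$pixels[m < q[1]] == 0))
  expect_true(all(st$pixels[m > q[2]] == 1))
})

test_that("stretching preserves intensity order inside the clip range", {
  m <- withr::with_seed(1, matrix(runif(256), 16, 16))
  st <- stretch_histogram(m, 0, 100)
  expect_equal(order(as.vector(m)), order(as.vector(st$pixels)))
})

test_that("constant images stretch to all zeros with a warning", {
  expect_warning(st <- stretch_histogram(matrix(3.2, 8, 8)), "constant image")
  expect_true(all(st$pixels == 0))
})

test_that("ROI-masked stretching uses only mask pixels for percentiles", {
  m <- matrix(0, 10, 10)
  m[1:5, ] <- 100 # bright half outside the mask
  mask <- matrix(0L, 10, 10)
  mask[6:10, ] <- 1L
  m[6:10, ] <- seq(0, 1, length.out = 50)
  st <- stretch_histogram(m, 0, 100, mask = mask)
  expect_equal(min(st$pixels[mask == 1]), 0)
  expect_equal(max(st$pixels[mask == 1]), 1)
})

test_that("make_roi keeps the pool and the inner half of the wall", {
  n <- 61
  ctr <- 31
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`))
  seg <- matrix(0L, n, n)
  seg[d <= 20] <- 2L
  seg[d > 20 & d <= 28] <- 1L
  roi <- make_roi(seg)
  expect_true(all(roi[seg == 2L] == 1)) # whole pool kept
  expect_true(all(roi[seg == 0L] == 0)) # background excluded
  # the innermost wall ring is in, the outermost is out
  expect_true(all(roi[d > 20 & d <= 21] == 1))
  expect_true(all(roi[d > 27 & d <= 28] == 0))
})

test_that("make_roi flags missing structures", {
  seg <- matrix(0L, 10, 10)
  expect_error(make_roi(seg), "geometry error")
  seg[3:6, 3:6] <- 1L # wall but no pool
  expect_true(all(make_roi(seg) == 0))
  seg[1, 1] <- 9L
  expect_error(make_roi(seg), "format error")
})
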