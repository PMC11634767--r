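test_that("Sierpinski carpet has exactly 8^level foreground cells", {
  for (lv in 1:4) {
    m <- phantom_sierpinski(lv)
    expect_equal(dim(m), c(3^lv, 3^lv))
    expect_equal(sum(m), 8^lv)
  }
  # pixel replication scales the count by px_per_cell^2
  m2 <- phantom_sierpinski(2, px_per_cell = 3)
  expect_equal(sum(m2), 64 * 9)
})

test_that("Sierpinski carpet is invariant under 90-degree rotation", {
  m <- phantom_sierpinski(3)
  expect_identical(rot90(m), m)
})

test_that("phantom_sierpinski validates its arguments", {
  expect_error(phantom_sierpinski(0), "positive integer")
  expect_error(phantom_sierpinski(8), "<= 7")
  expect_error(phantom_sierpinski(7, px_per_cell = 8), "max_side")
})

test_that("Koch curve raster is connected and level 0 is a straight line", {
  m0 <- phantom_koch(0, size_px = 64)
  rows <- which(m0 == 1, arr.ind = TRUE)[, 1]
  expect_equal(length(unique(rows)), 1) # a single horizontal line
  m3 <- phantom_koch(3, size_px = 256)
  expect_gt(sum(m3), sum(m0) * 256 / 64) # bumps add length
  expect_true(all(m3 %in% c(0L, 1L)))
})

test_that("phantom_koch rejects unresolvable levels", {
  expect_error(phantom_koch(6, size_px = 128), "too small")
  expect_error(phantom_koch(9), "0..8")
})

test_that("circle phantom has exact 4-fold rotational symmetry", {
  m <- phantom_circle(40, size_px = 128)
  expect_identical(rot90(m), m)
  expect_error(phantom_circle(70, size_px = 128), "radius_px")
})

test_that("midpoint profiles are seed-reproducible and zero mean", {
  p1 <- withr::with_seed(5, trabfd:::midpoint_profile(256, 0.5))
  p2 <- withr::with_seed(5, trabfd:::midpoint_profile(256, 0.5))
  expect_identical(p1, p2)
  expect_equal(mean(p1), 0)
  expect_length(p1, 256)
})

test_that("rough boundary phantoms are pure functions of their arguments", {
  a <- phantom_rough_boundary(0.5, seed = 3)
  b <- phantom_rough_boundary(0.5, seed = 3)
  expect_identical(a, b)
  c <- phantom_rough_boundary(0.5, seed = 4)
  expect_false(identical(a, c))
  expect_error(phantom_rough_boundary(0), "roughness_H")
})
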