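test_that("the level set separates two intensities inside the ROI", {
  # dark blob on a bright background within a square ROI
  n <- 60
  img <- matrix(0.9, n, n)
  truth <- matrix(0L, n, n)
  truth[20:40, 15:45] <- 1L
  img[truth == 1] <- 0.2
  roi <- matrix(0L, n, n)
  roi[5:56, 5:56] <- 1L
  out <- levelset_segment(img, roi)
  expect_identical(out$qc, "ok")
  expect_true(out$converged)
  expect_gt(dice_coefficient(out$mask, truth), 0.98)
})

test_that("blood_bright = FALSE selects the brighter phase instead", {
  n <- 40
  img <- matrix(0.2, n, n)
  blob <- matrix(0L, n, n)
  blob[10:30, 10:30] <- 1L
  img[blob == 1] <- 0.9
  roi <- matrix(1L, n, n)
  dark_cfg <- fd_config(blood_bright = FALSE)
  out <- levelset_segment(img, roi, dark_cfg)
  # under dark-blood convention the tissue phase is the brighter one
  expect_gt(dice_coefficient(out$mask, blob), 0.98)
})

test_that("level-set qc flags empty and uniform ROIs", {
  img <- matrix(0.5, 20, 20)
  expect_identical(levelset_segment(img, matrix(0L, 20, 20))$qc, "empty_roi")
  out <- levelset_segment(img, matrix(1L, 20, 20))
  expect_identical(out$qc, "degenerate_outline")
})

test_that("segmentation is deterministic across reruns", {
  ph <- two_intensity_phantom(seed = 2)
  st <- stretch_histogram(ph$image, mask = ph$roi)
  a <- levelset_segment(st, ph$roi)
  b <- levelset_segment(st, ph$roi)
  expect_identical(a$mask, b$mask)
  expect_identical(a$iterations, b$iterations)
})
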