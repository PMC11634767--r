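test_that("position normalization rescales valid slices to [0, 1]", {
  st <- fd_stack(position = c(2, 3, 4, 5, 6, 7, 8), fd = rep(1.2, 7))
  nst <- normalize_positions(st)
  expect_equal(range(nst$position), c(0, 1))
  # a single valid slice cannot be normalized
  one <- fd_stack(position = c(0.5), fd = 1.2)
  expect_true(isTRUE(attr(normalize_positions(one), "degenerate")))
  empty <- fd_stack(position = numeric(0), fd = numeric(0))
  expect_error(normalize_positions(empty), "no valid slices")
})

test_that("interpolated values stay within the input range", {
  set.seed(3)
  fdv <- runif(9, 1.1, 1.6)
  st <- fd_stack(position = (0:8) / 8, fd = fdv)
  prof <- interp_nine_slice(st)
  expect_equal(nrow(prof), 9)
  expect_true(all(prof$fd >= min(fdv) & prof$fd <= max(fdv)))
  expect_equal(prof$template_position, (0:8) / 8)
})

test_that("narrow bandwidth recovers matched input values", {
  fdv <- seq(1.1, 1.5, length.out = 9)
  st <- fd_stack(position = (0:8) / 8, fd = fdv)
  prof <- interp_nine_slice(st, bandwidth = 1e-3)
  expect_equal(prof$fd, fdv, tolerance = 1e-9)
})

test_that("fd_traits summarizes levels from the template profile", {
  fdv <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)
  st <- fd_stack(position = (0:8) / 8, fd = fdv)
  tr <- stack_traits(st)
  expect_identical(tr$qc, "ok")
  expect_equal(tr$basal_max, max(tr$fd_slice1, tr$fd_slice2, tr$fd_slice3))
  expect_equal(tr$global_mean,
               mean(unlist(tr[paste0("fd_slice", 1:9)])))
  expect_equal(tr$apical_min,
               min(unlist(tr[paste0("fd_slice", 7:9)])))
  expect_equal(tr$mid_median,
               median(unlist(tr[paste0("fd_slice", 4:6)])))
})

test_that("rejected stacks yield NA traits with the qc flag", {
  tr <- stack_traits(stack_with_k_valid(4))
  expect_identical(tr$qc, "lt_min_slices")
  expect_true(all(is.na(unlist(tr[fd_trait_names()]))))
  expect_equal(tr$n_valid_input_slices, 4)
})

test_that("trait names are the documented 25 in fixed order", {
  nms <- fd_trait_names()
  expect_length(nms, 25)
  expect_identical(nms[1:9], paste0("fd_slice", 1:9))
  expect_identical(nms[10:13], c("global_min", "global_mean",
                                 "global_median", "global_max"))
  expect_identical(nms[22:25], c("apical_min", "apical_mean",
                                 "apical_median", "apical_max"))
})
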