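test_that("autoplot methods return ggplot objects", {
  res <- mask_fd(phantom_circle(24, 64), outline = FALSE)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")

  st <- fd_stack(position = (0:8) / 8, fd = seq(1.2, 1.4, length.out = 9))
  expect_s3_class(ggplot2::autoplot(st), "ggplot")

  prof <- interp_nine_slice(st)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")

  cls <- classify_trabeculation(withr::with_seed(1, rnorm(500)))
  expect_s3_class(ggplot2::autoplot(cls), "ggplot")
})
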