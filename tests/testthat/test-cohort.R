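test_that("adjust_trait standardizes residuals and recovers planted effects", {
  beta <- rep(0, 19)
  names(beta) <- cohort_beta_names()
  beta["bsa"] <- 0.08
  beta["sex"] <- -0.02
  tab <- simulate_cohort(cohort_spec(n = 4000, beta = beta, seed = 21))
  adj <- adjust_trait(tab, "trait")
  expect_s3_class(adj, "trab_adjust")
  expect_lt(abs(mean(adj$residuals$residual)), 1e-10)
  expect_equal(sd(adj$residuals$residual), 1, tolerance = 1e-10)
  co <- tidy(adj)
  expect_equal(unname(co$estimate[co$term == "bsa"]), 0.08, tolerance = 0.02)
  expect_equal(unname(co$estimate[co$term == "sex"]), -0.02,
               tolerance = 0.02)
  gl <- glance(adj)
  expect_equal(gl$n_used, 4000)
  expect_equal(gl$residual_sd, 1)
})

test_that("adjustment is complete-case and counts exclusions", {
  tab <- simulate_cohort(cohort_spec(n = 300, seed = 2))
  tab$bsa[c(5, 10)] <- NA
  tab$trait[20] <- NA
  adj <- adjust_trait(tab, "trait")
  expect_equal(adj$n_excluded, 3)
  expect_equal(adj$n_used, 297)
  expect_false(any(adj$residuals$id %in% tab$id[c(5, 10, 20)]))
})

test_that("adjust_trait validates its inputs", {
  tab <- simulate_cohort(cohort_spec(n = 50, seed = 3))
  expect_error(adjust_trait(tab, "nope"), "nope")
  flat <- tab
  flat$trait <- 1
  expect_error(adjust_trait(flat, "trait"), "constant")
  tiny <- tab[1:10, ]
  expect_error(adjust_trait(tiny, "trait"), "too few complete cases")
})

test_that("s.d. classification thresholds behave as documented", {
  res <- c(-2.5, -1.6, -1.2, 0, 1.2, 1.6, 2.5)
  cls <- classify_trabeculation(res)
  expect_identical(as.character(cls$class),
                   c("hypo", "hypo", "normal", "normal", "normal",
                     "hyper", "hyper"))
  cls1 <- classify_trabeculation(res, mode = "sd_1")
  expect_equal(sum(cls1$class != "normal"), 6)
  cls2 <- classify_trabeculation(res, mode = "sd_2")
  expect_equal(sum(cls2$class != "normal"), 2)
  expect_identical(attr(cls, "mode"), "sd_1.5")
})

test_that("decile classification flags exactly the extreme bins", {
  res <- withr::with_seed(8, rnorm(200))
  cls <- classify_trabeculation(res, mode = "deciles")
  expect_equal(sum(cls$class == "hypo"), 20)
  expect_equal(sum(cls$class == "hyper"), 20)
  expect_true(all(cls$residual[cls$class == "hypo"] <
                  min(cls$residual[cls$class == "normal"])))
  expect_error(classify_trabeculation(rnorm(5), mode = "deciles"), "n >= 10")
})

test_that("identical groups compare with zero effect and p = 1", {
  x <- rep(c(-1, 0, 1), 20)
  vals <- c(x, x)
  groups <- rep(c("a", "b"), each = length(x))
  out <- compare_groups(vals, groups)
  expect_equal(out$diff, 0)
  expect_equal(out$p, 1)
})

test_that("compare_groups detects a shifted group", {
  withr::with_seed(5, {
    a <- rnorm(200)
    b <- rnorm(200, 0.5)
  })
  out <- compare_groups(c(a, b), rep(c("ref", "shift"), each = 200),
                        reference = "ref")
  expect_equal(out$group, "shift")
  expect_lt(out$p, 1e-4)
  expect_equal(out$diff, mean(b) - mean(a))
  expect_error(compare_groups(a, rep("ref", 200)), ">= 2 groups")
})

test_that("incidence_split excludes pre-index events", {
  cls <- classify_trabeculation(c(-2, 0, 0, 2))
  idx <- as.Date(c("2015-01-01", "2015-01-01", "2015-01-01", "2015-01-01"))
  evt <- as.Date(c("2014-06-01", NA, "2016-01-01", "2015-01-01"))
  out <- incidence_split(cls, idx, evt)
  expect_equal(out$n_excluded, 2) # pre-index and same-day events
  expect_equal(sum(out$table$event), 1)
  expect_error(incidence_split(cls, idx, evt, exclude_pre_index = FALSE),
               "validation error")
})
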