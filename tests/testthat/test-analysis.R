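test_that("paired_t matches the hand-computed closed form", {
  res <- paired_t(c(1, 2, 3, 4), c(2, 3, 5, 5))
  expect_identical(res$n, 4L)
  expect_equal(res$mean_difference, 1.25)
  expect_equal(res$sd_of_differences, 0.5)
  expect_equal(res$t, 5)
  expect_identical(res$df, 3L)
  expect_equal(res$p.value, 2 * pt(-5, 3))
})

test_that("identical measurements give t = 0, p = 1", {
  x <- c(4.2, 5.1, 3.3, 6)
  res <- paired_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p.value, 1)
})

test_that("incomplete pairs are dropped and too-few pairs are an error", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 5, 7)
  res <- paired_t(x, y)
  expect_identical(res$n, 3L)
  oracle <- t.test(c(2, 5, 7) - c(1, 4, 5))
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_error(paired_t(c(1, NA), c(2, NA)), class = "glywalk_insufficient_data")
  expect_error(paired_t(1:3, 1:4), class = "glywalk_bad_input")
})

test_that("paired_t agrees with the one-sample t oracle on random inputs", {
  set.seed(314)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- rnorm(n, 10, 4)
    y <- x + rnorm(n, runif(1, -2, 2), runif(1, 0.5, 3))
    res <- paired_t(x, y)
    oracle <- t.test(y - x)
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, oracle$p.value, tolerance = 1e-12)
    expect_equal(res$mean_difference, unname(oracle$estimate), tolerance = 1e-12)
    expect_identical(res$df, as.integer(oracle$parameter))
  }
})

test_that("diff_of_diffs mean equals mean(pre) - mean(post) for any sim column", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    pre <- rnorm(n, 12000, 20000)
    post <- rnorm(n, 10000, 19000)
    sim1 <- rnorm(n, 5000, 2000)
    sim2 <- runif(n, -1e5, 1e5)
    r1 <- diff_of_diffs(pre - sim1, post - sim1)
    r2 <- diff_of_diffs(pre - sim2, post - sim2)
    expect_equal(r1$mean_difference, mean(pre) - mean(post), tolerance = 1e-9)
    expect_equal(r2$mean_difference, mean(pre) - mean(post), tolerance = 1e-9)
  }
})

test_that("diff_of_diffs reproduces a hand-computed 3-pair example and the null", {
  d <- diff_of_diffs(c(10, 20, 30), c(5, 10, 15))
  expect_equal(d$mean_difference, 10)
  expect_equal(d$sd_of_differences, 5)
  expect_equal(d$t, 10 / (5 / sqrt(3)))
  same <- diff_of_diffs(c(3, 1, 4), c(3, 1, 4))
  expect_equal(same$t, 0)
})

test_that("imputation strategies coincide without missing data and LOCF zeroes its pairs", {
  pre <- c(4, 5, 6, 3)
  post <- c(5, 5, 7, 4)
  suite <- imputation_suite(pre, post)
  expect_equal(suite$complete_case$t, suite$mean_imputation$t)
  expect_equal(suite$complete_case$t, suite$carry_forward$t)

  post_m <- c(5, NA, 7, 4)
  suite <- imputation_suite(pre, post_m)
  # the carried-forward participant contributes a zero difference
  expect_identical(suite$carry_forward$n, 4L)
  expect_equal(suite$carry_forward$mean_difference,
               mean(c(1, 0, 1, 1)))
})

test_that("the most conservative strategy is the smallest |t|, verified by enumeration", {
  pre <- c(4, 5, 6, 3, 2)
  post <- c(5, 6, NA, 4, 2.5)
  suite <- imputation_suite(pre, post)
  cc <- t.test(c(5, 6, 4, 2.5) - c(4, 5, 3, 2))
  mi <- t.test(c(5, 6, mean(c(5, 6, 4, 2.5)), 4, 2.5) - pre)
  cf <- t.test(c(5, 6, 6, 4, 2.5) - pre)
  expect_equal(suite$complete_case$t, unname(cc$statistic), tolerance = 1e-12)
  expect_equal(suite$mean_imputation$t, unname(mi$statistic), tolerance = 1e-12)
  expect_equal(suite$carry_forward$t, unname(cf$statistic), tolerance = 1e-12)
  ts <- abs(c(cc$statistic, mi$statistic, cf$statistic))
  expect_equal(abs(suite$selected$t), min(ts), tolerance = 1e-12)
  expect_identical(suite$most_conservative,
                   c("complete_case", "mean_imputation", "carry_forward")[which.min(ts)])
})

test_that("subset filtering applies both exclusion reasons and reports counts", {
  co <- generate_cohort(cohort_params(n = 20, seed = 5, contamination = 0,
                                      pre_expectancy_sd = 5000,
                                      expectancy_noise_sd = 1000))
  res <- subset_filter(co)
  expect_identical(res$cohort, co)
  expect_identical(res$report$n_excluded, 0L)

  co$pre_expectancy_auc_decrease[3] <- 500000
  co$post_expectancy_auc_decrease[3] <- 500000
  co$pre_expectancy_auc_decrease[7] <- 500000  # one drawing only: retained
  co$excluded_candidate[9] <- TRUE
  res <- subset_filter(co)
  expect_identical(res$report$n_excluded, 2L)
  expect_identical(res$report$n_outlier_both_drawings, 1L)
  expect_identical(res$report$n_self_reported, 1L)
  expect_identical(res$cohort$id, setdiff(co$id, c(3, 9)))
})

test_that("the default cohort retains roughly the non-contaminated fraction", {
  co <- generate_cohort(cohort_params(seed = 31))
  res <- subset_filter(co)
  frac <- res$report$n_retained / res$report$n_input
  expect_gt(frac, 0.85)
  expect_lt(frac, 0.93)
})

test_that("summarize_study equals hand-computed summaries on a tiny cohort", {
  co <- data.frame(id = 1:4, hba1c = c(6.5, 7, 8, 9),
                   pre_expectancy_auc_decrease = c(10000, 14000, 9000, 13000),
                   post_expectancy_auc_decrease = c(9000, 12000, 8000, 12000),
                   sim_auc_reduction = c(5000, 6000, 5500, 5800),
                   intention_pre = c(4, 5, 6, 5),
                   intention_post = c(5, 6, 6, 5),
                   minutes_last_week = c(0, 60, 120, 30),
                   minutes_planned = c(30, 90, 120, 60),
                   excluded_candidate = rep(FALSE, 4))
  s <- summarize_study(co)
  expect_equal(s$full$expectancy$pre_mean, 11500)
  expect_equal(s$full$expectancy$post_mean, 10250)
  expect_equal(s$full$expectancy_shift$mean_difference, 1250)
  expect_equal(s$full$intention_tests$complete_case$mean_difference, 0.5)
  expect_equal(s$full$minutes_test$mean_difference, 22.5)
  expect_identical(s$subset$n, 4L)

  same <- co
  same$post_expectancy_auc_decrease <- same$pre_expectancy_auc_decrease
  same$intention_post <- same$intention_pre
  same$minutes_planned <- same$minutes_last_week
  s0 <- summarize_study(same)
  expect_equal(s0$full$expectancy_shift$mean_difference, 0)
  expect_equal(s0$full$intention_tests$selected$mean_difference, 0)
  expect_equal(s0$full$minutes_test$mean_difference, 0)
})

test_that("the default cohort's intention gain sits near the study's 0.31", {
  co <- generate_cohort(cohort_params(seed = 20251))
  s <- summarize_study(co)
  gain <- s$full$intention_tests$complete_case
  mc_se <- gain$sd_of_differences / sqrt(gain$n)
  expect_lt(abs(gain$mean_difference - 0.31), 3 * mc_se)
})
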