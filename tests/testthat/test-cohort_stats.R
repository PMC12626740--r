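test_that("paired_t matches the one-sample t on differences", {
  x <- c(0.30, 0.40, 0.50, 0.35)
  y <- c(0.20, 0.25, 0.45, 0.30)
  r <- paired_t(x, y)
  ref <- t.test(x - y)   # independent oracle: one-sample t on d
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p_two_sided, ref$p.value, tolerance = 1e-10)
  expect_equal(r$df, 3)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(r$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired_t rejects degenerate input", {
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  expect_error(paired_t(1, 1), "at least 2")
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "paired")
  # identical samples are the same degenerate case
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
})

test_that("bonferroni divides the familywise level", {
  expect_equal(bonferroni(0.05, 2), 0.025)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.06, 3), 0.02)
  expect_error(bonferroni(1.2, 2), "alpha_family")
  expect_error(bonferroni(0.05, 0), "positive integer")
})

test_that("delta_summary reports per-pair mean and sample SD", {
  r <- delta_summary(c(0.2, 0.3, 0.4), c(0.3, 0.4, 0.5))
  expect_equal(r$mean_delta, -0.1)
  expect_equal(r$sd_delta, 0)
  r <- delta_summary(c(0.3, 0.4), c(0.2, 0.2))
  expect_equal(r$mean_delta, 0.15)
  expect_equal(r$sd_delta, sd(c(0.1, 0.2)))   # n-1 denominator
  # sign convention: replan - original negative when risk drops
  r <- delta_summary(c(0.2, 0.25), c(0.3, 0.32))
  expect_lt(r$mean_delta, 0)
})

test_that("paired_power uses the noncentral t and has its limits", {
  expect_equal(paired_power(11, 1.1, 0.025), 0.8248, tolerance = 1e-3)
  expect_equal(paired_power(11, 0, 0.025), 0.025, tolerance = 1e-12)
  expect_equal(paired_power(8, 0, 0.05), 0.05, tolerance = 1e-12)
  # strictly increasing in n and in effect size
  pw_n <- vapply(c(4, 8, 11, 20, 40), function(n)
    paired_power(n, 0.8, 0.025), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_es <- vapply(c(0.2, 0.5, 0.8, 1.1, 1.5), function(es)
    paired_power(11, es, 0.025), numeric(1))
  expect_true(all(diff(pw_es) > 0))
  expect_error(paired_power(1, 1, 0.05), "n must")
})

test_that("empirical power agrees with the analytic value", {
  set.seed(31)
  n <- 11; es <- 1.1; alpha <- 0.025
  reps <- 4000
  d <- matrix(rnorm(reps * n, mean = es, sd = 1), nrow = reps)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tv <- m / (s / sqrt(n))
  emp <- mean(2 * pt(-abs(tv), n - 1) < alpha)
  expect_equal(emp, paired_power(n, es, alpha), tolerance = 0.03)
})

test_that("standardized_effect spans the clinically meaningful band", {
  expect_equal(standardized_effect(0.07, 0.062), 1.129, tolerance = 1e-3)
  expect_equal(standardized_effect(0.08, 0.062), 1.290, tolerance = 1e-3)
  expect_equal(standardized_effect(0, 0.05), 0)
  expect_error(standardized_effect(0.1, 0), "> 0")
})

test_that("paired_t p-values are uniform under the null", {
  set.seed(41)
  n <- 11; reps <- 2000
  d <- matrix(rnorm(reps * n), nrow = reps)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  p <- 2 * pt(-abs(m / (s / sqrt(n))), n - 1)
  # spot-check the vectorized null against the package implementation
  r <- paired_t(d[1, ], rep(0, n))
  expect_equal(r$p_two_sided, p[1], tolerance = 1e-12)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("null rejection rate at alpha = 0.025 is calibrated", {
  set.seed(51)
  n <- 11; reps <- 5000
  d <- matrix(rnorm(reps * n), nrow = reps)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  p <- 2 * pt(-abs(m / (s / sqrt(n))), n - 1)
  rate <- mean(p < 0.025)
  expect_gte(rate, 0.015)
  expect_lte(rate, 0.035)
})

make_cohort_df <- function(n, f) {
  do.call(rbind, lapply(c("original", "replan_3d", "replan_imrt"),
                        function(pl) data.frame(
                          patient_id = sprintf("P%02d", 1:n), plan = pl,
                          endpoint = "xerostomia", ntcp = f(pl, n))))
}

test_that("compare_cohort produces the study-table schema", {
  set.seed(61)
  base <- runif(11, 0.25, 0.45)
  df <- rbind(
    make_cohort_df(11, function(pl, n) switch(
      pl, original = base,
      replan_3d = base - 0.05 + rnorm(11, 0, 0.01),
      replan_imrt = base - 0.10 + rnorm(11, 0, 0.01))),
    within(make_cohort_df(11, function(pl, n) switch(
      pl, original = base * 0.6,
      replan_3d = base * 0.6 + rnorm(11, 0, 0.005),
      replan_imrt = base * 0.6 - 0.08 + rnorm(11, 0, 0.01))),
      endpoint <- "dry_eye"))
  cmp <- compare_cohort(df, alpha_family = 0.05, comparisons = 2)
  expect_s3_class(cmp, "comparison_table")
  # 2 endpoints x (3 plans + 1 supplementary contrast)
  expect_equal(nrow(cmp), 8)
  expect_equal(attr(cmp, "alpha_per_test"), 0.025)
  expect_setequal(unique(cmp$plan),
                  c("original", "replan_3d", "replan_imrt", "imrt_vs_3d"))
  # deltas computed per patient before summarizing
  x3 <- cmp[cmp$endpoint == "xerostomia" & cmp$plan == "replan_3d", ]
  expect_equal(x3$delta_mean_pct, -5, tolerance = 1)
  expect_true(x3$significant)   # large shift, consistent with paired_power
  expect_false(cmp$in_family[cmp$plan == "imrt_vs_3d"][1])
})

test_that("compare_cohort with identical plans finds nothing", {
  base <- seq(0.2, 0.4, length.out = 11)
  df <- make_cohort_df(11, function(pl, n) base)
  # identical replans make the paired t degenerate, which is an error
  expect_error(compare_cohort(df), "zero-variance")
  df$ntcp <- df$ntcp + ifelse(df$plan == "original", 0,
                              rep(c(-1, 1), length.out = 22) * 1e-3)
  cmp <- compare_cohort(df)
  expect_true(all(abs(cmp$delta_mean_pct) < 0.1, na.rm = TRUE))
  expect_false(any(cmp$significant[cmp$in_family]))
})

test_that("cohort_ntcp validates completeness and range", {
  df <- make_cohort_df(5, function(pl, n) runif(n, 0.1, 0.3))
  expect_s3_class(cohort_ntcp(df), "cohort_ntcp")
  expect_error(cohort_ntcp(df[-1, ]), "every patient")
  df2 <- df; df2$ntcp[1] <- 1.4
  expect_error(cohort_ntcp(df2), "\\[0, 1\\]")
  df3 <- df; df3$plan[1] <- "boost"
  expect_error(cohort_ntcp(df3), "unknown plan")
})
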