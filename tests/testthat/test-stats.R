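test_that("significance symbols follow the star convention exactly at the boundaries", {
  expect_identical(
    significance_symbol(c(0.2, 0.051, 0.05, 0.011, 0.01, 0.001, 0.0001)),
    c("ns", "ns", "*", "*", "**", "***", "****")
  )
  expect_error(significance_symbol(1.2), class = "chamberflow_parameter_error")
  expect_error(significance_symbol(NA_real_), class = "chamberflow_parameter_error")
})

test_that("the normality gate accepts Gaussians at ~1-alpha and rejects bimodal mixtures", {
  set.seed(11)
  accept <- mean(replicate(500, normality_gate(list(rnorm(40)))[1]))
  expect_gt(accept, 0.91)
  expect_lt(accept, 0.985)
  bimodal <- mean(replicate(200, {
    x <- c(rnorm(25, -4, 0.5), rnorm(25, 4, 0.5))
    normality_gate(list(x))[1]
  }))
  expect_lt(bimodal, 0.05) # rejected (gate FALSE) in > 95% of reps
  expect_false(normality_gate(list(rep(3, 10)))[1]) # zero variance
  expect_warning(g <- normality_gate(list(c(1, 2))), "n < 3")
  expect_false(g[1])
})

test_that("two-group comparison routes on normality and fills summaries", {
  set.seed(21)
  a <- rnorm(15, 10, 2)
  b <- rnorm(15, 14, 2)
  cmp <- compare_two_groups(a, b, label_a = "young", label_b = "old")
  expect_identical(cmp$test_name, "t_unpaired")
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$group_summaries$young$mean, mean(a))
  expect_equal(cmp$group_summaries$young$sem, sd(a) / sqrt(15))
  expect_identical(cmp$group_summaries$old$n, 15L)

  # heavily skewed data fails the gate and takes the rank test
  set.seed(22)
  x <- exp(rnorm(20, 0, 1.5))
  y <- exp(rnorm(20, 1, 1.5))
  cmp2 <- compare_two_groups(x, y)
  expect_identical(cmp2$test_name, "mann_whitney_u")

  expect_error(compare_two_groups(c(1, 2), rnorm(10), label_a = "tiny"),
    class = "chamberflow_analysis_error", regexp = "tiny")
})

test_that("identical groups compare as no difference (p = 1, ns)", {
  a <- rep(c(5, 5, 5, 5), 3)
  cmp <- compare_two_groups(a, a)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$significance_symbol, "ns")
  set.seed(5)
  b <- rnorm(12)
  cmp2 <- compare_two_groups(b, b)
  expect_gt(cmp2$p_value, 0.999)
  expect_identical(cmp2$significance_symbol, "ns")
})

test_that("a 2-SD shift at n = 15 is detected in nearly every replicate", {
  set.seed(31)
  hits <- mean(replicate(300, {
    compare_two_groups(rnorm(15), rnorm(15, 2, 1))$p_value <= 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("two-way ANOVA handles the unbalanced age x LPS design", {
  set.seed(41)
  records <- data.frame(
    age_group = rep(c("young", "old"), c(32, 28)),
    treatment = c(rep(c("control", "LPS"), c(16, 16)), rep(c("control", "LPS"), c(14, 14))),
    adherent_density_mm2 = c(
      rnorm(16, 15, 6), rnorm(16, 19, 6), rnorm(14, 19, 6), rnorm(14, 26, 6)
    )
  )
  res <- two_way_anova_age_lps(records)
  expect_named(res$factor_p_values, c("age", "lps", "interaction"))
  expect_true(all(res$factor_p_values >= 0 & res$factor_p_values <= 1))
  expect_identical(sum(res$design_counts), 60L)
  expect_lt(res$factor_p_values["lps"], 0.05)

  # all observations equal: no variance, no effect
  flat <- records
  flat$adherent_density_mm2 <- 7
  res0 <- two_way_anova_age_lps(flat)
  expect_equal(unname(res0$f_statistics), c(0, 0, 0))
  expect_equal(unname(res0$factor_p_values), c(1, 1, 1))

  # empty design cell is a named analysis error
  expect_error(
    two_way_anova_age_lps(records[records$treatment == "control" |
      records$age_group == "young", ]),
    class = "chamberflow_analysis_error", regexp = "old.*LPS"
  )
})

test_that("ANOVA agrees with an independent aov fit on a balanced design", {
  set.seed(42)
  records <- data.frame(
    age_group = rep(c("young", "old"), each = 20),
    treatment = rep(rep(c("control", "LPS"), each = 10), 2),
    adherent_density_mm2 = rnorm(40, 20, 5)
  )
  res <- two_way_anova_age_lps(records)
  ref <- summary(aov(
    adherent_density_mm2 ~ factor(age_group) * factor(treatment),
    data = records
  ))[[1]]
  # balanced design: Type I and Type II sums of squares coincide
  expect_equal(unname(res$factor_p_values), ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
  expect_equal(unname(res$f_statistics), ref[["F value"]][1:3], tolerance = 1e-10)
})

test_that("LPS response ratios reproduce the printed percent increases", {
  young <- lps_response_ratio(19, 15)
  old <- lps_response_ratio(26, 19)
  expect_equal(young$percent_increase, 400 / 15) # +26.67%
  expect_equal(old$percent_increase, 700 / 19)   # +36.84%
  expect_equal(mean(c(young$percent_increase, old$percent_increase)), 31.75438596)
  same <- lps_response_ratio(12, 12)
  expect_equal(same$ratio, 1)
  expect_equal(same$percent_increase, 0)
  expect_error(lps_response_ratio(10, 0), class = "chamberflow_analysis_error")
})

test_that("2^-ddCt fold changes are exact, multiplicative and monotone", {
  expect_equal(ddct_fold_change(25, 20, 5)$fold_change, 1)
  expect_equal(ddct_fold_change(26, 20, 5)$fold_change, 0.5)
  expect_equal(ddct_fold_change(23, 20, 5)$fold_change, 4)
  set.seed(51)
  ct_t <- runif(50, 15, 35)
  ct_r <- runif(50, 15, 35)
  cal <- runif(50, -3, 3)
  res <- ddct_fold_change(ct_t, ct_r, cal, gene = "ITGAX")
  expect_equal(res$fold_change, 2^(-((ct_t - ct_r) - cal))) # direct re-evaluation
  expect_true(all(res$fold_change > 0))
  # multiplicative in ddCt and strictly decreasing
  f <- function(d) ddct_fold_change(20 + d, 20, 0)$fold_change
  expect_equal(f(1.3 + 0.9), f(1.3) * f(0.9))
  expect_true(all(diff(f(seq(-3, 3, 0.5))) < 0))
  expect_error(ddct_fold_change(Inf, 20, 0), class = "chamberflow_parameter_error")
})

test_that("response variance separates heterogeneous from homogeneous groups", {
  # young: 4 of 16 donors respond below 1, the rest well above; old: uniform
  young <- c(rep(0.8, 4), rep(1.5, 12))
  old <- rep(1.35, 14) + seq(-0.02, 0.02, length.out = 14)
  rv <- response_variance_by_group(
    c(young, old), rep(c("young", "old"), c(16, 14))
  )
  expect_true(rv$young_more_heterogeneous)
  expect_equal(unname(rv$variance["young"]), var(young))
  # constant group has variance 0; variance is shift-invariant
  rv0 <- response_variance_by_group(
    c(rep(2, 5), 1:5), rep(c("young", "old"), each = 5)
  )
  expect_equal(unname(rv0$variance["young"]), 0)
  shifted <- response_variance_by_group(
    c(young, old) + 10, rep(c("young", "old"), c(16, 14))
  )
  expect_equal(shifted$variance, rv$variance)
  expect_error(response_variance_by_group(1:3, c("young", "young", "old")),
    class = "chamberflow_analysis_error")
})
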