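test_that("ICC(3,1) behaves at its analytic extremes", {
  s <- stats::rnorm(20)
  m <- cbind(s, s, s)
  expect_equal(icc_consistency(m)$icc, 1)
  # no between-subject variance: nothing to agree on
  set.seed(1)
  noise <- matrix(stats::rnorm(60), 20, 3)
  expect_lt(icc_consistency(matrix(5, 20, 3) + noise * 0 + noise)$icc, 0.3)
  expect_error(icc_consistency(cbind(c(1, NA), c(2, 3))), "complete")
  expect_error(icc_consistency(matrix(1, 1, 3)), "at least 2")
})

test_that("ICC(3,1) recovers the variance-ratio target on simulated raters", {
  set.seed(20)
  n <- 200
  subj <- stats::rnorm(n, sd = 1)
  m <- sapply(1:3, function(k) subj + stats::rnorm(n, sd = 0.5))
  # target: sigma_b^2 / (sigma_b^2 + sigma_e^2) = 1 / 1.25 = 0.8
  expect_equal(icc_consistency(m)$icc, 0.8, tolerance = 0.05)
  expect_match(icc_consistency(m)$model_tag, "ICC\\(3,1\\)")
  expect_equal(icc_consistency(m)$consistency_band, "high")
})

test_that("paired comparison gates on the normality of differences", {
  x <- stats::rnorm(47)
  expect_equal(paired_comparison(x, x)$p_value, 1)
  expect_match(paired_comparison(x, x)$flags, "exact-equality")
  set.seed(5)
  nrm <- paired_comparison(stats::rnorm(47), stats::rnorm(47))
  expect_equal(nrm$test_name, "paired t")
  expect_true(nrm$normality_used)
  # heavy tails push the gate to the signed-rank branch in nearly all draws
  picks <- replicate(40, {
    paired_comparison(stats::rcauchy(47), stats::rnorm(47))$test_name
  })
  expect_gte(mean(picks == "Wilcoxon signed-rank"), 0.95)
  expect_error(paired_comparison(1:4, 1:5), "paired")
})

test_that("two-group comparison gates and detects a one-sigma shift", {
  x <- rep(2, 10)
  r <- group_comparison(x, x)
  expect_equal(r$p_value, 1)
  set.seed(12)
  shift <- group_comparison(stats::rnorm(100), stats::rnorm(100, mean = 1))
  expect_lt(shift$p_value, 0.001)   # analytic power > 0.99 at n = 100
  expect_true(shift$normality_used)
  skewed <- group_comparison(stats::rexp(60), stats::rexp(60))
  expect_equal(skewed$test_name, "Mann-Whitney U")
  expect_error(group_comparison(1:2, 1:10), "n >= 3")
})

test_that("multi-group comparison gates between ANOVA and Kruskal-Wallis", {
  g <- rep(list(rep(1, 10)), 3)
  expect_equal(multi_group_comparison(g)$p_value, 1)
  set.seed(112)
  norm3 <- replicate(3, stats::rnorm(80), simplify = FALSE)
  r0 <- multi_group_comparison(norm3)
  expect_equal(r0$test_name, "one-way ANOVA")
  shifted <- c(norm3[1:2], list(stats::rnorm(80, mean = 1)))
  r1 <- multi_group_comparison(shifted)
  expect_lt(r1$p_value, 1e-6)
  heavy <- replicate(3, stats::rcauchy(80), simplify = FALSE)
  expect_equal(multi_group_comparison(heavy)$test_name, "Kruskal-Wallis")
  expect_error(multi_group_comparison(norm3[1:2]), "3 groups")
})

test_that("chi-square GOF reproduces the textbook cases", {
  r <- chi_square_gof(c(75, 65))
  expect_equal(unname(r$statistic), 0.7143, tolerance = 1e-3)
  expect_equal(round(r$p_value, 3), 0.398)
  expect_equal(chi_square_gof(c(50, 50))$p_value, 1)
  r10 <- chi_square_gof(c(10, 0))
  expect_equal(unname(r10$statistic), 10)
  expect_equal(r10$p_value, 2 * (1 - stats::pnorm(sqrt(10))), tolerance = 1e-6)
  expect_error(chi_square_gof(c(0, 0)), "positive total")
})

test_that("summary tables format cells as recomputed mean +/- SD strings", {
  set.seed(8)
  ears <- sprintf("e%02d", 1:20)
  tbl <- tidyr::expand_grid(ear_id = ears, parameter = c("p1", "p2"),
                            method = c("manual", "automated"), replicate = 1:3)
  tbl$value <- stats::rnorm(nrow(tbl), mean = ifelse(tbl$parameter == "p1", 5, 8), sd = 0.4)
  tbl$sex <- rep(c("F", "M"), each = nrow(tbl) / 2)
  rep_meth <- summarize_measurements(tbl, "method")
  expect_equal(nrow(rep_meth), 2)
  avg <- tbl |> dplyr::filter(parameter == "p1", method == "manual") |>
    dplyr::group_by(ear_id) |> dplyr::summarize(v = mean(value))
  expect_equal(rep_meth$manual[rep_meth$parameter == "p1"],
               sprintf("%.2f ± %.2f", mean(avg$v), stats::sd(avg$v)))
  expect_true(all(c("test", "p_value", "icc") %in% names(rep_meth)))
  rep_sex <- summarize_measurements(tbl, "sex")
  expect_true(all(c("F", "M") %in% names(rep_sex)))
  desc <- summarize_measurements(tbl, "method", comparisons = FALSE)
  expect_false("p_value" %in% names(desc))
  expect_error(summarize_measurements(tbl[, -1], "method"), "missing columns")
  expect_error(summarize_measurements(tbl, "side"), "absent")
  md <- summary_markdown(rep_meth)
  expect_match(md, "^\\| parameter \\|")
})

test_that("percentages print like the demographic table", {
  expect_equal(pct_string(75, 140), "53.6")
  expect_equal(pct_string(130, 226), "57.5")
  expect_equal(pct_string(96, 226), "42.5")
})

test_that("tidiers return well-formed tibbles", {
  td <- tidy(chi_square_gof(c(75, 65)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  ti <- tidy(icc_consistency(cbind(1:5, 1:5)))
  expect_equal(ti$icc, 1)
})
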