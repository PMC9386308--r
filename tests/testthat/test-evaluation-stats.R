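test_that("rsq is squared correlation with its degenerate guards", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(rsq(x, x), 1)
  expect_equal(rsq(-x, x), 1)
  set.seed(83)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(rsq(a, b), 0.01)
  expect_error(rsq(rep(1, 5), x), "zero variance")
})

test_that("slope and bias follow their conventions", {
  ref <- c(2, 4, 6, 9)
  expect_equal(slope(ref, ref), 1)
  expect_equal(slope(2 * ref, ref), 2)
  expect_equal(slope(0.9 * ref + 3, ref), 0.9)
  expect_equal(bias(ref, ref), 0)
  # bias = mean(lab - predicted): lab one unit above predictions -> +1
  expect_equal(bias(ref, ref + 1), 1)
})

test_that("SEP follows the n-denominator formula, corrected and not", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(sep(x, x), 0)
  d <- 0.7
  expect_equal(sep(x + d, x, bias_corrected = TRUE), 0)
  expect_equal(sep(x + d, x, bias_corrected = FALSE), d)
  # differences with sample mean -0.011949 and sample SD 0.328882 (n = 60)
  # give the population-SD form of SEP(C)
  dvec <- vector_with_moments(60, -0.011949, 0.328882, seed = 89)
  expect_equal(sep(dvec, rep(0, 60), bias_corrected = TRUE),
               0.328882 * sqrt(59 / 60), tolerance = 1e-12)
  expect_equal(round(sep(dvec, rep(0, 60)), 3), 0.326)
  # n-1 flag reproduces the sample-SD convention
  expect_equal(sep(dvec, rep(0, 60), n_minus_1 = TRUE), 0.328882,
               tolerance = 1e-12)
})

test_that("RPD arithmetic, class bands, and the perfect-fit guard", {
  expect_equal(rpd(0.25, 0.069), 0.25 / 0.069)
  expect_equal(rpd(1, 1), 1)
  expect_error(rpd(0.5, 0), "unbounded|zero")
  # a pure offset has zero bias-corrected SEP, so RPD is flagged, not Inf
  x <- c(1, 2, 3)
  expect_error(rpd(1, sep(x + 5, x, bias_corrected = TRUE)))

  expect_equal(rpd_class(3.62), "excellent")
  expect_equal(rpd_class(2.12), "very good")
  expect_equal(rpd_class(0.5), "very poor")
  expect_equal(rpd_class(1.2), "poor")
  expect_equal(rpd_class(1.6), "fair")
  expect_equal(rpd_class(1.9), "good")
  expect_equal(rpd_class(2.5), "excellent")
})

test_that("SEP^2 decomposes exactly into SEP(C)^2 + bias^2", {
  set.seed(97)
  for (i in 1:200) {
    n <- sample(5:100, 1)
    pred <- rnorm(n, 10, 3)
    lab <- pred + rnorm(n, 0.5, 1)
    lhs <- sep(pred, lab, bias_corrected = FALSE)^2
    rhs <- sep(pred, lab, bias_corrected = TRUE)^2 + bias(pred, lab)^2
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("paired t-test matches explicit sums and stats::t.test", {
  x <- c(1, 2, 3)
  r <- paired_t_test(x, x)
  expect_equal(r$t_value, 0)
  expect_equal(r$p_value, 1)

  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:80, 1)
    lab <- rnorm(n, 10, 2)
    pred <- lab + rnorm(n, 0.1, 0.5)
    ours <- paired_t_test(lab, pred)
    oracle <- t.test(lab, pred, paired = TRUE)
    expect_equal(ours$t_value, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(c(ours$ci_lower, ours$ci_upper),
                 as.numeric(oracle$conf.int), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ours$df, unname(oracle$parameter))
    expect_equal(ours$t_value, ours$mean_diff / ours$se_mean)
  }

  # zero-variance nonzero-mean differences are flagged, not NaN
  r2 <- paired_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_equal(r2$t_value, Inf)
  expect_equal(r2$p_value, 0)
})

test_that("validation report guards in-sample use and reproduces its own
           arithmetic", {
  fx <- small_fixture(n = 45, seed = 103)
  plan <- split_by_trait(fx$reference, "protein_pct")
  cal <- subset_samples(fx$spectra, plan$calibration_ids)
  val <- subset_samples(fx$spectra, plan$validation_ids)
  model <- calibrate(cal, fx$reference, "protein_pct", method = "pls",
                     scatter = "snv_dt", treatment = "2,4,4,1")
  expect_error(validation_report(model, cal, fx$reference), "overlap")
  flagged <- validation_report(model, cal, fx$reference,
                               allow_in_sample = TRUE)
  expect_true(flagged$in_sample)

  report <- validation_report(model, val, fx$reference)
  expect_false(report$in_sample)
  df <- as.data.frame(report)
  expect_true(all(is.finite(unlist(df[sapply(df, is.numeric)]))))
  # table-row arithmetic: the stored RPD is SD / SEP(C)
  expect_equal(report$rpd, report$sd / report$sep_c, tolerance = 1e-12)
  expect_equal(report$sep^2, report$sep_c^2 + report$bias^2,
               tolerance = 1e-10)
  expect_equal(report$val_range,
               range(fx$reference$protein_pct[
                 fx$reference$sample_id %in% plan$validation_ids]))
})
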