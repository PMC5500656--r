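# ROI means, partial correlations, r-to-z comparison, Bonferroni,
# demographics battery.

test_that("roi_mean is the unweighted cluster mean", {
  m <- array(3.5, c(4, 4, 4))
  expect_identical(roi_mean(m, 1:10), 3.5)
  m2 <- array(0, c(4, 4, 4)); m2[5] <- 9
  expect_identical(roi_mean(m2, 5L), 9)
  checker <- array(c(0, 1), c(4, 4, 4))
  expect_identical(roi_mean(checker, 1:8), 0.5)
  expect_error(roi_mean(m, integer(0)), "empty")
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(51)
  for (rep in 1:6) {
    n <- 40L
    covs <- matrix(rnorm(n * 3), n, 3)
    x <- rnorm(n) + covs %*% c(0.5, -0.2, 0.1)
    y <- rnorm(n) + covs %*% c(-0.3, 0.4, 0.2) + 0.4 * x
    pc <- partial_correlation(x, y, covs)
    expect_equal(pc$r, oracle_partial_cor(x, y, covs), tolerance = 1e-12)
    expect_identical(pc$df, n - 2L - 3L)
  }
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(52)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(pc$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ref$p.value, tolerance = 1e-10)

  expect_equal(partial_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(x, rep(1, 30)), "constant")
  expect_error(partial_correlation(x[1:5], y[1:5], matrix(rnorm(15), 5)),
               "k \\+ 4")
})

test_that("partial correlation is invariant to affine covariate rescaling", {
  set.seed(53)
  n <- 35
  covs <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  x <- rnorm(n); y <- rnorm(n)
  pc1 <- partial_correlation(x, y, covs)
  covs2 <- data.frame(a = 100 * covs$a - 7, b = covs$b / 3, c = covs$c + 42)
  pc2 <- partial_correlation(x, y, covs2)
  expect_equal(pc1$r, pc2$r, tolerance = 1e-12)
  expect_equal(pc1$p, pc2$p, tolerance = 1e-12)
})

test_that("correlation comparison follows the Fisher r-to-z formula", {
  eq <- compare_correlations(0.4, 30, 0.4, 50)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)

  a <- compare_correlations(0.5, 50, 0.0, 50)
  b <- compare_correlations(0.0, 50, 0.5, 50)
  expect_identical(a$z, -b$z)                      # antisymmetry
  expect_equal(a$z, atanh(0.5) / sqrt(2 / 47), tolerance = 1e-12)

  expect_error(compare_correlations(0.5, 3, 0.1, 50), "exceed 3")
  expect_error(compare_correlations(1, 30, 0.1, 50), "< 1")
})

test_that("Bonferroni adjustment caps and preserves order", {
  expect_equal(bonferroni_adjust(0.046, 2), 0.092)
  expect_identical(bonferroni_adjust(c(0.2, 0.01), 1), c(0.2, 0.01))
  expect_identical(bonferroni_adjust(0.9, 5), 1)
  p <- c(0.001, 0.04, 0.2, 0.8)
  expect_identical(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  expect_identical(order(bonferroni_adjust(p, 3)), order(p))
})

test_that("gender chi-squared reproduces the cohort worked example", {
  clin <- data.frame(
    group = rep(c("patient", "control"), c(53, 55)),
    gender = c(rep(c("M", "F"), c(25, 28)), rep(c("M", "F"), c(29, 26))),
    age = c(rnorm(53, 56, 7), rnorm(55, 55, 7))
  )
  res <- demographics_tests(clin, variables = character(0))
  chi <- res[res$variable == "gender", ]
  expect_equal(round(chi$statistic, 3), 0.333)
  expect_equal(round(chi$p, 3), 0.564)
})

test_that("the demographics battery routes by normality", {
  set.seed(54)
  clin <- data.frame(
    group = rep(c("patient", "control"), each = 40),
    gender = rep(c("M", "F"), 40),
    symmetric = rnorm(80),
    skewed = exp(rnorm(80, sd = 1.5)),
    flat = rep(2, 80)
  )
  res <- demographics_tests(clin, c("symmetric", "skewed", "flat"))
  expect_identical(res$test[res$variable == "symmetric"], "t-test")
  expect_identical(res$test[res$variable == "skewed"], "mann-whitney")
  expect_match(res$test[res$variable == "flat"], "skipped")

  # identical groups: t exactly zero
  clin2 <- data.frame(group = rep(c("patient", "control"), each = 10),
                      gender = rep("M", 20), v = rep(rnorm(10), 2))
  res2 <- demographics_tests(clin2, "v")
  expect_equal(res2$statistic[res2$variable == "v"], 0, tolerance = 1e-12)

  # full separation: Mann-Whitney at its extreme
  x <- c(exp(rnorm(20)), exp(rnorm(20)) + 100)
  clin3 <- data.frame(group = rep(c("patient", "control"), each = 20),
                      gender = rep("M", 40), v = x)
  res3 <- demographics_tests(clin3, "v")
  expect_lt(res3$p[res3$variable == "v"], 1e-6)
})

test_that("the ROI battery reports per-group correlations and comparisons", {
  set.seed(55)
  n <- 60
  clin <- data.frame(
    subject = sprintf("s%02d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    age = rnorm(n, 55, 7), gender = rep(c("M", "F"), n / 2),
    education = rnorm(n, 11, 3), hba1c = rnorm(n, 7, 2)
  )
  roi <- data.frame(subject = clin$subject,
                    hub = rnorm(n) - 0.5 * clin$hba1c)
  bat <- correlation_battery(roi, clin, targets = "hba1c")
  expect_identical(nrow(bat$correlations), 2L)
  expect_identical(unique(bat$correlations$family_size), 1L)
  expect_identical(bat$correlations$p_bonferroni, bat$correlations$p)
  expect_identical(nrow(bat$comparisons), 1L)
  expect_true(all(bat$correlations$r < 0))

  roi_bad <- roi; roi_bad$subject <- rev(roi_bad$subject)
  expect_error(correlation_battery(roi_bad, clin, targets = "hba1c"),
               "misaligned")
})
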