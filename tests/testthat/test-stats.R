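test_that("one-sample t: closed forms, raw/summary agreement, t.test cross-check", {
  expect_equal(one_sample_t(mean = 0, sd = 1, n = 10)$statistic, 0)
  expect_equal(one_sample_t(mean = 0, sd = 1, n = 10)$p.value, 1)
  # hand computation: mean 2, sd 1, n 3 -> t = 2 / (1/sqrt(3))
  tt <- one_sample_t(c(1, 2, 3))
  expect_equal(tt$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)

  set.seed(5)
  x <- rnorm(40, 0.3, 1.2)
  a <- one_sample_t(x)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = length(x))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  # independent route: stats::t.test on the raw values
  ref <- t.test(x, mu = 0)
  expect_equal(a$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p.value, ref$p.value, tolerance = 1e-12)

  expect_error(one_sample_t(mean = 1, sd = 0, n = 5), "sd")
  expect_error(one_sample_t(mean = 1, sd = 1, n = 1), "n >= 2")
})

test_that("2x2 chi-squared: formula oracle, invariances, chisq.test cross-check", {
  # proportional rows are independent
  expect_equal(chi2_prevalence(10, 20, 5, 10)$statistic, 0)
  # hand computation: 60 * (20*20 - 10*10)^2 / 30^4
  expect_equal(chi2_prevalence(20, 10, 10, 20)$statistic,
               60 * (400 - 100)^2 / 30^4)
  expect_equal(chi2_prevalence(20, 10, 10, 20)$statistic, 20 / 3,
               tolerance = 1e-12)
  # transposition and simultaneous row+column swap leave the statistic fixed
  expect_equal(chi2_prevalence(55, 36, 24, 54)$statistic,
               chi2_prevalence(55, 24, 36, 54)$statistic)
  expect_equal(chi2_prevalence(55, 36, 24, 54)$statistic,
               chi2_prevalence(54, 24, 36, 55)$statistic)
  # independent route: stats::chisq.test without continuity correction
  ref <- chisq.test(matrix(c(55, 24, 36, 54), 2L), correct = FALSE)
  mine <- chi2_prevalence(55, 36, 24, 54)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)

  expect_error(chi2_prevalence(0, 0, 3, 4), "marginal")
})

test_that("Pearson correlation matches a naive covariance oracle and cor.test", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  expect_equal(pearson_r(x, -x)$p.value, 0)

  set.seed(8)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  # naive oracle: explicit covariance / sd*sd loops
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cov_ <- sum((a - ma) * (b - mb)) / (n - 1)
  r_naive <- cov_ / (sqrt(sum((a - ma)^2) / (n - 1)) *
                       sqrt(sum((b - mb)^2) / (n - 1)))
  mine <- pearson_r(a, b)
  expect_equal(mine$statistic, r_naive, tolerance = 1e-12)
  ref <- cor.test(a, b)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 pairs")
})

fake_cohort <- function(frontal, occipital, feature = "petalia") {
  out <- tibble::tibble(a = frontal, b = occipital)
  names(out) <- paste0(feature, c("_frontal", "_occipital"))
  out
}

test_that("prevalence tables tabulate quadrants with exact marginals", {
  co <- fake_cohort(c(1, 1, -1, -1), c(-1, 1, -1, 1))
  pt <- prevalence_table(co, "petalia")
  expect_true(all(pt$percent == 25))
  expect_equal(sum(pt$counts), 4L)
  expect_equal(unname(pt$row_percent), c(50, 50))

  co2 <- fake_cohort(rep(-1, 7), rep(-1, 7))
  pt2 <- prevalence_table(co2, "petalia")
  expect_equal(pt2$percent["LO", "RF"], 100)
  expect_equal(sum(pt2$counts), 7L)
  expect_error(prevalence_table(fake_cohort(numeric(0), numeric(0))),
               "empty")
})

test_that("species comparison collapses quadrants or margins before chi-squared", {
  co <- fake_cohort(c(1, 1, -1, -1, -1), c(-1, 1, -1, 1, -1))
  expect_equal(species_comparison(co, co, "petalia",
                                  "RF/LO")$statistic, 0)
  # disjoint extremes: all vs none of 10 each -> 20 by the formula
  all_in <- fake_cohort(rep(-1, 10), rep(-1, 10))
  none_in <- fake_cohort(rep(1, 10), rep(1, 10))
  expect_equal(species_comparison(all_in, none_in, "petalia",
                                  "RF/LO")$statistic,
               20 * (100 - 0)^2 / 10^4)
  # margin collapse: occipital direction only
  all_bend <- fake_cohort(rep(-1, 10), rep(-1, 10), "bending")
  none_bend <- fake_cohort(rep(1, 10), rep(1, 10), "bending")
  st <- species_comparison(all_bend, none_bend, "bending", "LO")
  expect_equal(st$statistic, 20)
  expect_error(species_comparison(co, co, "petalia", "XX"), "unknown")
})

test_that("reconstructed counts honour printed percentages and cohort sizes", {
  expect_identical(reconstruct_counts(c(60.44, 100 - 60.44), 91),
                   c(55L, 36L))
  expect_identical(reconstruct_counts(c(30.77, 100 - 30.77), 78),
                   c(24L, 54L))
})

test_that("the one-sample t test is calibrated at alpha = 0.01 under the null", {
  # 1000 null cohorts sampled from the generator's parameter regime;
  # rejection rate of the occipital-petalia test must sit at the nominal
  # level (1% within +/- 1%)
  n_rep <- 1000L
  n_sub <- 15L
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    draws <- sample_torque_params(n_sub, regime = "null", seed = 20000 + i)
    p <- one_sample_t(draws$petalia_occipital)$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  rate <- 100 * rejections / n_rep
  expect_gte(rate, 0)
  expect_lte(rate, 2)
})

test_that("human-regime cohorts are powered for the occipital petalia test", {
  hits <- 0L
  for (i in seq_len(100L)) {
    draws <- sample_torque_params(91L, regime = "human_like",
                                  seed = 30000 + i)
    if (one_sample_t(draws$petalia_occipital)$p.value < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
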