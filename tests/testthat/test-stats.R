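test_that("residualize returns residuals orthogonal to the design", {
  set.seed(5)
  n <- 80
  cov <- data.frame(age = runif(n, 6, 17), sex = rbinom(n, 1, 0.5),
                    site = factor(sample(1:3, n, TRUE)))
  y <- rnorm(n)
  r <- residualize(y, cov)
  expect_equal(sum(r), 0, tolerance = 1e-8)
  expect_lt(abs(sum(r * cov$age)), 1e-8)
  expect_lt(abs(sum(r * cov$sex)), 1e-8)
  for (lv in levels(cov$site)) {
    expect_lt(abs(sum(r[cov$site == lv])), 1e-8)
  }

  # intercept-only and exact-fit cases
  expect_equal(residualize(y, cov[, 0, drop = FALSE]), y - mean(y))
  expect_equal(residualize(2 * cov$age + 1, cov), rep(0, n),
               tolerance = 1e-10)

  # collinear column is named
  cov$age2 <- cov$age * 2
  expect_error(residualize(y, cov), "age2",
               class = "asymtopo_validation_error")
})

test_that("exclude_outliers drops exact score matches and logs ids", {
  tab <- tiny_table(20)
  tab$decoding[c(4, 9)] <- c(47, 55)
  out <- exclude_outliers(tab, c(47, 55))
  expect_equal(nrow(out), 18L)
  expect_setequal(attr(out, "excluded_ids"), tab$id[c(4, 9)])
  expect_equal(nrow(exclude_outliers(tab)), 20L)
  expect_equal(nrow(exclude_outliers(tab, 150)), 20L)
})

test_that("jitter is bounded, centered and reproducible", {
  x <- rnorm(500)
  j <- jitter_values(x, seed = 3)
  expect_true(all(abs(j - x) <= 1e-5))
  expect_lt(abs(mean(j - x)), 1e-5)
  expect_identical(jitter_values(x, seed = 3), j)
  expect_false(identical(jitter_values(x, seed = 4), j))
})

test_that("cohen_d_from_t implements d = 2t/sqrt(df)", {
  expect_equal(round(cohen_d_from_t(3.40, 420), 3), 0.332)
  expect_equal(cohen_d_from_t(0, 55), 0)
  expect_equal(cohen_d_from_t(2, 100), 0.4)
  expect_error(cohen_d_from_t(1, 0), class = "asymtopo_validation_error")
})

test_that("fit_linear matches the normal-equations oracle", {
  set.seed(9)
  n <- 200
  x <- runif(n)
  y <- 2 * x + rnorm(n, sd = 0.1)
  y <- y - mean(y)
  f <- fit_linear(y, x)
  expect_equal(f$estimate, oracle_ols_slope(y, x), tolerance = 1e-10)
  expect_gt(f$estimate, 1.9)
  expect_lt(f$estimate, 2.1)
  expect_equal(f$df, n - 2L)
  expect_equal(f$d, 2 * f$t / sqrt(f$df))
  expect_true(f$ci[1] < f$estimate && f$estimate < f$ci[2])

  z <- rep(0, n)
  f0 <- fit_linear(z, x)
  expect_equal(c(f0$estimate, f0$t, f0$d), c(0, 0, 0))

  expect_error(fit_linear(y, rep(1, n)),
               class = "asymtopo_degenerate_predictor")
  expect_error(fit_linear(y[1:5], x[1:5]),
               class = "asymtopo_validation_error")
})

test_that("quantile sandpile fit matches the exhaustive basic-solution oracle", {
  set.seed(21)
  for (i in 1:8) {
    for (tau in c(0.5, 0.8, 0.99)) {
      y <- rnorm(12, 100, 15)
      a <- pmax(0, 1 - ((y - 100) / 30)^2) * runif(12) + rnorm(12, sd = 0.05)
      ft <- fit_quantile_sandpile(a, y, tau = tau)
      P <- poly(y, 2)
      orc <- oracle_quantile(cbind(1, P[, 1], P[, 2]), a, tau)
      expect_equal(c(ft$intercept, ft$linear, ft$quadratic),
                   orc$coefficients, tolerance = 1e-6)
    }
  }

  # constant response: intercept only, polynomial terms vanish
  yc <- rnorm(40, 100, 15)
  fc <- fit_quantile_sandpile(rep(0.7, 40), yc, tau = 0.99)
  expect_equal(fc$intercept, 0.7, tolerance = 1e-10)
  expect_equal(fc$linear, 0, tolerance = 1e-8)
  expect_equal(fc$quadratic, 0, tolerance = 1e-8)
  expect_error(fit_quantile_sandpile(rnorm(30), rep(1, 30)),
               class = "asymtopo_degenerate_predictor")
})

test_that("median (tau = 0.5) fit recovers the conditional median line", {
  set.seed(30)
  y <- rnorm(600, 100, 15)
  a <- 0.5 + 0.02 * (y - 100) + rnorm(600, sd = 0.3)  # symmetric noise
  ft <- fit_quantile_sandpile(a, y, tau = 0.5)
  P <- poly(y, 2)
  slope_scale <- 0.02 * sum(P[, 1] * (y - 100)) # linear basis norm conversion
  expect_equal(ft$linear, slope_scale, tolerance = 0.15 * abs(slope_scale))
  expect_lt(abs(ft$quadratic), 0.5)
})

test_that("chained imputation respects observed data and PMM donors", {
  tab <- tiny_table(60)
  imps <- chained_imputation(tab, m = 3, seed = 2)
  expect_length(imps, 3L)
  for (im in imps) expect_identical(im, tab)  # no missingness: untouched

  tabm <- tiny_table(120, miss = 0.15)
  imps2 <- chained_imputation(tabm, m = 2, seed = 4)
  for (im in imps2) {
    expect_false(anyNA(im$decoding))
    obsmask <- !is.na(tabm$decoding)
    expect_equal(im$decoding[obsmask], tabm$decoding[obsmask])
    # predictive-mean matching: every imputed value is an observed value
    expect_true(all(im$decoding[!obsmask] %in% tabm$decoding[obsmask]))
  }
  expect_identical(chained_imputation(tabm, m = 2, seed = 4), imps2)

  bad <- tabm
  bad$decoding <- NA_real_
  expect_error(chained_imputation(bad, 2, 1),
               class = "asymtopo_validation_error")
})

test_that("imputation recovers the column mean under MCAR", {
  means <- vapply(1:10, function(s) {
    tabm <- tiny_table(400, seed = s, miss = 0.1)
    imps <- chained_imputation(tabm, m = 2, seed = s * 13)
    mean(vapply(imps, function(im) mean(im$decoding), numeric(1)))
  }, numeric(1))
  expect_true(all(means > 98 & means < 102))
})

test_that("bootstrap_pool is seeded, pooled and failure-tolerant", {
  set.seed(14)
  dat <- data.frame(y = rnorm(300), x = rnorm(300))
  fit <- function(d, idx) c(slope = oracle_ols_slope(d$y[idx], d$x[idx]))

  bp <- bootstrap_pool(fit, dat, B = 1000, seed = 6)
  full <- oracle_ols_slope(dat$y, dat$x)
  mcse <- sd(bp$draws) / sqrt(nrow(bp$draws))
  expect_lt(abs(bp$pooled - full), max(2 * mcse, 0.02))
  expect_identical(bootstrap_pool(fit, dat, B = 1000, seed = 6)$draws,
                   bp$draws)

  # identity resample recovers the plain fit
  b1 <- bootstrap_pool(fit, dat, B = 1, seed = 1, resample = FALSE)
  expect_equal(unname(b1$pooled), full)

  # failing draws are excluded and counted
  flaky <- function(d, idx) {
    if (idx[1] %% 7 == 0) stop("boom")
    fit(d, idx)
  }
  bf <- bootstrap_pool(flaky, dat, B = 50, seed = 2)
  expect_equal(nrow(bf$draws) + bf$n_failed, 50L)
  expect_gt(bf$n_failed, 0L)
})

test_that("pooling over imputations averages fits and floors p at 1/B", {
  same <- matrix(2.5, nrow = 4, ncol = 1, dimnames = list(NULL, "est"))
  p <- pool_over_imputations(list(same, same))
  expect_equal(unname(p$pooled), 2.5)
  expect_equal(p$count, 8L)
  expect_equal(unname(p$p_bootstrap), 1 / 4)  # no draw crosses zero

  known <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "est"))
  expect_equal(unname(pool_over_imputations(list(known))$pooled), 2)
  expect_equal(pool_over_imputations(list(known[1:2, , drop = FALSE],
                                          known[1:2, , drop = FALSE]))$count, 4L)
  expect_error(pool_over_imputations(list()),
               class = "asymtopo_validation_error")
})
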