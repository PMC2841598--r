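test_that("restricted fits recover exact autoregressions", {
  # noiseless AR(1), coefficient 0.5
  x <- numeric(30); x[1] <- 1
  for (t in 2:30) x[t] <- 0.5 * x[t - 1]
  f <- fit_restricted(x, 1)
  expect_equal(unname(f$coef[2]), 0.5, tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)
  # deterministic linear recurrence x_t = 1 + x_{t-1}
  f2 <- fit_restricted(c(1, 2, 3, 4, 5), 1)
  expect_equal(unname(f2$coef), c(1, 1), tolerance = 1e-10)
  expect_lt(f2$rss, 1e-20)
  # alternating series: solve the normal equations by hand -> x_t = 3 - x_{t-1}
  f3 <- fit_restricted(c(1, 2, 1, 2, 1, 2), 1)
  expect_equal(unname(f3$coef), c(3, -1), tolerance = 1e-10)
  expect_lt(f3$rss, 1e-20)
  expect_error(fit_restricted(c(1, 2, 3), 1), "too short")
})

test_that("unrestricted fits handle uninformative and perfect regressors", {
  set.seed(8)
  x <- rnorm(40)
  f0 <- fit_restricted(x, 2)
  fu <- fit_unrestricted(x, rep(0, 40), 2)
  expect_true(fu$degenerate)            # zero column: rank deficient
  expect_equal(fu$rss, f0$rss, tolerance = 1e-10)
  # x is a lagged copy of y: perfect cross prediction
  y <- rnorm(50)
  x2 <- c(0, y[-50])
  fp <- fit_unrestricted(x2, y, 1)
  expect_lt(fp$rss, 1e-18)
  expect_equal(unname(fp$coef[3]), 1, tolerance = 1e-8)
})

test_that("nested-model inequality holds against an independent OLS oracle", {
  set.seed(123)
  for (rep in 1:25) {
    T <- 50; p <- 2
    x <- rnorm(T); y <- rnorm(T)
    fr <- fit_restricted(x, p)
    fu <- fit_unrestricted(x, y, p)
    expect_lte(fu$rss, fr$rss + 1e-10)
    # oracle: explicit normal-equation solve
    rows <- (p + 1):T
    X0 <- cbind(1, x[rows - 1], x[rows - 2])
    X1 <- cbind(X0, y[rows - 1], y[rows - 2])
    expect_equal(fr$rss, bf_ols_rss(X0, x[rows]), tolerance = 1e-8)
    expect_equal(fu$rss, bf_ols_rss(X1, x[rows]), tolerance = 1e-8)
  }
})

test_that("granger_statistic implements the F formula and its edge cases", {
  st <- granger_statistic(3, 1, 1, 12)
  expect_equal(st$statistic, 18)
  expect_equal(st$df1, 1L)
  expect_equal(st$df2, 9L)
  same <- granger_statistic(2.5, 2.5, 2, 30)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # S at the F(1, 9) 0.95 quantile has p-value 0.05
  S <- qf(0.95, 1, 9)
  st2 <- granger_statistic(1 + S / 9, 1, 1, 12)
  expect_equal(st2$p_value, 0.05, tolerance = 1e-10)
  expect_warning(z <- granger_statistic(1, 0, 1, 12), "perfect")
  expect_equal(z$statistic, Inf)
  expect_equal(z$p_value, 0)
})

test_that("AIC lag selection prefers parsimony and finds true lags", {
  set.seed(10)
  expect_equal(select_lag_aic(rnorm(30), rnorm(30), p_max = 1)$p, 1L)
  # white noise: penalty dominates -> modal selected lag 1
  picks <- sapply(1:40, function(i) {
    set.seed(i)
    select_lag_aic(rnorm(200), rnorm(200), p_max = 4)$p
  })
  expect_equal(as.integer(names(which.max(table(picks)))), 1L)
  # lag-3 cross drive is found: selected p >= 3 in >= 90% of replicates
  hits <- sapply(1:40, function(i) {
    sp <- var_spec(2, data.frame(target = c(1, 2, 2), source = c(1, 2, 1),
                                 lag = c(1, 1, 3), coef = c(0.4, 0.4, 0.8)))
    d <- simulate_var(sp, T = 500, seed = 1000 + i)$data
    select_lag_aic(d[2, ], d[1, ], p_max = 4)$p >= 3
  })
  expect_gte(mean(hits), 0.9)
})

test_that("granger_test detects perfect lagged causality and not its reverse", {
  set.seed(21)
  y <- rnorm(100)
  x <- c(0, y[-100])
  r <- granger_test(x, y)
  expect_true(r$reject)
  expect_equal(r$alpha, 0.05)     # default significance level
  rev <- granger_test(y, x, p = 1)
  expect_false(rev$reject)
})

test_that("degenerate series yield a reasoned no-edge result, not an error", {
  r <- suppressWarnings(granger_test(rep(1, 30), rep(2, 30)))
  expect_false(r$reject)
  expect_false(is.null(r$reason))
  expect_equal(r$statistic, 0)
})

test_that("type-I error is near alpha under independence (reduced replicate run)", {
  rej <- vapply(1:400, function(i) {
    set.seed(20000 + i)
    granger_test(rnorm(100), rnorm(100), p = "auto", p_max = 4)$reject
  }, logical(1))
  # 99% binomial band around 0.05 at n = 400 is ~ +/- 0.028; widen for
  # lag-selection effects as in the full calibration run
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("pairwise_causality performs n(n-1) tests with a zero diagonal", {
  set.seed(3)
  m <- matrix(rnorm(6 * 40), 6, 40)
  d <- pairwise_causality(m, p = 1)
  expect_equal(attr(d, "n_tests"), 30L)
  expect_true(all(diag(unclass(d)) == 0))
  expect_true(all(unclass(d) >= 0))
  # a constant row is degenerate everywhere but must not crash the scan
  m2 <- rbind(m[1:3, ], const = rep(1, 40))
  d2 <- pairwise_causality(m2, p = 1)
  expect_equal(attr(d2, "n_tests"), 12L)
  expect_true(all(unclass(d2)[, "const"] == 0))
})

test_that("pairwise scan recovers the dataset-2 structure at T = 1000", {
  d <- pairwise_causality(dataset2(T = 1000, seed = 77)$data, p = "auto")
  a <- symmetrize_max(d)
  te <- true_edges(dataset2(T = 5)$spec)
  for (r in seq_len(nrow(te))) {
    expect_gt(unclass(a)[te[r, 1], te[r, 2]], 0)
  }
})
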