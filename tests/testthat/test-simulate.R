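test_that("var_spec validates its inputs", {
  expect_error(var_spec(3, data.frame(target = 1, source = 2, lag = 0, coef = 1)),
               "lag")
  expect_error(var_spec(3, data.frame(target = 1, source = 4, lag = 1, coef = 1)),
               "indices")
  expect_error(var_spec(3, data.frame(target = 1, source = 2, lag = 1, coef = NaN)),
               "non-finite")
  expect_error(simulate_var(var_spec(2, data.frame(target = 1, source = 2,
                                                   lag = 5, coef = 0.1)),
                            T = 10, burn_in = 3),
               "configuration")
})

test_that("zero-noise zero-initial systems stay identically zero", {
  sp <- var_spec(2, data.frame(target = c(1, 2), source = c(1, 1),
                               lag = c(1, 2), coef = c(0.5, 0.8)),
                 noise_sd = 0)
  expect_equal(simulate_var(sp, T = 20, seed = 3)$data,
               matrix(0, 2, 20, dimnames = list(c("x1", "x2"),
                                                paste0("t", 1:20))))
  expect_true(all(dataset2(T = 15, seed = 9, strong = 0.8)$spec$noise_sd == 1))
  z <- simulate_var(var_spec(4, dataset2(T = 5)$spec$terms, noise_sd = 0),
                    T = 15, seed = 2)
  expect_true(all(z$data == 0))
})

test_that("simulation is bitwise deterministic in (spec, T, seed, burn_in)", {
  sp <- var_spec(3, data.frame(target = 2, source = 1, lag = 2, coef = 0.7))
  a <- simulate_var(sp, T = 50, seed = 7, burn_in = 10)
  b <- simulate_var(sp, T = 50, seed = 7, burn_in = 10)
  expect_identical(a$data, b$data)
  c <- simulate_var(sp, T = 50, seed = 8, burn_in = 10)
  expect_false(identical(a$data, c$data))
})

test_that("stable AR(1) reaches its closed-form stationary variance", {
  # x_t = 0.5 x_{t-1} + e_t  =>  var = 1 / (1 - 0.25) = 4/3
  sp <- var_spec(1, data.frame(target = 1, source = 1, lag = 1, coef = 0.5))
  x <- simulate_var(sp, T = 5000, seed = 11)$data[1, ]
  expect_lt(abs(var(x) - 4 / 3) / (4 / 3), 0.10)
})

test_that("divergent specs are caught by the runtime guard", {
  sp <- var_spec(1, data.frame(target = 1, source = 1, lag = 1, coef = 1.6))
  expect_error(simulate_var(sp, T = 300, seed = 1), "divergent")
})

test_that("benchmark datasets encode the stated causal structure", {
  expect_equal(true_edges(dataset1(T = 5)$spec),
               cbind(i = c(1L, 1L, 1L, 4L), j = c(2L, 3L, 4L, 5L)))
  expect_equal(true_edges(dataset2(T = 5)$spec),
               cbind(i = c(1L, 1L, 2L, 3L), j = c(2L, 4L, 3L, 4L)))
  d3 <- dataset3(T = 5)
  expect_equal(nrow(d3$data), 6L)
  expect_equal(true_edges(d3$spec),
               cbind(i = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L),
                     j = c(2L, 6L, 3L, 5L, 4L, 6L, 5L, 6L)))
  # lag structure as stated: spot-check the distinctive lags
  tr <- dataset1(T = 5)$spec$terms
  expect_equal(tr$lag[tr$target == 3 & tr$source == 1], 3L)
  tr3 <- d3$spec$terms
  expect_equal(tr3$lag[tr3$target == 6 & tr3$source == 3], 3L)
})

test_that("true-edge extractor equals a brute-force pass over terms", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:6, 1)
    k <- sample(0:8, 1)
    terms <- data.frame(target = sample(n, k, TRUE), source = sample(n, k, TRUE),
                        lag = sample(3, k, TRUE), coef = runif(k, -0.3, 0.3))
    sp <- var_spec(n, terms)
    expected <- unique(t(apply(
      terms[terms$target != terms$source, c("target", "source"), drop = FALSE],
      1, function(r) sort(r))))
    got <- true_edges(sp)
    if (nrow(got) == 0) {
      expect_true(nrow(terms[terms$target != terms$source, ]) == 0)
    } else {
      expect_setequal(paste(got[, 1], got[, 2]),
                      paste(expected[, 1], expected[, 2]))
    }
  }
})

test_that("combined system embeds the three datasets disjointly", {
  cs <- combined_system(T = 120, seed = 4)
  expect_equal(nrow(cs$data), 15L)
  # no cross-set terms
  tr <- cs$spec$terms
  set_of <- function(i) findInterval(i, c(1, 6, 10))
  expect_true(all(set_of(tr$target) == set_of(tr$source)))
  # rows 1-5 reproduce dataset1 exactly (stream-per-process seeding)
  expect_identical(cs$data[1:5, ], dataset1(T = 120, seed = 4)$data)
})
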