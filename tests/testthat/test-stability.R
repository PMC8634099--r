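test_that("bootstrap of a constant estimator has zero-width intervals", {
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  boot <- nonparametric_bootstrap(x, function(d) c(k = 2.5), B = 50, seed = 1)
  expect_equal(unname(boot$lower), 2.5)
  expect_equal(unname(boot$upper), 2.5)
  expect_equal(unname(boot$prop_zero), 0)
  boot0 <- nonparametric_bootstrap(x, function(d) c(z = 0), B = 50, seed = 1)
  expect_equal(unname(boot0$prop_zero), 1)
})

test_that("bootstrap machinery is bit-reproducible from its seed", {
  set.seed(999)  # outer state must not matter
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  est <- function(d) colMeans(d)
  b1 <- nonparametric_bootstrap(x, est, B = 100, seed = 42)
  set.seed(123)
  b2 <- nonparametric_bootstrap(x, est, B = 100, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$lower, b2$lower)
  cs1 <- case_dropping_cs(x, function(d) colMeans(d), grid = c(0.2, 0.5),
                          B = 20, seed = 7)
  cs2 <- case_dropping_cs(x, function(d) colMeans(d), grid = c(0.2, 0.5),
                          B = 20, seed = 7)
  expect_identical(cs1$correlations, cs2$correlations)
})

test_that("bootstrap quantile intervals achieve near-nominal coverage", {
  # estimator = sample mean of a uniform column; the 95% interval should
  # cover the true mean 0.5 in about 95% of outer repetitions
  n <- 60
  covered <- 0L
  for (rep_i in 1:200) {
    set.seed(3000 + rep_i)
    x <- matrix(runif(n), n, 1, dimnames = list(NULL, "u"))
    boot <- nonparametric_bootstrap(x, function(d) c(m = mean(d[, 1])),
                                    B = 1000, seed = rep_i)
    if (boot$lower <= 0.5 && 0.5 <= boot$upper) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.90)
  expect_lte(covered / 200, 0.99)
})

test_that("failed replicates are tolerated up to five percent", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  flaky <- local({
    i <- 0
    function(d) {
      i <<- i + 1
      if (i %% 30 == 0) stop("boom")
      c(m = mean(d))
    }
  })
  boot <- nonparametric_bootstrap(x, flaky, B = 100, seed = 5)
  expect_equal(boot$n_failed, 3L)
  expect_false(anyNA(boot$lower))
  mostly_failing <- local({
    i <- 0
    function(d) {
      i <<- i + 1
      if (i > 1 && i %% 2 == 0) stop("no")
      c(m = mean(d))
    }
  })
  expect_error(nonparametric_bootstrap(x, mostly_failing, B = 100, seed = 5),
               "failed")
})

test_that("paired difference test matches hand-computed quantiles", {
  reps <- cbind(a = c(3, 5, 7, 9, 11), b = c(2, 3, 4, 5, 6))
  boot <- structure(list(statistics = c("a", "b"),
                         point = c(a = 7, b = 4),
                         replicates = reps, B = 5, seed = 1,
                         n_failed = 0L, level = 0.95),
                    class = "bootstrap_result")
  res <- bootstrap_difference_test(boot, "a", "b")
  # paired differences 1..5; type-7 quantiles: h = 4p + 1
  expect_equal(res$lower, 1.1)   # p = .025 -> h = 1.1
  expect_equal(res$upper, 4.9)   # p = .975 -> h = 4.9
  expect_equal(res$difference, 3)
  expect_true(res$significant)
  # a statistic against itself: zero difference, nonsignificant
  same <- bootstrap_difference_test(boot, "a", "a")
  expect_equal(same$difference, 0)
  expect_false(same$significant)
  expect_error(bootstrap_difference_test(boot, "a", "zzz"), "paired")
})

test_that("difference-test significance is monotone in alpha", {
  set.seed(17)
  x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, "a"] <- x[, "a"] + 0.25
  boot <- nonparametric_bootstrap(x, function(d) colMeans(d), B = 400,
                                  seed = 2)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    r05 <- bootstrap_difference_test(boot, pair[1], pair[2], alpha = 0.05)
    r10 <- bootstrap_difference_test(boot, pair[1], pair[2], alpha = 0.10)
    if (r05$significant) expect_true(r10$significant)
    expect_lte(r05$lower, r10$lower)
    expect_gte(r05$upper, r10$upper)
  }
})

test_that("case-dropping CS hits the grid extremes for (un)stable statistics", {
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("v", 1:4)))
  # data-independent statistic: perfectly stable, CS = max of grid
  stable <- function(d) c(a = 1, b = 2, c = 3, d = 4)
  cs <- case_dropping_cs(x, stable, grid = c(0.25, 0.5, 0.75), B = 20,
                         seed = 1)
  expect_equal(unname(cs$cs), 0.75)
  # statistic = a single random row: correlations hover near zero, CS = 0
  unstable <- function(d) d[sample.int(nrow(d), 1), ]
  cs0 <- case_dropping_cs(x, unstable, grid = c(0.1, 0.3), B = 40, seed = 2)
  expect_equal(unname(cs0$cs), 0)
})

test_that("infeasible proportions (subsample <= p) are marked, not scored", {
  x <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  cs <- case_dropping_cs(x, function(d) colMeans(d), grid = c(0.2, 0.9),
                         B = 10, seed = 3)
  expect_equal(cs$infeasible, 0.9)
  expect_true(all(is.na(cs$correlations[[format(0.9)]])))
})
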