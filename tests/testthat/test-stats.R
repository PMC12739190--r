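test_that("Pearson correlation matches the brute-force covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # independent oracle: direct evaluation of the covariance quotient
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(brute, 0.8)
  expect_equal(pearson_with_ci(x, y)$r, brute)
})

test_that("perfect linear dependence gives r = +/-1", {
  x <- c(0.3, 1.9, 4.4, 7.2, 9)
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
})

test_that("degenerate correlation inputs raise informative errors", {
  expect_error(pearson_with_ci(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_error(pearson_with_ci(1:3, c(2, 4, 6)), "n >= 4")
  expect_error(pearson_with_ci(1:4, 1:5), "equal length")
})

test_that("the Fisher interval brackets r and shrinks like 1/sqrt(n)", {
  set.seed(501)
  x <- stats::rnorm(400); y <- x + stats::rnorm(400)
  res_n <- pearson_with_ci(x, y)
  expect_true(res_n$ci_low <= res_n$r && res_n$r <= res_n$ci_high)
  res_small <- pearson_with_ci(x[1:100], y[1:100])
  expect_gt(res_small$ci_high - res_small$ci_low,
            res_n$ci_high - res_n$ci_low)
  expect_lt(res_n$p_value, 1e-10)
})

test_that("correlation is affine-invariant and flips sign under negation", {
  set.seed(502)
  for (i in 1:10) {
    x <- stats::rnorm(50); y <- stats::rnorm(50, x)
    r0 <- pearson_with_ci(x, y)$r
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1, 0, 10)
    expect_equal(pearson_with_ci(a * x + b, y)$r, r0)
    expect_equal(pearson_with_ci(x, a * y + b)$r, r0)
    expect_equal(pearson_with_ci(-x, y)$r, -r0)
  }
})

test_that("variance shares always sum to exactly 100", {
  set.seed(503)
  for (i in 1:8) {
    n <- 50
    co <- make_cohort(S = stats::runif(n, 0, 100), A = stats::runif(n, 0, 100),
                      K = stats::runif(n, 0, 100), Q = stats::runif(n, 0, 100))
    vs <- variance_decomposition(co, weight_config())
    expect_equal(sum(unlist(vs)), 100, tolerance = 1e-9)
  }
})

test_that("two exchangeable equal-variance terms split the variance 50/50", {
  set.seed(504)
  S <- stats::runif(200, 0, 100)
  A <- rev(S)  # same marginal sample: variances agree exactly
  co <- make_cohort(S = S, A = A, K = rep(40, 200), Q = rep(60, 200))
  vs <- variance_decomposition(co, weight_config(0.5, 0.5, 0, 0))
  expect_equal(vs$share_S, vs$share_A, tolerance = 1e-9)
  expect_equal(vs$share_S, 50, tolerance = 1e-6)
  expect_equal(vs$share_K + vs$share_Q, 0, tolerance = 1e-9)
})

test_that("Monte Carlo shares match the independence closed form", {
  co <- generate_profiles(independent_config(n = 10000L, seed = 22))
  w <- weight_config()
  vs <- variance_decomposition(co, w)
  # closed form under independent components: share_i = w_i^2 s_i^2 / sum_j
  beta_var <- function(a, b) a * b / ((a + b)^2 * (a + b + 1))
  cfg <- independent_config(n = 10000L, seed = 22)
  sigma2 <- 100^2 * c(beta_var(cfg$alpha_S, cfg$beta_S),
                      beta_var(cfg$alpha_A, cfg$beta_A),
                      beta_var(cfg$alpha_K, cfg$beta_K),
                      beta_var(cfg$alpha_Q, cfg$beta_Q))
  wv <- unclass(w)^2 * sigma2
  closed <- 100 * wv / sum(wv)
  expect_true(all(abs(unlist(vs) - closed) < 2))
})

test_that("degenerate cohorts are rejected by the decomposition", {
  co <- make_cohort(S = c(50, 50), A = c(50, 50), K = c(50, 50), Q = c(50, 50))
  expect_error(variance_decomposition(co), "variance is zero")
  expect_error(variance_decomposition(co[1, ]), ">= 2 profiles")
})

test_that("group contrast reproduces hand-computed Cohen's d", {
  gc <- group_contrast(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, mean difference = -3
  expect_equal(gc$cohens_d, -3)
  expect_equal(abs(gc$cohens_d), 3)
})

test_that("identical groups give a null contrast; separated groups an extreme one", {
  g <- c(10, 12, 15, 13)
  gc <- group_contrast(g, g)
  expect_equal(gc$t_statistic, 0)
  expect_equal(gc$cohens_d, 0)
  set.seed(505)
  a <- stats::rnorm(20, 0, 0.01); b <- stats::rnorm(20, 10, 0.01)
  gc2 <- group_contrast(a, b)
  expect_lt(gc2$p_value, 1e-12)
  expect_gt(abs(gc2$cohens_d), 50)
  expect_error(group_contrast(1, c(2, 3)), "at least 2")
})
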