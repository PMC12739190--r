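test_that("perturbing a weight by factor 1 is the identity", {
  w <- weight_config()
  expect_equal(unclass(perturb_weights(w, "S", 1)), unclass(w))
})

test_that("perturbed weights match hand renormalization", {
  up <- perturb_weights(weight_config(), "S", 1.2)
  expect_equal(unclass(up),
               c(w_S = 0.48, w_A = 0.2 * 0.52 / 0.6,
                 w_K = 0.25 * 0.52 / 0.6, w_Q = 0.15 * 0.52 / 0.6))
  down <- perturb_weights(weight_config(), "S", 0.75)
  expect_equal(unclass(down),
               c(w_S = 0.30, w_A = 0.2 * 0.7 / 0.6,
                 w_K = 0.25 * 0.7 / 0.6, w_Q = 0.15 * 0.7 / 0.6))
})

test_that("perturbed weights always sum to one", {
  set.seed(601)
  for (i in 1:30) {
    w4 <- stats::runif(4, 0.05, 1); w4 <- w4 / sum(w4)
    w <- weight_config(w4[1], w4[2], w4[3], w4[4])
    comp <- sample(c("S", "A", "K", "Q"), 1)
    f <- stats::runif(1, 0.2, 1 / max(w4) * 0.99)
    p <- perturb_weights(w, comp, f)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("infeasible perturbations are refused", {
  expect_error(perturb_weights(weight_config(), "S", 2.6), "infeasible")
  expect_error(perturb_weights(weight_config(), "X", 1.1), "one of")
  expect_error(perturb_weights(weight_config(), "S", -1), "positive")
})

test_that("tornado rows are the four components sorted by decreasing swing", {
  co <- generate_profiles(small_config(1000, seed = 61))
  tor <- tornado_analysis(co, weight_config(), pct = 0.2)
  expect_setequal(tor$component, c("S", "A", "K", "Q"))
  expect_true(all(diff(tor$delta_range) <= 0))
  expect_true(all(tor$weight_low < tor$weight_high))
  expect_true(all(tor$delta_range >= 0))
})

test_that("zero perturbation produces all-zero swings", {
  co <- generate_profiles(small_config(200, seed = 62))
  tor <- tornado_analysis(co, weight_config(), pct = 0)
  expect_equal(tor$delta_range, rep(0, 4))
})

test_that("tornado matches a brute-force recomputation on a hand-built cohort", {
  # S constant across profiles, others varying
  co <- make_cohort(S = rep(60, 10),
                    A = c(5, 95, 20, 80, 35, 65, 50, 10, 90, 45),
                    K = c(90, 10, 80, 20, 70, 30, 60, 40, 50, 55),
                    Q = c(15, 85, 25, 75, 35, 65, 45, 55, 5, 95))
  base <- weight_config()
  tor <- tornado_analysis(co, base, pct = 0.2)
  for (comp in c("S", "A", "K", "Q")) {
    m <- vapply(c(0.8, 1.2), function(f) {
      w <- perturb_weights(base, comp, f)
      mean(w[["w_S"]] * co$sugar_S + w[["w_A"]] * co$acid_A +
             w[["w_K"]] * (100 - co$protective_K) +
             w[["w_Q"]] * (100 - co$quality_Q))
    }, numeric(1))
    row <- tor[tor$component == comp, ]
    expect_equal(row$mean_ddrs_low, m[1])
    expect_equal(row$mean_ddrs_high, m[2])
    expect_equal(row$delta_range, abs(m[2] - m[1]))
  }
})

test_that("the swing obeys the exact lever-arm identity", {
  # mean DDRS is linear in the weights, so perturbing component i by
  # +/-pct with proportional renormalization swings the mean by exactly
  # 2 * pct * w_i * |m_i - rest_i|, where m_i is the mean of the i-th
  # (risk-direction) term on the 0-100 scale and rest_i the weighted mean
  # of the other three terms
  set.seed(603)
  co <- make_cohort(S = stats::runif(300, 20, 100), A = stats::runif(300, 0, 60),
                    K = stats::runif(300, 30, 90), Q = stats::runif(300, 10, 70))
  w <- unclass(weight_config())
  m <- c(S = mean(co$sugar_S), A = mean(co$acid_A),
         K = mean(100 - co$protective_K), Q = mean(100 - co$quality_Q))
  pct <- 0.2
  tor <- tornado_analysis(co, weight_config(), pct = pct)
  for (comp in c("S", "A", "K", "Q")) {
    wi <- w[[paste0("w_", comp)]]
    rest <- sum(w[paste0("w_", setdiff(names(m), comp))] *
                  m[setdiff(names(m), comp)]) / (1 - wi)
    expect_equal(tor$delta_range[tor$component == comp],
                 2 * pct * wi * abs(m[[comp]] - rest))
  }
})

test_that("sugar-weight experiment matches hand arithmetic on a toy cohort", {
  co <- make_cohort(S = c(80, 40), A = c(20, 60), K = c(30, 70), Q = c(50, 50))
  base <- weight_config()
  m <- vapply(c(0.30, 0.50), function(ws) {
    w <- perturb_weights(base, "S", ws / 0.40)
    mean(score_cohort(co, w))
  }, numeric(1))
  expected <- 100 * (m[2] - m[1]) / m[1]
  expect_equal(as.numeric(sugar_weight_experiment(co, base)), expected)
})

test_that("the experiment is weight-invariant on the diagonal cohort", {
  # profiles with S = A = 100-K = 100-Q score identically under any weights
  co <- make_cohort(S = c(30, 70), A = c(30, 70), K = c(70, 30), Q = c(70, 30))
  expect_equal(as.numeric(sugar_weight_experiment(co)), 0)
})

test_that("a zero-mean cohort makes the percent change undefined", {
  co <- make_cohort(S = c(0, 0), A = c(0, 0), K = c(100, 100), Q = c(100, 100))
  expect_error(sugar_weight_experiment(co), "undefined")
})
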