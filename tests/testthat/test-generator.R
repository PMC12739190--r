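test_that("generation is reproducible: same config, identical cohort", {
  cfg <- small_config(400, seed = 123)
  a <- generate_profiles(cfg)
  b <- generate_profiles(cfg)
  expect_identical(a, b)
  # serialized form is byte-identical too
  fa <- tempfile(); fb <- tempfile()
  write_cohort_csv(a, fa); write_cohort_csv(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # and a different seed gives a different cohort
  expect_false(identical(a, generate_profiles(small_config(400, seed = 124))))
})

test_that("generated values respect their type bounds for random configs", {
  set.seed(401)
  for (i in 1:12) {
    cfg <- generator_config(
      n_profiles = 300L, seed = sample.int(1e6, 1),
      latent_shape_a = stats::runif(1, 0.5, 8),
      latent_shape_b = stats::runif(1, 0.5, 8),
      alpha_S = stats::runif(1, 2, 5), beta_S = stats::runif(1, 3, 6),
      alpha_A = stats::runif(1, 2, 5), beta_A = stats::runif(1, 3, 6),
      alpha_K = stats::runif(1, 2, 5), beta_K = stats::runif(1, 3, 6),
      alpha_Q = stats::runif(1, 2, 5), beta_Q = stats::runif(1, 3, 6),
      lambda_S = stats::runif(1), lambda_A = stats::runif(1),
      lambda_K = stats::runif(1), lambda_Q = stats::runif(1),
      lambda_M = stats::runif(1),
      sigma_dpi = stats::runif(1, 0, 30), sigma_hei = stats::runif(1, 0, 30))
    co <- generate_profiles(cfg)
    for (col in c("sugar_S", "acid_A", "protective_K", "quality_Q", "dpi", "hei")) {
      expect_true(all(co[[col]] >= 0 & co[[col]] <= 100), label = col)
    }
    expect_true(all(co$medas_raw %in% 0:14))
  }
})

test_that("saturated loadings with a degenerate latent factor pin all outputs", {
  cfg <- generator_config(n_profiles = 200L, seed = 5,
                          latent_shape_a = 1e6, latent_shape_b = 1,
                          lambda_S = 1, lambda_A = 1, lambda_K = 1,
                          lambda_Q = 1, sigma_dpi = 0, sigma_hei = 0)
  co <- generate_profiles(cfg)
  expect_true(all(co$sugar_S < 0.5) && all(co$acid_A < 0.5))
  expect_true(all(co$protective_K > 99.5) && all(co$quality_Q > 99.5))
  expect_true(all(co$dpi > 99.5) && all(co$hei > 99.5))
})

test_that("zero loadings give uncorrelated components", {
  co <- generate_profiles(independent_config(n = 10000L))
  comps <- co[c("sugar_S", "acid_A", "protective_K", "quality_Q")]
  r <- stats::cor(comps)
  off <- r[upper.tri(r)]
  expect_true(all(abs(off) < 3 / sqrt(nrow(co))))
})

test_that("positive loadings couple components to the latent factor", {
  # with loadings > 0, K tracks H and S tracks (1 - H): on a large sample
  # corr(K, S) must be clearly negative while independent noise keeps it
  # away from -1
  co <- generate_profiles(small_config(5000, seed = 31,
                                       lambda_S = 0.7, lambda_K = 0.7,
                                       lambda_Q = 0.7))
  r <- stats::cor(co$protective_K, co$sugar_S)
  expect_lt(r, -0.3)
  expect_gt(r, -1)
  expect_gt(stats::cor(co$protective_K, co$quality_Q), 0.3)
  # the calibrated generator couples more weakly but in the same directions
  cal <- generate_profiles(small_config(5000, seed = 31))
  expect_lt(stats::cor(cal$protective_K, cal$sugar_S), -0.05)
})

test_that("invalid configs fail naming the violated bound", {
  expect_error(generator_config(alpha_S = 1.5), "alpha_S.*\\[2, 5\\]")
  expect_error(generator_config(beta_Q = 7), "beta_Q.*\\[3, 6\\]")
  expect_error(generator_config(lambda_K = 1.2), "lambda_K.*\\[0, 1\\]")
  expect_error(generator_config(sigma_dpi = -1), "sigma_dpi")
  expect_error(generator_config(n_profiles = 0), "n_profiles")
  expect_error(generator_config(latent_shape_a = -2), "latent_shape_a")
})

test_that("generator config round-trips through YAML", {
  cfg <- small_config(50, seed = 77, lambda_S = 0.5)
  f <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-10)
  expect_identical(generate_profiles(back), generate_profiles(cfg))
})

test_that("scenario presets produce their defining index levels", {
  h <- generate_scenario_cohort("healthy", n = 2000, seed = 43)
  idx_h <- validate_indices(h)
  expect_true(all(colMeans(idx_h) >= 70))
  u <- generate_scenario_cohort("unhealthy", n = 2000, seed = 44)
  idx_u <- validate_indices(u)
  expect_true(all(colMeans(idx_u) <= 30))
  m <- generate_scenario_cohort("mixed", n = 2000, seed = 45)
  idx_m <- validate_indices(m)
  # mixed pattern: moderate MEDAS/HEI but low phytochemical intake
  expect_true(abs(mean(idx_m$medas_norm) - 55) < 8)
  expect_true(abs(mean(idx_m$dpi) - 25) < 8)
  expect_true(abs(mean(idx_m$hei) - 65) < 8)
})

test_that("scenario cohorts are deterministic and size-exact", {
  a <- generate_scenario_cohort("healthy", n = 150, seed = 9)
  b <- generate_scenario_cohort("healthy", n = 150, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a), 150L)
  empty <- generate_scenario_cohort("mixed", n = 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_error(generate_scenario_cohort("vegan", n = 10, seed = 1),
               "healthy.*unhealthy.*mixed")
})
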