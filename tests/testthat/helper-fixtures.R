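# Shared test fixtures: tiny hand-built cohorts and small generator configs.

# A cohort built directly from component values (no simulation).
make_cohort <- function(S, A, K, Q, medas = NULL, dpi = NULL, hei = NULL) {
  n <- length(S)
  data.frame(
    sugar_S = S, acid_A = A, protective_K = K, quality_Q = Q,
    medas_raw = if (is.null(medas)) rep(7L, n) else medas,
    dpi = if (is.null(dpi)) K else dpi,
    hei = if (is.null(hei)) Q else hei
  )
}

corner_max <- list(sugar_S = 100, acid_A = 100, protective_K = 0, quality_Q = 0)
corner_min <- list(sugar_S = 0, acid_A = 0, protective_K = 100, quality_Q = 100)
midpoint <- list(sugar_S = 50, acid_A = 50, protective_K = 50, quality_Q = 50)

small_config <- function(n = 500L, seed = 11L, ...) {
  generator_config(n_profiles = n, seed = seed, ...)
}

# Config with all latent loadings zero: components are independent draws.
independent_config <- function(n = 10000L, seed = 21L) {
  generator_config(n_profiles = n, seed = seed,
                   lambda_S = 0, lambda_A = 0, lambda_K = 0, lambda_Q = 0,
                   lambda_M = 0)
}
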