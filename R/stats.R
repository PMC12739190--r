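# Inferential statistics of the study: Pearson correlations with Fisher-z
# confidence intervals, covariance-based variance decomposition of the
# composite score, and two-group contrasts (Welch t + Cohen's d).

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson coefficient with a two-sided confidence interval from the
#' Fisher z-transform, `atanh(r) +/- z_crit / sqrt(n - 3)` back-transformed,
#' and a two-sided p-value from the t-distribution with `n - 2` degrees of
#' freedom (as computed by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, neither constant.
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row: `r`, `ci_low`, `ci_high`, `p_value`,
#'   `n`.
#' @examples
#' pearson_with_ci(1:5, c(2, 1, 4, 3, 5))  # r = 0.8
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stop("x and y must be numeric with no missing values", call. = FALSE)
  }
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4L) {
    stop(sprintf("insufficient data: need n >= 4 observations, got %d", n),
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: input is constant", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  data.frame(r = unname(ct$estimate),
             ci_low = ct$conf.int[1L], ci_high = ct$conf.int[2L],
             p_value = ct$p.value, n = n)
}

#' Correlations between DDRS and the three dietary indices
#'
#' Convenience wrapper computing [pearson_with_ci()] of a DDRS vector
#' against normalized MEDAS, DPI and HEI of the same cohort.
#'
#' @param cohort Profile data frame containing `medas_raw`, `dpi`, `hei`.
#' @param ddrs Numeric DDRS vector aligned with `cohort` rows.
#' @param level Confidence level.
#' @return Data frame with rows `medas`, `dpi`, `hei` and columns
#'   `index`, `r`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
index_correlations <- function(cohort, ddrs, level = 0.95) {
  idx <- validate_indices(cohort)
  res <- rbind(pearson_with_ci(ddrs, idx$medas_norm, level),
               pearson_with_ci(ddrs, idx$dpi, level),
               pearson_with_ci(ddrs, idx$hei, level))
  cbind(index = c("medas", "dpi", "hei"), res)
}

#' Covariance-based variance decomposition of DDRS
#'
#' Writes DDRS as the sum of its four weighted terms
#' `w_S*S + w_A*A + w_K*(100-K) + w_Q*(100-Q)` and attributes its variance
#' to each term via covariance shares,
#' `share_i = 100 * Cov(term_i, DDRS) / Var(DDRS)`. By bilinearity of the
#' covariance the four shares sum to exactly 100 whatever the correlation
#' structure of the components, which is why this decomposition is used for
#' components coupled through a common latent factor.
#'
#' @param cohort Profile data frame with the four component columns
#'   (>= 2 rows).
#' @param weights A [weight_config()] object.
#' @return A one-row data frame `share_S`, `share_A`, `share_K`, `share_Q`
#'   (percent).
#' @examples
#' cohort <- generate_profiles(generator_config(n_profiles = 500, seed = 2))
#' variance_decomposition(cohort, weight_config())
#' @export
variance_decomposition <- function(cohort, weights = weight_config()) {
  validate_weights(unclass(weights))
  if (nrow(cohort) < 2L) {
    stop("insufficient data: variance decomposition needs >= 2 profiles",
         call. = FALSE)
  }
  terms <- cbind(S = weights[["w_S"]] * cohort$sugar_S,
                 A = weights[["w_A"]] * cohort$acid_A,
                 K = weights[["w_K"]] * (100 - cohort$protective_K),
                 Q = weights[["w_Q"]] * (100 - cohort$quality_Q))
  ddrs <- rowSums(terms)
  v <- stats::var(ddrs)
  if (v <= 0) {
    stop("degenerate cohort: DDRS variance is zero", call. = FALSE)
  }
  shares <- 100 * apply(terms, 2L, stats::cov, y = ddrs) / v
  data.frame(share_S = shares[["S"]], share_A = shares[["A"]],
             share_K = shares[["K"]], share_Q = shares[["Q"]])
}

#' Two-group DDRS contrast
#'
#' Welch's independent-samples t-test (unequal variances) together with
#' Cohen's d computed from the pooled standard deviation with the
#' `n1 + n2 - 2` denominator.
#'
#' @param ddrs_a,ddrs_b Numeric DDRS vectors of the two groups, each with
#'   at least 2 observations.
#' @return A one-row data frame: `t_statistic`, `p_value`, `cohens_d`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' group_contrast(c(1, 2, 3), c(4, 5, 6))  # d = -3
#' @export
group_contrast <- function(ddrs_a, ddrs_b) {
  if (!is.numeric(ddrs_a) || !is.numeric(ddrs_b) ||
      anyNA(ddrs_a) || anyNA(ddrs_b)) {
    stop("group values must be numeric with no missing values", call. = FALSE)
  }
  n1 <- length(ddrs_a); n2 <- length(ddrs_b)
  if (n1 < 2L || n2 < 2L) {
    stop("insufficient data: each group needs at least 2 observations",
         call. = FALSE)
  }
  m1 <- mean(ddrs_a); m2 <- mean(ddrs_b)
  s_pooled <- sqrt(((n1 - 1) * stats::var(ddrs_a) +
                    (n2 - 1) * stats::var(ddrs_b)) / (n1 + n2 - 2))
  if (s_pooled == 0) {
    # both groups constant: degenerate limit of the contrast
    d <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    t_stat <- d
    p <- if (m1 == m2) 1 else 0
  } else {
    tt <- stats::t.test(ddrs_a, ddrs_b, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    d <- (m1 - m2) / s_pooled
  }
  data.frame(t_statistic = t_stat, p_value = p, cohens_d = d,
             mean_a = m1, mean_b = m2, n_a = n1, n_b = n2)
}
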