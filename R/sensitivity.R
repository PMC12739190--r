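# One-at-a-time weight-sensitivity analysis: perturb each DDRS weight by
# +/- pct (multiplicative, with proportional renormalization of the other
# three weights so the composite keeps its 0-100 bound) and record the
# swing in cohort mean DDRS; plus the dedicated sugar-weight experiment
# moving w_S between 0.30 and 0.50.

#' Tornado analysis of DDRS weight perturbations
#'
#' For each component in turn, the baseline weight is multiplied by
#' `1 - pct` and `1 + pct` (other weights renormalized via
#' [perturb_weights()]), the cohort mean DDRS is evaluated under both
#' settings, and the absolute swing `delta_range` is recorded. Rows are
#' returned sorted by decreasing swing, the ordering displayed by a
#' tornado diagram.
#'
#' @param cohort Non-empty profile data frame.
#' @param base Baseline [weight_config()].
#' @param pct Relative perturbation (default 0.20 for +/-20%).
#' @return A data frame with columns `component`, `weight_low`,
#'   `weight_high`, `mean_ddrs_low`, `mean_ddrs_high`, `delta_range`,
#'   sorted by decreasing `delta_range`.
#' @examples
#' cohort <- generate_profiles(generator_config(n_profiles = 500, seed = 5))
#' tornado_analysis(cohort, weight_config())
#' @export
tornado_analysis <- function(cohort, base = weight_config(), pct = 0.20) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (!is.numeric(pct) || length(pct) != 1L || pct < 0 || pct >= 1) {
    stop("pct must be a single value in [0, 1)", call. = FALSE)
  }
  rows <- lapply(c("S", "A", "K", "Q"), function(comp) {
    w_lo <- perturb_weights(base, comp, 1 - pct)
    w_hi <- perturb_weights(base, comp, 1 + pct)
    m_lo <- mean(score_cohort(cohort, w_lo))
    m_hi <- mean(score_cohort(cohort, w_hi))
    data.frame(component = comp,
               weight_low = w_lo[[paste0("w_", comp)]],
               weight_high = w_hi[[paste0("w_", comp)]],
               mean_ddrs_low = m_lo, mean_ddrs_high = m_hi,
               delta_range = abs(m_hi - m_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_range), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sugar-weight experiment: 30% to 50% sugar weighting
#'
#' Recomputes the cohort mean DDRS with the sugar weight set to 0.30 and to
#' 0.50 (the other weights proportionally renormalized each time) and
#' returns the percent change of the mean,
#' `100 * (mean_0.50 - mean_0.30) / mean_0.30`.
#'
#' @param cohort Non-empty profile data frame.
#' @param base Baseline [weight_config()]; its `w_S` anchors the
#'   multiplicative factors `0.30 / w_S` and `0.50 / w_S`.
#' @param w_low,w_high Sugar weights to contrast (defaults 0.30 and 0.50).
#' @return A single numeric percent change; attributes `mean_low` and
#'   `mean_high` carry the two underlying means.
#' @examples
#' cohort <- generate_profiles(generator_config(n_profiles = 500, seed = 5))
#' sugar_weight_experiment(cohort)
#' @export
sugar_weight_experiment <- function(cohort, base = weight_config(),
                                    w_low = 0.30, w_high = 0.50) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  base_s <- base[["w_S"]]
  m_low <- mean(score_cohort(cohort, perturb_weights(base, "S", w_low / base_s)))
  m_high <- mean(score_cohort(cohort, perturb_weights(base, "S", w_high / base_s)))
  if (m_low == 0) {
    stop("percent change undefined: mean DDRS at the low sugar weight is zero",
         call. = FALSE)
  }
  structure(100 * (m_high - m_low) / m_low,
            mean_low = m_low, mean_high = m_high)
}
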