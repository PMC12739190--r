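# Core DDRS scoring. The composite is affine in the four components, so all
# cohort-level behavior (bounds, monotonicity, weight linearity) follows from
# the formula applied element-wise.

ddrs_formula <- function(S, A, K, Q, w) {
  w[["w_S"]] * S + w[["w_A"]] * A + w[["w_K"]] * (100 - K) + w[["w_Q"]] * (100 - Q)
}

check_components <- function(S, A, K, Q) {
  for (nm in c("S", "A", "K", "Q")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v)) {
      stop(sprintf("component %s must be numeric with no missing values", nm), call. = FALSE)
    }
    if (any(v < 0 | v > 100)) {
      stop(sprintf("component %s outside [0, 100] (found %g)", nm,
                   v[which(v < 0 | v > 100)[1L]]), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Compute the Dental Diet Risk Score for one profile
#'
#' Evaluates `w_S*S + w_A*A + w_K*(100-K) + w_Q*(100-Q)` for a single
#' dietary profile. With weights summing to 1 the result lies in \[0, 100\];
#' 0 is the minimal-risk corner (no sugar or acid, maximal protective intake
#' and quality) and 100 the maximal-risk corner.
#'
#' @param profile A list or one-row data frame with numeric fields
#'   `sugar_S`, `acid_A`, `protective_K`, `quality_Q`, each in \[0, 100\].
#' @param weights A [weight_config()] object.
#'
#' @return A single numeric DDRS value in \[0, 100\].
#'
#' @examples
#' p <- list(sugar_S = 80, acid_A = 60, protective_K = 20, quality_Q = 30)
#' compute_ddrs(p, weight_config())  # 74.5
#' @export
compute_ddrs <- function(profile, weights = weight_config()) {
  validate_weights(unclass(weights))
  need <- c("sugar_S", "acid_A", "protective_K", "quality_Q")
  if (!all(need %in% names(profile))) {
    stop("profile must contain fields sugar_S, acid_A, protective_K, quality_Q",
         call. = FALSE)
  }
  S <- as.numeric(profile[["sugar_S"]]); A <- as.numeric(profile[["acid_A"]])
  K <- as.numeric(profile[["protective_K"]]); Q <- as.numeric(profile[["quality_Q"]])
  if (any(lengths(list(S, A, K, Q)) != 1L)) {
    stop("compute_ddrs scores a single profile; use score_cohort() for cohorts",
         call. = FALSE)
  }
  check_components(S, A, K, Q)
  ddrs_formula(S, A, K, Q, weights)
}

#' Score a cohort of dietary profiles
#'
#' Vectorized, order-preserving application of [compute_ddrs()] to every row
#' of a cohort.
#'
#' @param profiles A data frame with columns `sugar_S`, `acid_A`,
#'   `protective_K`, `quality_Q` (e.g. from [generate_profiles()]).
#' @param weights A [weight_config()] object.
#'
#' @return Numeric vector of DDRS values, one per row (length 0 for an
#'   empty cohort).
#'
#' @examples
#' cohort <- generate_profiles(generator_config(n_profiles = 50, seed = 1))
#' summary(score_cohort(cohort))
#' @export
score_cohort <- function(profiles, weights = weight_config()) {
  validate_weights(unclass(weights))
  need <- c("sugar_S", "acid_A", "protective_K", "quality_Q")
  if (!all(need %in% names(profiles))) {
    stop("cohort must contain columns sugar_S, acid_A, protective_K, quality_Q",
         call. = FALSE)
  }
  if (nrow(profiles) == 0L) return(numeric(0))
  check_components(profiles$sugar_S, profiles$acid_A,
                   profiles$protective_K, profiles$quality_Q)
  ddrs_formula(profiles$sugar_S, profiles$acid_A,
               profiles$protective_K, profiles$quality_Q, weights)
}
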