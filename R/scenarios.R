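# Scenario classification and per-group DDRS summaries: profiles are
# labeled healthy / unhealthy / mixed from their three index scores, and
# each group is summarized by its DDRS median and interquartile range.

#' Scenario thresholds
#'
#' @param healthy_min Minimum of all three normalized indices for the
#'   healthy label (default 70).
#' @param unhealthy_max Maximum of all three indices for the unhealthy
#'   label (default 30); must satisfy
#'   `0 <= unhealthy_max < healthy_min <= 100`.
#' @return An object of class `ddrs_scenario_spec`.
#' @examples
#' scenario_spec()
#' @export
scenario_spec <- function(healthy_min = 70, unhealthy_max = 30) {
  if (!is.numeric(healthy_min) || !is.numeric(unhealthy_max) ||
      length(healthy_min) != 1L || length(unhealthy_max) != 1L) {
    stop("thresholds must be single numeric values", call. = FALSE)
  }
  if (!(0 <= unhealthy_max && unhealthy_max < healthy_min && healthy_min <= 100)) {
    stop("thresholds must satisfy 0 <= unhealthy_max < healthy_min <= 100",
         call. = FALSE)
  }
  structure(list(healthy_min = healthy_min, unhealthy_max = unhealthy_max),
            class = "ddrs_scenario_spec")
}

#' Classify profiles into dietary scenarios
#'
#' A profile is `healthy` when all three normalized indices (MEDAS on
#' 0-100, DPI, HEI) are at or above `healthy_min`, `unhealthy` when all are
#' at or below `unhealthy_max`, and `mixed` otherwise. Every profile
#' receives exactly one label.
#'
#' @param profiles Profile data frame (or single profile) with
#'   `medas_raw`, `dpi`, `hei`.
#' @param spec A [scenario_spec()].
#' @return Character vector of labels, one per profile.
#' @examples
#' classify_profiles(list(medas_raw = 7, dpi = 25, hei = 65))  # "mixed"
#' @export
classify_profiles <- function(profiles, spec = scenario_spec()) {
  stopifnot(inherits(spec, "ddrs_scenario_spec"))
  idx <- validate_indices(profiles)
  hi <- idx$medas_norm >= spec$healthy_min & idx$dpi >= spec$healthy_min &
    idx$hei >= spec$healthy_min
  lo <- idx$medas_norm <= spec$unhealthy_max & idx$dpi <= spec$unhealthy_max &
    idx$hei <= spec$unhealthy_max
  ifelse(hi, "healthy", ifelse(lo, "unhealthy", "mixed"))
}

#' Summarize DDRS distributions per dietary scenario
#'
#' Splits a scored cohort by scenario label and reports, per group, the
#' member count, the DDRS median and interquartile range (25th/75th
#' percentiles with linear interpolation), and the mean of each index. A
#' group with no members is reported with `n = 0` and `NA` quantiles rather
#' than raising an error. When both the healthy and unhealthy groups have
#' at least two members, their [group_contrast()] (Welch t, Cohen's d) is
#' attached as attribute `"contrast"`.
#'
#' @param cohort Profile data frame with index columns and a numeric
#'   `ddrs` column (see [score_cohort()]).
#' @param spec A [scenario_spec()].
#' @return A data frame with one row per scenario (`healthy`, `unhealthy`,
#'   `mixed`): `scenario`, `n`, `median_ddrs`, `iqr_low`, `iqr_high`,
#'   `mean_medas`, `mean_dpi`, `mean_hei`.
#' @examples
#' cohort <- generate_profiles(generator_config(n_profiles = 300, seed = 4))
#' cohort$ddrs <- score_cohort(cohort)
#' summarize_scenarios(cohort)
#' @export
summarize_scenarios <- function(cohort, spec = scenario_spec()) {
  if (!"ddrs" %in% names(cohort)) {
    stop("cohort must carry a ddrs column; score it with score_cohort() first",
         call. = FALSE)
  }
  labels <- classify_profiles(cohort, spec)
  idx <- validate_indices(cohort)
  rows <- lapply(c("healthy", "unhealthy", "mixed"), function(lab) {
    sel <- labels == lab
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(scenario = lab, n = 0L, median_ddrs = NA_real_,
                        iqr_low = NA_real_, iqr_high = NA_real_,
                        mean_medas = NA_real_, mean_dpi = NA_real_,
                        mean_hei = NA_real_))
    }
    d <- cohort$ddrs[sel]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(scenario = lab, n = n, median_ddrs = q[2L],
               iqr_low = q[1L], iqr_high = q[3L],
               mean_medas = mean(idx$medas_norm[sel]),
               mean_dpi = mean(idx$dpi[sel]),
               mean_hei = mean(idx$hei[sel]))
  })
  out <- do.call(rbind, rows)
  h <- cohort$ddrs[labels == "healthy"]
  u <- cohort$ddrs[labels == "unhealthy"]
  if (length(h) >= 2L && length(u) >= 2L) {
    attr(out, "contrast") <- group_contrast(h, u)
  }
  out
}
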