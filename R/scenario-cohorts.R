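# Scenario preset cohorts.
#
# The scenario analysis contrasts predefined dietary-quality conditions.
# Each preset is a set of overrides of the calibrated generator, frozen in
# inst/extdata/scenario_presets.yaml:
#   healthy   — latent factor shifted toward 1 until the group means of
#               normalized MEDAS, DPI and HEI all reach >= 70;
#   unhealthy — shifted toward 0 until all means are <= 30;
#   mixed     — intermediate latent level with the protective-food pathway
#               decoupled from the latent factor (low DPI despite moderate
#               MEDAS/HEI), targeting index means near (55, 25, 65).

scenario_presets <- function() {
  yaml::read_yaml(calibrated_fixture_path("scenario_presets.yaml"))
}

#' Generate a scenario preset cohort
#'
#' Draws a cohort from one of the three frozen scenario presets
#' (`"healthy"`, `"unhealthy"`, `"mixed"`), which override the calibrated
#' generator's latent-factor parameters to represent contrasting dietary
#' patterns. Deterministic under a fixed seed.
#'
#' @param scenario Preset name: `"healthy"`, `"unhealthy"` or `"mixed"`.
#' @param n Cohort size (default 2000); `n = 0` returns an empty cohort.
#' @param seed Integer seed.
#' @return A profile data frame as from [generate_profiles()] (0 rows when
#'   `n = 0`).
#' @examples
#' h <- generate_scenario_cohort("healthy", n = 500, seed = 42)
#' colMeans(validate_indices(h))
#' @export
generate_scenario_cohort <- function(scenario, n = 2000L, seed = 42L) {
  presets <- scenario_presets()
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% names(presets)) {
    stop(sprintf("unknown scenario preset %s; valid presets: %s",
                 deparse(scenario), paste(names(presets), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  if (n == 0L) {
    empty <- data.frame(sugar_S = numeric(0), acid_A = numeric(0),
                        protective_K = numeric(0), quality_Q = numeric(0),
                        medas_raw = integer(0), dpi = numeric(0),
                        hei = numeric(0))
    attr(empty, "clamp_frac") <- NA_real_
    return(empty)
  }
  cfg <- do.call(generator_config,
                 c(list(n_profiles = as.integer(n), seed = seed),
                   presets[[scenario]]))
  generate_profiles(cfg)
}
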