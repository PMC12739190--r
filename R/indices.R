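#' Rescale a raw MEDAS score to the common 0-100 scale
#'
#' The Mediterranean Diet Adherence Screener (MEDAS) is a 14-item tool
#' scored 0-14. All downstream analyses work on a common 0-100 scale, so
#' the raw total is rescaled linearly as `raw * 100 / 14` with the exact
#' rational factor (no rounding); DPI and HEI are already 0-100 and pass
#' through unchanged.
#'
#' @param raw Integer-valued MEDAS total(s) in 0-14.
#' @return Numeric score(s) in \[0, 100\]; 0 maps to 0 and 14 to exactly 100.
#' @examples
#' normalize_medas(7)   # 50
#' normalize_medas(0:14)
#' @export
normalize_medas <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L || anyNA(raw)) {
    stop("raw MEDAS must be numeric with no missing values", call. = FALSE)
  }
  if (any(raw != round(raw))) {
    stop(sprintf("raw MEDAS must be integer-valued (found %g)",
                 raw[which(raw != round(raw))[1L]]), call. = FALSE)
  }
  if (any(raw < 0 | raw > 14)) {
    stop(sprintf("raw MEDAS outside [0, 14] (found %g)",
                 raw[which(raw < 0 | raw > 14)[1L]]), call. = FALSE)
  }
  raw * (100 / 14)
}

#' Validate and assemble the three index scores of a profile
#'
#' Returns the index triple used by scenario classification: MEDAS rescaled
#' to 0-100 plus DPI and HEI validated against their 0-100 range. Pure
#' pass-through apart from the MEDAS rescale, and idempotent in the sense
#' that re-validating an already valid triple changes nothing.
#'
#' @param profile A list or one-row data frame with `medas_raw` (integer
#'   0-14), `dpi` and `hei` (each 0-100). Vectorized over rows when given a
#'   multi-row data frame.
#' @return A data frame with columns `medas_norm`, `dpi`, `hei`.
#' @examples
#' validate_indices(list(medas_raw = 7, dpi = 25, hei = 65))
#' @export
validate_indices <- function(profile) {
  need <- c("medas_raw", "dpi", "hei")
  if (!all(need %in% names(profile))) {
    stop("profile must contain fields medas_raw, dpi, hei", call. = FALSE)
  }
  medas_norm <- normalize_medas(as.numeric(profile[["medas_raw"]]))
  for (nm in c("dpi", "hei")) {
    v <- as.numeric(profile[[nm]])
    if (anyNA(v)) stop(sprintf("index %s has missing values", nm), call. = FALSE)
    if (any(v < 0 | v > 100)) {
      stop(sprintf("index %s outside [0, 100] (found %g)", nm,
                   v[which(v < 0 | v > 100)[1L]]), call. = FALSE)
    }
  }
  data.frame(medas_norm = medas_norm,
             dpi = as.numeric(profile[["dpi"]]),
             hei = as.numeric(profile[["hei"]]))
}
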