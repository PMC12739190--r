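#' DDRS component weights
#'
#' Construct and validate the weight scheme of the Dental Diet Risk Score.
#' The score is the affine composite
#' \deqn{DDRS = w_S S + w_A A + w_K (100 - K) + w_Q (100 - Q)}
#' so that higher sugar (S) and acid (A) exposure raise risk while higher
#' protective-food intake (K) and overall diet quality (Q) lower it. The
#' defaults are the literature-informed scheme 0.40 / 0.20 / 0.25 / 0.15.
#'
#' @param w_S Weight on free-sugar exposure (default 0.40).
#' @param w_A Weight on acidic-beverage exposure (default 0.20).
#' @param w_K Weight on the protective-food deficit `100 - K` (default 0.25).
#' @param w_Q Weight on the diet-quality deficit `100 - Q` (default 0.15).
#'
#' @return An object of class `ddrs_weights`: a named numeric vector
#'   `c(w_S, w_A, w_K, w_Q)`.
#'
#' @details Weights must be non-negative and sum to 1 (tolerance 1e-9);
#'   weights summing to 1 guarantee the score stays in \[0, 100\] for
#'   components in \[0, 100\].
#'
#' @examples
#' weight_config()
#' weight_config(0.5, 0.2, 0.2, 0.1)
#' @export
weight_config <- function(w_S = 0.40, w_A = 0.20, w_K = 0.25, w_Q = 0.15) {
  w <- c(w_S = w_S, w_A = w_A, w_K = w_K, w_Q = w_Q)
  validate_weights(w)
  structure(w, class = "ddrs_weights")
}

validate_weights <- function(w) {
  if (!is.numeric(w) || length(w) != 4L || anyNA(w)) {
    stop("weights must be four non-missing numeric values", call. = FALSE)
  }
  if (any(w < 0)) {
    bad <- names(w)[which(w < 0)[1L]]
    stop(sprintf("weight %s is negative (%g); all weights must be >= 0", bad, w[[bad]]),
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("weights must sum to 1 (got %.12f)", sum(w)), call. = FALSE)
  }
  invisible(w)
}

#' @export
print.ddrs_weights <- function(x, ...) {
  cat("DDRS weights: S =", format(x[["w_S"]]), " A =", format(x[["w_A"]]),
      " (100-K) =", format(x[["w_K"]]), " (100-Q) =", format(x[["w_Q"]]), "\n")
  invisible(x)
}

#' Perturb one DDRS weight with proportional renormalization
#'
#' Multiplies the weight of one component by `factor` and rescales the
#' remaining three weights by a common multiplier so the four weights again
#' sum to 1. This is the perturbation primitive behind the one-at-a-time
#' (tornado) sensitivity analysis.
#'
#' @param base A [weight_config()] object.
#' @param component One of `"S"`, `"A"`, `"K"`, `"Q"`.
#' @param factor Positive multiplicative factor on the target weight; the
#'   perturbed weight `factor * w` must remain below 1.
#'
#' @return A new `ddrs_weights` object summing to 1.
#'
#' @examples
#' perturb_weights(weight_config(), "S", 1.2)  # w_S 0.40 -> 0.48
#' @export
perturb_weights <- function(base, component, factor) {
  stopifnot(inherits(base, "ddrs_weights"))
  if (!is.character(component) || length(component) != 1L ||
      !component %in% c("S", "A", "K", "Q")) {
    stop("component must be one of \"S\", \"A\", \"K\", \"Q\"", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  key <- paste0("w_", component)
  w <- unclass(base)
  target <- w[[key]] * factor
  if (target >= 1) {
    stop(sprintf("infeasible perturbation: %s would become %g (>= 1) before renormalization",
                 key, target), call. = FALSE)
  }
  others <- setdiff(names(w), key)
  rest <- sum(w[others])
  w[others] <- if (rest > 0) w[others] * (1 - target) / rest else (1 - target) / 3
  w[[key]] <- target
  structure(w, class = "ddrs_weights")
}
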