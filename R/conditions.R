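#' lnscore: lymph-node involvement scoring from preclinical ultrasound
#'
#' Quantifies tumor-draining lymph nodes in a paired left/right design:
#' Cavalieri volumes and length/width morphometry from 3D B-mode contour
#' stacks, bolus-kinetic perfusion parameters (arrival, time-to-peak,
#' wash-in rate) from contrast-enhanced ultrasound time-intensity curves,
#' a five-parameter binary score with missing-data-aware sum score, and
#' diagnostic evaluation against histopathology with exact binomial
#' confidence intervals. A synthetic-cohort generator emulates the paired
#' small-animal study design end to end.
#'
#' @keywords internal
"_PACKAGE"

# Structured error helper: every package error carries class "lnscore_error"
# plus one specific subclass so callers can branch on failure mode.
stop_lnscore <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "lnscore_error", "error")))
}

abort_degenerate <- function(msg) stop_lnscore(msg, "lnscore_degenerate_geometry")
abort_invalid <- function(msg) stop_lnscore(msg, "lnscore_invalid_input")
abort_spec <- function(msg) stop_lnscore(msg, "lnscore_invalid_spec")
abort_no_enhancement <- function(msg) stop_lnscore(msg, "lnscore_no_enhancement")
abort_fit_failure <- function(msg) stop_lnscore(msg, "lnscore_fit_failure")
abort_insufficient <- function(msg) stop_lnscore(msg, "lnscore_insufficient_data")
abort_degenerate_test <- function(msg) stop_lnscore(msg, "lnscore_degenerate_test")
abort_empty_eval <- function(msg) stop_lnscore(msg, "lnscore_empty_evaluation")
abort_schema <- function(msg) stop_lnscore(msg, "lnscore_schema_error")
abort_pairing <- function(msg) stop_lnscore(msg, "lnscore_pairing_error")

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
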