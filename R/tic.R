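#' Construct a time-intensity curve
#'
#' A CEUS bolus time-intensity curve (TIC): mean contrast enhancement in a
#' region of interest sampled over the cine loop, together with a mask of
#' frames excluded after motion correction.
#'
#' @param time_s strictly increasing numeric vector of sample times (s).
#' @param intensity numeric vector of mean ROI intensities (a.u.), same
#'   length as `time_s`.
#' @param excluded logical mask of motion-excluded frames (default none).
#' @param node_id character identifier.
#' @return An object of class `tic`.
#' @export
time_intensity_curve <- function(time_s, intensity, excluded = NULL,
                                 node_id = "node") {
  n <- length(time_s)
  if (n < 50L)
    abort_invalid("a TIC needs at least 50 samples")
  if (length(intensity) != n)
    abort_invalid("`time_s` and `intensity` must have the same length")
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  if (length(excluded) != n || !is.logical(excluded))
    abort_invalid("`excluded` must be a logical vector matching `time_s`")
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0))
    abort_invalid("`time_s` must be finite and strictly increasing")
  if (any(time_s < 0))
    abort_invalid("`time_s` must be non-negative")
  structure(
    list(time_s = as.numeric(time_s), intensity = as.numeric(intensity),
         excluded = excluded, node_id = as.character(node_id)),
    class = "tic"
  )
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("<tic> node '%s': %d frames over %.2f s, %.1f%% excluded\n",
              x$node_id, length(x$time_s), diff(range(x$time_s)),
              100 * mean(x$excluded)))
  invisible(x)
}

excluded_fraction <- function(tic) mean(tic$excluded)
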