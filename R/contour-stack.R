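#' Construct a contour stack
#'
#' A contour stack is the raw geometry of one lymph node as acquired by a
#' motorised 3D sweep: an ordered list of simple closed planar polygons
#' (one per B-mode slice, vertices in mm in a common in-plane frame) at a
#' uniform elevational spacing.
#'
#' @param slices list of numeric matrices, each `n_i x 2` (columns x, y in
#'   mm), one per slice in physical order along the translation axis. Each
#'   polygon is closed implicitly (last vertex connects to first).
#' @param spacing_mm positive slice spacing in mm (motor step size).
#' @param node_id character identifier for the node.
#' @return An object of class `contour_stack`.
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' contour_stack(list(sq), spacing_mm = 0.038, node_id = "demo")
#' @export
contour_stack <- function(slices, spacing_mm, node_id = "node") {
  if (!is.list(slices) || length(slices) < 1L)
    abort_invalid("`slices` must be a non-empty list of vertex matrices")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    abort_invalid("`spacing_mm` must be a single positive number")
  slices <- lapply(seq_along(slices), function(i) {
    m <- slices[[i]]
    if (is.data.frame(m)) m <- as.matrix(m)
    if (!is.matrix(m) || ncol(m) != 2L || !is.numeric(m))
      abort_invalid(sprintf("slice %d is not an n x 2 numeric matrix", i))
    if (nrow(m) < 3L)
      abort_degenerate(sprintf("slice %d has fewer than 3 vertices", i))
    if (any(!is.finite(m)))
      abort_invalid(sprintf("slice %d contains non-finite coordinates", i))
    dimnames(m) <- list(NULL, c("x_mm", "y_mm"))
    m
  })
  structure(
    list(slices = slices, spacing_mm = as.numeric(spacing_mm),
         node_id = as.character(node_id)),
    class = "contour_stack"
  )
}

#' @export
print.contour_stack <- function(x, ...) {
  nv <- vapply(x$slices, nrow, integer(1))
  cat(sprintf("<contour_stack> node '%s': %d slices at %.3f mm spacing (%d-%d vertices/slice)\n",
              x$node_id, length(x$slices), x$spacing_mm, min(nv), max(nv)))
  invisible(x)
}

#' Polygon area by the shoelace formula
#'
#' Absolute (orientation-independent) area of a simple closed polygon.
#'
#' @param polygon numeric `n x 2` matrix of vertices (mm); the polygon is
#'   closed implicitly.
#' @return Area in mm^2 (non-negative scalar).
#' @examples
#' polygon_area(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE))
#' @export
polygon_area <- function(polygon) {
  if (is.data.frame(polygon)) polygon <- as.matrix(polygon)
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    abort_degenerate("polygon must have at least 3 vertices (n x 2 matrix)")
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}
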