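#' Cavalieri volume of a contour stack
#'
#' Volume estimate as the sum of slice areas times the uniform slice
#' spacing (slab sum). At a 0.038 mm motor step this is accurate to well
#' under 1% for node-sized convex bodies; no end-cap correction is applied.
#'
#' @param stack a [contour_stack()].
#' @return Volume in mm^3.
#' @examples
#' st <- generate_ellipsoid_contours(c(1, 1, 1), spacing_mm = 0.038, seed = 1)
#' volume_from_stack(st) # ~ 4/3 * pi
#' @export
volume_from_stack <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  areas <- vapply(stack$slices, polygon_area, numeric(1))
  stack$spacing_mm * sum(areas)
}

# cross product z-component of (b - a) x (c - a)
.cross3 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# Convex-hull diameter by rotating calipers (antipodal pairs).
# Returns list(d, i, j): squared-distance-maximal vertex pair of `pts`.
.calipers_diameter <- function(pts) {
  h <- grDevices::chull(pts)          # clockwise indices
  h <- rev(h)                         # counter-clockwise
  P <- pts[h, , drop = FALSE]
  m <- nrow(P)
  if (m == 1L) return(list(d = 0, i = h[1L], j = h[1L]))
  if (m == 2L) {
    return(list(d = sqrt(sum((P[1L, ] - P[2L, ])^2)), i = h[1L], j = h[2L]))
  }
  best <- -1; bi <- 1L; bj <- 1L
  upd <- function(a, b) {
    d <- sum((P[a, ] - P[b, ])^2)
    if (d > best) { best <<- d; bi <<- a; bj <<- b }
  }
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- i %% m + 1L
    repeat {
      j2 <- j %% m + 1L
      if (.cross3(P[i, ], P[i2, ], P[j2, ]) > .cross3(P[i, ], P[i2, ], P[j, ])) {
        j <- j2
      } else break
    }
    upd(i, j); upd(i2, j)
  }
  list(d = sqrt(best), i = h[bi], j = h[bj])
}

# Exhaustive O(n^2) maximum vertex-pair chord; independent oracle for the
# calipers routine and fallback for tiny inputs.
.exhaustive_diameter <- function(pts) {
  n <- nrow(pts)
  best <- -1; bi <- 1L; bj <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum((pts[i, ] - pts[j, ])^2)
      if (d > best) { best <- d; bi <- i; bj <- j }
    }
  }
  list(d = sqrt(best), i = bi, j = bj)
}

#' Node length and width from a contour stack
#'
#' The length is the longest diameter found over all slices: the maximum
#' vertex-pair chord of each slice polygon (its convex-hull diameter,
#' found by rotating calipers), maximised over slices. The width is the
#' longest perpendicular diameter in the same slice, measured as the
#' breadth of that slice perpendicular to the length chord, i.e. the
#' maximal perpendicular component over all point pairs of the boundary
#' (equivalently the support width normal to the length axis) --- the
#' caliper measurement a reader makes on the B-mode image.
#'
#' Slices with zero area (collinear vertices) are skipped; if every slice
#' is degenerate an error of class `lnscore_degenerate_geometry` is
#' signalled.
#'
#' @param stack a [contour_stack()].
#' @return list with `length_mm`, `width_mm`, `slice_index` (0-based index
#'   of the slice carrying the length chord).
#' @examples
#' rect <- matrix(c(0, 0, 4, 0, 4, 1, 0, 1), ncol = 2, byrow = TRUE)
#' length_width(contour_stack(list(rect), 0.038)) # length sqrt(17), width ~1.94
#' @export
length_width <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  best_len <- -1; best_slice <- NA_integer_; best_pair <- NULL
  for (k in seq_along(stack$slices)) {
    poly <- stack$slices[[k]]
    if (polygon_area(poly) <= 0) next
    dk <- .calipers_diameter(poly)
    if (dk$d > best_len) { best_len <- dk$d; best_slice <- k; best_pair <- dk }
  }
  if (is.na(best_slice))
    abort_degenerate("all slices are degenerate (zero area); cannot measure length/width")
  poly <- stack$slices[[best_slice]]
  u <- poly[best_pair$j, ] - poly[best_pair$i, ]
  u <- u / sqrt(sum(u^2))
  nrm <- c(-u[2], u[1])
  proj <- poly %*% nrm
  width <- max(proj) - min(proj)
  list(length_mm = best_len, width_mm = as.numeric(width),
       slice_index = best_slice - 1L)
}

#' Full morphometry of one node
#'
#' Computes volume, length, width, length/width ratio and the roundness
#' classification (ratio < 2 means round, a sonographic sign of malignant
#' involvement) from a contour stack.
#'
#' @param stack a [contour_stack()].
#' @return An object of class `ln_morphometry`: list with `node_id`,
#'   `volume_mm3`, `length_mm`, `width_mm`, `lw_ratio`, `is_round`,
#'   `length_slice_index`.
#' @export
measure_stack <- function(stack) {
  lw <- length_width(stack)
  if (lw$width_mm <= 0)
    abort_degenerate("zero width: slice polygon is degenerate")
  structure(
    list(node_id = stack$node_id,
         volume_mm3 = volume_from_stack(stack),
         length_mm = lw$length_mm,
         width_mm = lw$width_mm,
         lw_ratio = lw$length_mm / lw$width_mm,
         is_round = (lw$length_mm / lw$width_mm) < 2,
         length_slice_index = lw$slice_index),
    class = "ln_morphometry"
  )
}

#' Paired left/right volume ratio
#'
#' Ratio of the tumor-draining (left) node volume to its within-animal
#' control (right) node volume; the unit of the volume criterion.
#'
#' @param left_volume_mm3,right_volume_mm3 positive volumes in mm^3.
#' @return `left / right` quotient.
#' @examples
#' volume_ratio(12.076, 1.438)
#' @export
volume_ratio <- function(left_volume_mm3, right_volume_mm3) {
  if (!is.finite(left_volume_mm3) || !is.finite(right_volume_mm3) ||
      left_volume_mm3 <= 0 || right_volume_mm3 <= 0)
    abort_invalid("volumes must be finite and positive")
  left_volume_mm3 / right_volume_mm3
}
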