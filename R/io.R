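#' Write a cohort to a directory layout
#'
#' Serialises a cohort as plain comma-separated text: `cohort.csv` (one
#' row per node: subject, group, side, node id, hilum flag, pathology,
#' slice spacing and relative paths), `contours/<node_id>.csv`
#' (slice_index, vertex_index, x_mm, y_mm; slice_index is 0-based) and
#' `tic/<node_id>.csv` (time_s, intensity, excluded as 0/1), plus
#' `spec.dcf` mirroring the generating [cohort_spec()] when the cohort
#' came from [generate_cohort()].
#'
#' @param cohort a `synthetic_cohort` or a cohort loaded by
#'   [load_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "contours"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tic"), showWarnings = FALSE)
  rows <- list()
  for (subj in cohort) {
    for (side in c("left", "right")) {
      node <- subj[[side]]
      cpath <- file.path("contours", paste0(node$node_id, ".csv"))
      cdf <- do.call(rbind, lapply(seq_along(node$contours$slices), function(k) {
        m <- node$contours$slices[[k]]
        data.frame(slice_index = k - 1L,
                   vertex_index = seq_len(nrow(m)) - 1L,
                   x_mm = m[, 1], y_mm = m[, 2])
      }))
      utils::write.csv(cdf, file.path(dir, cpath), row.names = FALSE)
      tpath <- NA_character_
      if (!is.null(node$tic)) {
        tpath <- file.path("tic", paste0(node$node_id, ".csv"))
        utils::write.csv(
          data.frame(time_s = node$tic$time_s, intensity = node$tic$intensity,
                     excluded = as.integer(node$tic$excluded)),
          file.path(dir, tpath), row.names = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, group = subj$group, side = side,
        node_id = node$node_id, hilum_visible = node$hilum_visible,
        pathology_positive = if (side == "left") subj$pathology_positive_left
                             else subj$pathology_positive_right,
        spacing_mm = node$contours$spacing_mm,
        contour_path = cpath, tic_path = tpath,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    flat <- lapply(unclass(spec), function(v) format(v, digits = 17))
    write.dcf(as.data.frame(flat, stringsAsFactors = FALSE),
              file.path(dir, "spec.dcf"))
  }
  invisible(dir)
}

#' Load a cohort from a directory layout
#'
#' Reads and validates the layout written by [write_cohort()]. Schema
#' violations (duplicate subject/side, unknown group, missing referenced
#' files) raise an error of class `lnscore_schema_error` naming the
#' offending row.
#'
#' @param dir cohort directory containing `cohort.csv`.
#' @return A list of subjects mirroring [generate_cohort()] output
#'   (without latent `truth`), with attribute `"table"` holding the raw
#'   node table.
#' @export
load_cohort <- function(dir) {
  path <- file.path(dir, "cohort.csv")
  if (!file.exists(path)) abort_schema(paste("no cohort.csv under", dir))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "side", "node_id", "hilum_visible",
            "pathology_positive", "spacing_mm", "contour_path", "tic_path")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    abort_schema(paste("cohort.csv misses column(s):", paste(miss, collapse = ", ")))
  key <- paste(tab$subject_id, tab$side)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    abort_schema(sprintf("row %d: duplicated subject/side pair '%s'", i, key[i]))
  }
  bad_group <- !tab$group %in% c("tumor_injected", "control_injected")
  if (any(bad_group)) {
    i <- which(bad_group)[1L]
    abort_schema(sprintf("row %d: unknown group '%s'", i, tab$group[i]))
  }
  load_node <- function(i) {
    cfile <- file.path(dir, tab$contour_path[i])
    if (!file.exists(cfile))
      abort_schema(sprintf("row %d: contour file '%s' not found", i,
                           tab$contour_path[i]))
    cdf <- utils::read.csv(cfile)
    slices <- lapply(split(cdf, cdf$slice_index), function(d) {
      d <- d[order(d$vertex_index), , drop = FALSE]
      cbind(d$x_mm, d$y_mm)
    })
    slices <- slices[order(as.integer(names(slices)))]
    stack <- contour_stack(slices, spacing_mm = tab$spacing_mm[i],
                           node_id = tab$node_id[i])
    tic <- NULL
    if (!is.na(tab$tic_path[i]) && nzchar(tab$tic_path[i])) {
      tfile <- file.path(dir, tab$tic_path[i])
      if (!file.exists(tfile))
        abort_schema(sprintf("row %d: TIC file '%s' not found", i,
                             tab$tic_path[i]))
      tdf <- utils::read.csv(tfile)
      tic <- time_intensity_curve(tdf$time_s, tdf$intensity,
                                  as.logical(tdf$excluded),
                                  node_id = tab$node_id[i])
    }
    list(node_id = tab$node_id[i], contours = stack, tic = tic,
         hilum_visible = as.logical(tab$hilum_visible[i]))
  }
  subjects <- list()
  for (id in unique(tab$subject_id)) {
    idx <- which(tab$subject_id == id)
    sides <- tab$side[idx]
    if (!setequal(sides, c("left", "right")))
      abort_schema(sprintf("subject '%s' must have exactly one left and one right node", id))
    li <- idx[sides == "left"]; ri <- idx[sides == "right"]
    subjects[[length(subjects) + 1L]] <- list(
      subject_id = id, group = tab$group[li],
      left = load_node(li), right = load_node(ri),
      pathology_positive_left = as.logical(tab$pathology_positive[li]),
      pathology_positive_right = as.logical(tab$pathology_positive[ri]))
  }
  attr(subjects, "table") <- tab
  subjects
}
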